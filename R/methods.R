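#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d genes, R = %.3f\n", length(x$members), x$R))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Subnetwork marker set: %d marker(s), theta = %s\n",
              length(x$markers), format(x$config$theta)))
  for (i in seq_along(x$markers))
    cat(sprintf("  %2d. %2d genes  R = %7.3f  [%s%s]\n", i,
                length(x$markers[[i]]$members), x$markers[[i]]$R,
                paste(utils::head(x$markers[[i]]$members, 4L),
                      collapse = ", "),
                if (length(x$markers[[i]]$members) > 4L) ", ..." else ""))
  invisible(x)
}

#' Summarize a fitted marker set
#'
#' @param object A `"marker_set"` from [identify_markers()].
#' @param ... Unused.
#' @return A data frame with one row per marker: size, discriminative power
#'   R, number of merged source paths, and the members as a single string.
#' @export
summary.marker_set <- function(object, ...) {
  df <- data.frame(
    marker = seq_along(object$markers),
    size = vapply(object$markers, function(m) length(m$members), 1L),
    R = vapply(object$markers, function(m) m$R, 1),
    n_paths = vapply(object$markers, function(m) length(m$source_paths), 1L),
    members = vapply(object$markers,
                     function(m) paste(m$members, collapse = ";"), "")
  )
  class(df) <- c("summary.marker_set", "data.frame")
  df
}

#' Marker activity scores for new (or the training) samples
#'
#' Computes each marker's summed-LLR activity on an expression matrix using
#' the class-conditional Gaussian parameters stored in the fit (so no labels
#' of the new samples are needed).
#'
#' @param object A `"marker_set"`.
#' @param newdata An [expression_set()] or bare expression matrix covering
#'   the marker genes.
#' @param ... Unused.
#' @return A markers x samples numeric matrix of activity scores.
#' @export
predict.marker_set <- function(object, newdata, ...) {
  llr <- compute_llr(newdata, object$params)
  out <- t(vapply(object$markers,
                  function(m) subnetwork_activity(m$members, llr),
                  numeric(ncol(llr))))
  rownames(out) <- sprintf("marker_%03d", seq_along(object$markers))
  out
}

#' Plot the discriminative power profile of a marker set
#'
#' Bar plot of each marker's absolute activity t-statistic in discovery
#' order.
#'
#' @param x A `"marker_set"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.marker_set <- function(x, ...) {
  R <- vapply(x$markers, function(m) m$R, 1)
  graphics::barplot(R, names.arg = seq_along(R),
                    xlab = "marker (discovery order)",
                    ylab = "discriminative power |t|", ...)
  invisible(x)
}
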