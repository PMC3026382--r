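#' Run configuration for subnetwork marker discovery
#'
#' Collects every tunable of the discovery pipeline into a validated list.
#' Defaults follow the settings reported to work well on genome-scale PPI
#' overlays: `theta = 8`, beam width `M = 20`, `m = 100` top paths restricted
#' to lengths 5--8, merge threshold `epsilon = 0.01`, and `k = 50` markers.
#'
#' @param theta Non-negative trade-off between per-gene discriminative power
#'   and inter-member LLR correlation in the path score. `Inf` reduces the
#'   score to the plain mean absolute t-statistic of the members.
#' @param max_path_length Maximum number of nodes `L` in a searched path.
#' @param beam_width Number of top-scoring partial paths `M` retained per
#'   (node, length) cell during the dynamic-programming search.
#' @param top_paths Number `m` of top-scoring paths pooled for assembly.
#' @param length_range Integer pair `c(L_min, L_max)`; only paths whose node
#'   count falls in this closed range enter the assembly pool.
#' @param epsilon Relative improvement a merge must exceed to be accepted:
#'   a union is kept iff `R_new > (1 + epsilon) * R_old`.
#' @param marker_count Number `k` of non-overlapping markers to extract.
#' @param norm_exponent Length-normalization exponent: the reported path
#'   score is `S = s / l^norm_exponent`. Exponent 1 makes the
#'   `theta = Inf` score the mean member |t|; 2 is also supported.
#' @param var_equal Logical; `FALSE` (default) uses the Welch unequal-variance
#'   t-statistic, `TRUE` the pooled-variance Student form.
#' @param multi_pass Logical; if `TRUE` the greedy merge rescans the path pool
#'   until no further merge is accepted instead of the default single ordered
#'   pass.
#' @param rng_seed Integer seed recorded with the run.
#'
#' @return A list of class `"marker_config"`.
#' @examples
#' cfg <- marker_config(theta = 8, marker_count = 3)
#' cfg$length_range
#' @export
marker_config <- function(theta = 8,
                          max_path_length = 8L,
                          beam_width = 20L,
                          top_paths = 100L,
                          length_range = c(5L, 8L),
                          epsilon = 0.01,
                          marker_count = 50L,
                          norm_exponent = 1L,
                          var_equal = FALSE,
                          multi_pass = FALSE,
                          rng_seed = 1L) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0)
    stop("'theta' must be a single non-negative number (Inf allowed)")
  max_path_length <- as.integer(max_path_length)
  beam_width <- as.integer(beam_width)
  top_paths <- as.integer(top_paths)
  length_range <- as.integer(length_range)
  if (max_path_length < 1L) stop("'max_path_length' must be >= 1")
  if (beam_width < 1L) stop("'beam_width' must be >= 1")
  if (top_paths < 1L) stop("'top_paths' must be >= 1")
  if (length(length_range) != 2L || length_range[1L] > length_range[2L])
    stop("'length_range' must be c(L_min, L_max) with L_min <= L_max")
  if (length_range[1L] < 1L) stop("path lengths count nodes; L_min must be >= 1")
  if (!is.numeric(epsilon) || epsilon < 0) stop("'epsilon' must be >= 0")
  if (as.integer(marker_count) < 1L) stop("'marker_count' must be >= 1")
  if (!norm_exponent %in% c(1L, 2L)) stop("'norm_exponent' must be 1 or 2")
  structure(list(
    theta = theta,
    max_path_length = max_path_length,
    beam_width = beam_width,
    top_paths = top_paths,
    length_range = length_range,
    epsilon = epsilon,
    marker_count = as.integer(marker_count),
    norm_exponent = as.integer(norm_exponent),
    var_equal = isTRUE(var_equal),
    multi_pass = isTRUE(multi_pass),
    rng_seed = as.integer(rng_seed)
  ), class = "marker_config")
}

#' @export
print.marker_config <- function(x, ...) {
  cat("Subnetwork marker discovery configuration\n")
  cat(sprintf("  theta = %s, L = %d, M = %d, m = %d\n",
              format(x$theta), x$max_path_length, x$beam_width, x$top_paths))
  cat(sprintf("  length range [%d, %d], epsilon = %g, k = %d\n",
              x$length_range[1L], x$length_range[2L], x$epsilon,
              x$marker_count))
  cat(sprintf("  t-statistic: %s; normalization exponent %d; %s-pass merge\n",
              if (x$var_equal) "pooled Student" else "Welch",
              x$norm_exponent, if (x$multi_pass) "multi" else "single"))
  invisible(x)
}
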