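#' Estimate class-conditional Gaussian parameters per gene
#'
#' For each gene and each phenotype k the sample mean and the unbiased sample
#' standard deviation (divisor n_k - 1) over the phenotype-k samples are
#' computed. Standard deviations are floored at `1e-6` times the global
#' standard deviation of the whole matrix so that a gene constant within a
#' class still yields finite log-likelihood ratios.
#'
#' @param expression An [expression_set()].
#' @return A list of class `"gaussian_params"` with per-gene vectors
#'   `mu1, mu2, sd1, sd2` and the scalar `sigma_floor`.
#' @export
estimate_params <- function(expression) {
  labels <- expression$labels
  v <- expression$values
  n1 <- sum(labels == 1L); n2 <- sum(labels == 2L)
  if (n1 < 2L || n2 < 2L)
    stop("each phenotype class needs >= 2 samples to estimate a variance")
  v1 <- v[, labels == 1L, drop = FALSE]
  v2 <- v[, labels == 2L, drop = FALSE]
  gsd <- stats::sd(as.vector(v))
  sigma_floor <- 1e-6 * if (is.finite(gsd) && gsd > 0) gsd else 1
  row_sd <- function(m) sqrt(rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L))
  structure(list(
    mu1 = rowMeans(v1), mu2 = rowMeans(v2),
    sd1 = pmax(row_sd(v1), sigma_floor),
    sd2 = pmax(row_sd(v2), sigma_floor),
    sigma_floor = sigma_floor
  ), class = "gaussian_params")
}

#' Log-likelihood ratio transform of an expression matrix
#'
#' Each expression value x of gene i is replaced by
#' `alpha(x) = log f_i^1(x) - log f_i^2(x)`, the natural-log ratio of the
#' gene's class-1 to class-2 Gaussian density at x. Positive values favour
#' phenotype 1. Parameters may come from a training subset, allowing
#' leak-free transformation of held-out samples.
#'
#' @param expression An [expression_set()] (or a bare numeric matrix with the
#'   same gene rows as `params`).
#' @param params A `"gaussian_params"` object from [estimate_params()].
#' @return A numeric matrix with the dimensions and dimnames of the input.
#' @export
compute_llr <- function(expression, params) {
  v <- if (inherits(expression, "expression_set")) expression$values else expression
  if (!identical(rownames(v), names(params$mu1)))
    params <- lapply(params, function(p)
      if (length(p) > 1L) p[rownames(v)] else p)
  out <- stats::dnorm(v, mean = params$mu1, sd = params$sd1, log = TRUE) -
    stats::dnorm(v, mean = params$mu2, sd = params$sd2, log = TRUE)
  dimnames(out) <- dimnames(v)
  out
}

#' Subnetwork activity: sum of member-gene log-likelihood ratios
#'
#' @param members Character vector of member gene identifiers (non-empty).
#' @param llr LLR matrix from [compute_llr()].
#' @return Per-sample numeric vector, named by sample.
#' @export
subnetwork_activity <- function(members, llr) {
  if (length(members) == 0L) stop("empty member set")
  missing <- setdiff(members, rownames(llr))
  if (length(missing) > 0L)
    stop("member gene(s) absent from LLR matrix: ",
         paste(missing, collapse = ", "))
  colSums(llr[members, , drop = FALSE])
}

#' Two-sample t-statistic of a per-sample score vector
#'
#' Computes `(mean_1 - mean_2) / sqrt(s1^2/n1 + s2^2/n2)` (Welch, the
#' default) or the pooled-variance Student form. A degenerate spread (both
#' class variances zero) returns 0 with a warning rather than NaN.
#'
#' @param values Per-sample numeric vector.
#' @param labels Phenotype labels in `{1, 2}`, same length.
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return A single t value; sign convention is class 1 minus class 2.
#' @export
t_statistic <- function(values, labels, var_equal = FALSE) {
  x1 <- values[labels == 1L]; x2 <- values[labels == 2L]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  se <- if (var_equal) {
    sp <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    sqrt(sp * (1 / n1 + 1 / n2))
  } else {
    sqrt(v1 / n1 + v2 / n2)
  }
  if (!is.finite(se) || se == 0) {
    warning("degenerate spread; t-statistic set to 0")
    return(0)
  }
  (mean(x1) - mean(x2)) / se
}

#' Per-gene t-statistics of the log-likelihood ratios
#'
#' The discriminative power of each gene is measured as the two-sample
#' t-statistic of its LLR row, `t_alpha(g_i)`. Vectorised over genes.
#'
#' @param llr LLR matrix from [compute_llr()].
#' @param labels Phenotype labels in `{1, 2}`.
#' @inheritParams t_statistic
#' @return Named per-gene numeric vector of (signed) t values.
#' @export
gene_t_scores <- function(llr, labels, var_equal = FALSE) {
  m1 <- llr[, labels == 1L, drop = FALSE]
  m2 <- llr[, labels == 2L, drop = FALSE]
  n1 <- ncol(m1); n2 <- ncol(m2)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  v1 <- rowSums((m1 - rowMeans(m1))^2) / (n1 - 1L)
  v2 <- rowSums((m2 - rowMeans(m2))^2) / (n2 - 1L)
  se <- if (var_equal) {
    sp <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    sqrt(sp * (1 / n1 + 1 / n2))
  } else {
    sqrt(v1 / n1 + v2 / n2)
  }
  t <- (rowMeans(m1) - rowMeans(m2)) / se
  t[!is.finite(t)] <- 0
  t
}
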