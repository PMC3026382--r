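#' Pearson correlation matrix of member-gene log-likelihood ratios
#'
#' Correlations are taken across all samples, both classes pooled. A gene
#' whose LLR row has zero variance gets correlation 0 against every other
#' gene and 1 on the diagonal, so downstream weight matrices stay finite.
#'
#' @param genes Ordered character vector of member gene identifiers.
#' @param llr LLR matrix from [compute_llr()].
#' @return An l x l correlation matrix with dimnames `genes`.
#' @export
llr_correlation <- function(genes, llr) {
  missing <- setdiff(genes, rownames(llr))
  if (length(missing) > 0L)
    stop("gene(s) absent from LLR matrix: ", paste(missing, collapse = ", "))
  m <- llr[genes, , drop = FALSE]
  P <- suppressWarnings(stats::cor(t(m)))
  P[!is.finite(P)] <- 0
  diag(P) <- 1
  dimnames(P) <- list(genes, genes)
  P
}

#' Correlation-derived weight matrix of a linear path
#'
#' `Sigma' = (P + (theta - 1) I) / (l - 1 + theta)`. At `theta = 0` the
#' effective weight of each gene is its average LLR correlation with the
#' other members; as `theta -> Inf` the matrix tends to the identity and the
#' path score reduces to the mean member |t|. For a single gene the matrix is
#' the scalar 1 at every theta.
#'
#' @param P Correlation matrix from [llr_correlation()].
#' @param theta Non-negative trade-off parameter; `Inf` returns the identity.
#' @return The l x l weight matrix.
#' @export
sigma_prime <- function(P, theta) {
  if (theta < 0) stop("'theta' must be non-negative")
  l <- nrow(P)
  if (l == 1L) return(matrix(1, 1L, 1L, dimnames = dimnames(P)))
  if (is.infinite(theta)) {
    out <- diag(l)
    dimnames(out) <- dimnames(P)
    return(out)
  }
  (P + diag(theta - 1, l)) / (l - 1 + theta)
}

#' Correlation-weighted discriminative score of a linear path
#'
#' The raw score is `s = |t|' Sigma' J` (J the all-ones column vector), i.e.
#' the sum of member |t| values weighted by their Sigma' row sums; the
#' reported score is the length-normalized `S = s / l^norm_exponent`. Path
#' ranking uses S.
#'
#' @param genes Ordered character vector of member gene identifiers.
#' @param t_alpha Named per-gene vector of t values (absolute values are
#'   taken internally) covering `genes`.
#' @param P Correlation matrix over `genes` (from [llr_correlation()]).
#' @param theta Non-negative trade-off parameter or `Inf`.
#' @param norm_exponent Length-normalization exponent, 1 (default) or 2.
#' @return List with elements `s` (raw) and `S` (normalized).
#' @export
path_score <- function(genes, t_alpha, P, theta, norm_exponent = 1L) {
  l <- length(genes)
  if (l == 0L) stop("empty path")
  if (nrow(P) != l || ncol(P) != l)
    stop("correlation matrix dimension does not match path length")
  tv <- abs(t_alpha[genes])
  if (anyNA(tv)) stop("t value missing for gene(s): ",
                      paste(genes[is.na(tv)], collapse = ", "))
  Sg <- sigma_prime(P, theta)
  s <- sum(tv * rowSums(Sg))
  list(s = s, S = s / l^norm_exponent)
}
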