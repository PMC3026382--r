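#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a randomly chosen class-1 sample outscores a randomly
#' chosen class-2 sample, with ties counting one half. Equivalent to an
#' exhaustive concordant-pair count.
#'
#' @param scores Per-sample numeric vector.
#' @param labels Phenotype labels in `{1, 2}`; class 1 is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 2L]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification error as a function of the true-positive rate
#'
#' For each target TPR, thresholds (predict class 1 when `score >= cutoff`)
#' whose sensitivity reaches at least that TPR are admissible; the smallest
#' overall misclassification rate among them is reported.
#'
#' @param scores Per-sample numeric vector (higher favours class 1).
#' @param labels Phenotype labels in `{1, 2}`.
#' @param tpr_grid Increasing vector of target TPR values in `(0, 1]`.
#' @return Data frame with columns `tpr` (target) and `error`.
#' @export
error_at_tpr <- function(scores, labels, tpr_grid = seq(0.1, 1, by = 0.1)) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 2L]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present")
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) mean(pos >= c), 0)
  err <- vapply(cuts, function(c)
    (sum(pos < c) + sum(neg >= c)) / length(scores), 0)
  out_err <- vapply(tpr_grid, function(target)
    min(err[tpr >= target]), 0)
  data.frame(tpr = tpr_grid, error = out_err)
}

#' Mean absolute t-score of the top-K markers
#'
#' Each marker's activity is its summed-LLR score on the evaluation data;
#' markers are ranked by absolute t and, for each K, the mean of the K
#' largest |t| values is reported. Supports cross-dataset evaluation by
#' passing an LLR matrix computed on a different dataset than the one the
#' markers were discovered on.
#'
#' @param markers A `marker_set`, a list of gene-identifier vectors, or a
#'   named list as returned by [read_markers_gmt()].
#' @param llr LLR matrix of the evaluation dataset.
#' @param labels Its phenotype labels.
#' @param K_values Integer vector of K values.
#' @param var_equal Passed to [t_statistic()].
#' @return Data frame with columns `K` and `mean_abs_t`.
#' @export
mean_topk_tscore <- function(markers, llr, labels,
                             K_values = c(10L, 20L, 30L, 40L, 50L),
                             var_equal = FALSE) {
  sets <- .marker_gene_sets(markers)
  tt <- sort(abs(marker_t_scores(sets, llr, labels, var_equal)$t),
             decreasing = TRUE)
  if (any(K_values > length(tt)))
    message("K clipped to the number of markers (", length(tt), ")")
  data.frame(
    K = K_values,
    mean_abs_t = vapply(K_values, function(K)
      mean(tt[seq_len(min(K, length(tt)))]), 0))
}

#' Per-marker activity t-scores
#'
#' @param markers As in [mean_topk_tscore()].
#' @param llr LLR matrix.
#' @param labels Phenotype labels.
#' @param var_equal Passed to [t_statistic()].
#' @return Data frame with columns `marker`, `size`, `t` (signed), ordered by
#'   decreasing |t| with ties broken by marker name.
#' @export
marker_t_scores <- function(markers, llr, labels, var_equal = FALSE) {
  sets <- .marker_gene_sets(markers)
  t <- vapply(sets, function(g)
    t_statistic(subnetwork_activity(g, llr), labels, var_equal), 0)
  df <- data.frame(marker = names(sets),
                   size = vapply(sets, length, 1L), t = t)
  df <- df[order(-abs(df$t), df$marker), ]
  rownames(df) <- NULL
  df
}

.marker_gene_sets <- function(markers) {
  sets <- if (inherits(markers, "marker_set"))
    lapply(markers$markers, function(m) m$members)
  else if (is.character(markers)) list(markers)
  else markers
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- sprintf("marker_%03d", seq_along(sets))
  sets
}

#' Single-gene baseline markers covered by a marker set
#'
#' Selects the `top_n` genes with the largest absolute LLR t-score among all
#' genes covered by the given markers, each as a singleton marker. Depends
#' only on the union of covered genes, not on marker order.
#'
#' @param markers As in [mean_topk_tscore()].
#' @param llr LLR matrix.
#' @param labels Phenotype labels.
#' @param top_n Number of genes to keep (all covered genes if fewer).
#' @param var_equal Passed to [gene_t_scores()].
#' @return Named list of singleton gene sets, ranked by decreasing |t|.
#' @export
gene_marker_baseline <- function(markers, llr, labels, top_n = 50L,
                                 var_equal = FALSE) {
  covered <- sort(unique(unlist(.marker_gene_sets(markers))))
  covered <- intersect(covered, rownames(llr))
  tt <- abs(gene_t_scores(llr[covered, , drop = FALSE], labels, var_equal))
  ord <- order(-tt, covered)
  keep <- covered[ord][seq_len(min(top_n, length(covered)))]
  stats::setNames(as.list(keep), keep)
}

#' Rank gene sets by mean member absolute t-score
#'
#' The averaging scheme used for pathway-style baselines: each set is scored
#' by the mean absolute LLR t-statistic over its members; sets are sorted by
#' decreasing score with ties broken by set name. Members absent from the
#' LLR matrix are skipped with a warning; a set with no surviving member
#' scores 0.
#'
#' @param gene_sets Named list of gene-identifier vectors.
#' @param llr LLR matrix.
#' @param labels Phenotype labels.
#' @param var_equal Passed to [gene_t_scores()].
#' @return Data frame with columns `set`, `size`, `score`, sorted.
#' @export
average_t_ranking <- function(gene_sets, llr, labels, var_equal = FALSE) {
  if (is.null(names(gene_sets)))
    names(gene_sets) <- sprintf("set_%03d", seq_along(gene_sets))
  tt <- abs(gene_t_scores(llr, labels, var_equal))
  score <- vapply(gene_sets, function(g) {
    present <- intersect(g, rownames(llr))
    if (length(present) < length(g))
      warning(length(g) - length(present), " member(s) of a set absent from",
              " the LLR matrix were skipped")
    if (length(present) == 0L) return(0)
    mean(tt[present])
  }, 0)
  df <- data.frame(set = names(gene_sets),
                   size = vapply(gene_sets, length, 1L), score = score)
  df <- df[order(-df$score, df$set), ]
  rownames(df) <- NULL
  df
}

#' Mean-expression activity of a gene set
#'
#' The averaging-style activity: each member gene is z-score normalized
#' (mean/SD taken over the reference samples, by default all samples) and the
#' per-sample mean over members is returned.
#'
#' @param members Character vector of gene identifiers.
#' @param expression An [expression_set()] or bare matrix.
#' @param ref_samples Optional character/integer index of columns used to
#'   estimate the normalization mean and SD (e.g. the training samples).
#' @return Per-sample numeric vector.
#' @export
mean_expression_activity <- function(members, expression, ref_samples = NULL) {
  v <- if (inherits(expression, "expression_set")) expression$values else expression
  if (length(members) == 0L) stop("empty member set")
  missing <- setdiff(members, rownames(v))
  if (length(missing) > 0L)
    stop("member gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  m <- v[members, , drop = FALSE]
  ref <- if (is.null(ref_samples)) m else m[, ref_samples, drop = FALSE]
  mu <- rowMeans(ref)
  sd <- apply(ref, 1L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  colMeans((m - mu) / sd)
}
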