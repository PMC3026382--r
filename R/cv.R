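# Nested cross-validation harness:
#   outer 10-fold split -> 1 test fold;
#   the 9 training folds are split 6 (marker-ranking set: parameter
#   estimation for ranking/fitting, logistic regression) / 3 (feature
#   selection set: forward selection by AUC);
#   all class-conditional parameters are re-estimated on the 9 training
#   folds of each split, so test samples never inform them.

.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (k in c(1L, 2L)) {
    idx <- sample(which(labels == k))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Nested cross-validation of marker-based classifiers
#'
#' Evaluates a fixed set of markers (discovery is not re-run per fold) with
#' repeated stratified 10-fold cross-validation. Within each split, marker
#' activities are computed with parameters estimated on the 9 training folds
#' only; markers are ranked by absolute activity t-statistic on the 6-fold
#' marker-ranking set; features are forward-selected, starting from the top
#' marker, keeping a candidate iff the logistic-regression AUC on the 3-fold
#' feature-selection set strictly increases; the selected model's AUC on the
#' held-out test fold is recorded. The feature pool is capped at the top
#' `max_features` markers.
#'
#' @param expression An [expression_set()].
#' @param markers A `marker_set`, named list of gene sets, or GMT list.
#' @param scheme Activity scheme: `"llr_sum"` (summed per-gene LLR under
#'   training-fold Gaussian fits) or `"mean_expression"` (mean of
#'   training-normalized member expression).
#' @param n_repeats Number of random 10-fold splits.
#' @param n_folds Number of outer folds (default 10).
#' @param n_rank_folds Training folds assigned to the marker-ranking set
#'   (default 6; the rest form the feature-selection set).
#' @param max_features Cap on the ranked feature pool (default 50).
#' @param var_equal Passed to the t-statistics.
#' @param tpr_grid TPR grid for the pooled error curve.
#' @return An object of class `"cv_result"`: data frame `folds` (one row per
#'   repeat x fold with the selected-feature count and test AUC), `mean_auc`,
#'   pooled `curve` (error vs TPR), and `fold_samples` recording which sample
#'   ids entered estimation/ranking/selection/test in every split.
#' @examples
#' sim <- simulate_study(n_nodes = 40, n_modules = 1, module_size = 4,
#'                       n1 = 30, n2 = 30, delta = 2, rho_target = 0.6,
#'                       seed = 7)
#' set.seed(7)
#' cv <- nested_cv(sim$expression, list(mod1 = sim$truth$modules[[1]]),
#'                 n_repeats = 2)
#' cv$mean_auc
#' @export
nested_cv <- function(expression, markers, scheme = c("llr_sum",
                                                      "mean_expression"),
                      n_repeats = 5L, n_folds = 10L, n_rank_folds = 6L,
                      max_features = 50L, var_equal = FALSE,
                      tpr_grid = seq(0.1, 1, by = 0.1)) {
  scheme <- match.arg(scheme)
  sets <- .marker_gene_sets(markers)
  labels <- expression$labels
  samples <- names(labels)
  if (min(table(labels)) < n_folds)
    stop("each class needs at least ", n_folds,
         " samples for stratified ", n_folds, "-fold splits")
  rows <- list(); fold_samples <- list()
  pooled_scores <- numeric(0); pooled_labels <- integer(0)
  for (rep_i in seq_len(n_repeats)) {
    fold <- .stratified_folds(labels, n_folds)
    for (f in seq_len(n_folds)) {
      train <- fold != f
      train_fold_ids <- setdiff(seq_len(n_folds), f)
      rank_folds <- sample(train_fold_ids, n_rank_folds)
      is_rank <- train & fold %in% rank_folds
      is_sel <- train & !fold %in% rank_folds

      act <- .marker_activities(expression, sets, scheme, train, var_equal)

      t_rank <- apply(act[, is_rank, drop = FALSE], 1L, t_statistic,
                      labels = labels[is_rank], var_equal = var_equal)
      ord <- order(-abs(t_rank), names(sets))
      pool <- ord[seq_len(min(max_features, length(ord)))]

      sel <- .forward_select(act, labels, is_rank, is_sel, pool)
      test_scores <- .logistic_scores(act, labels, is_rank, !train,
                                      sel$features)
      test_auc <- auc(test_scores, labels[!train])
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, fold = f, n_features = length(sel$features),
        selection_auc = sel$auc, test_auc = test_auc)
      fold_samples[[length(fold_samples) + 1L]] <- list(
        rep = rep_i, fold = f,
        estimation = samples[train], ranking = samples[is_rank],
        selection = samples[is_sel], test = samples[!train])
      pooled_scores <- c(pooled_scores, test_scores)
      pooled_labels <- c(pooled_labels, labels[!train])
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(
    folds = folds, mean_auc = mean(folds$test_auc),
    curve = error_at_tpr(pooled_scores, pooled_labels, tpr_grid),
    fold_samples = fold_samples, scheme = scheme,
    n_repeats = n_repeats, n_folds = n_folds
  ), class = "cv_result")
}

# markers x samples activity matrix under the chosen scheme; parameters are
# estimated on the training samples only
.marker_activities <- function(expression, sets, scheme, train, var_equal) {
  if (scheme == "llr_sum") {
    train_set <- expression_set(expression$values[, train, drop = FALSE],
                                expression$labels[train])
    params <- estimate_params(train_set)
    llr <- compute_llr(expression, params)
    act <- t(vapply(sets, subnetwork_activity, numeric(ncol(llr)),
                    llr = llr))
  } else {
    act <- t(vapply(sets, mean_expression_activity,
                    numeric(ncol(expression$values)),
                    expression = expression, ref_samples = which(train)))
  }
  rownames(act) <- names(sets)
  act
}

.fit_logistic <- function(act, labels, fit_on, features) {
  df <- as.data.frame(t(act[features, , drop = FALSE]))
  colnames(df) <- sprintf("f%d", seq_along(features))
  df$y <- as.integer(labels == 1L)
  suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                              data = df[fit_on, , drop = FALSE]))
}

.logistic_scores <- function(act, labels, fit_on, score_on, features) {
  fit <- .fit_logistic(act, labels, fit_on, features)
  df <- as.data.frame(t(act[features, , drop = FALSE]))
  colnames(df) <- sprintf("f%d", seq_along(features))
  unname(suppressWarnings(
    stats::predict(fit, newdata = df[score_on, , drop = FALSE],
                   type = "response")))
}

.forward_select <- function(act, labels, is_rank, is_sel, pool) {
  features <- pool[1L]
  best <- auc(.logistic_scores(act, labels, is_rank, is_sel, features),
              labels[is_sel])
  for (j in pool[-1L]) {
    cand <- c(features, j)
    a <- auc(.logistic_scores(act, labels, is_rank, is_sel, cand),
             labels[is_sel])
    if (a > best) { features <- cand; best <- a }
  }
  list(features = features, auc = best)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Nested CV (%d repeats x %d folds, %s activity)\n",
              x$n_repeats, x$n_folds, x$scheme))
  cat(sprintf("  mean test AUC = %.4f (sd %.4f over %d fold evaluations)\n",
              x$mean_auc, stats::sd(x$folds$test_auc), nrow(x$folds)))
  cat(sprintf("  mean features selected = %.1f\n", mean(x$folds$n_features)))
  invisible(x)
}
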