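# File-level run orchestration: each run_* function reads standard-format
# inputs, calls the in-memory API, writes its outputs into an output
# directory together with a JSON manifest (config echo, input hashes,
# package version, seed, timestamps, output list). The inst/cli dispatcher
# is a thin shell over these functions.

.write_manifest <- function(out_dir, command, config, inputs, outputs, seed) {
  manifest <- list(
    tool = "pathmarker",
    version = as.character(utils::packageVersion("pathmarker")),
    command = command,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list(),
    outputs = unname(unlist(outputs))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Simulate a planted-module study and write it to disk
#'
#' Writes `expression.tsv`, `labels.tsv`, `network.tsv` (edge list) and
#' `truth.json` into `out_dir`, plus a run manifest.
#'
#' @inheritParams simulate_study
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list from [simulate_study()].
#' @export
run_simulate <- function(out_dir, n_nodes = 300L, n_modules = 3L,
                         module_size = 6L, n1 = 100L, n2 = 100L,
                         delta = 2, rho_target = 0.5, noise_sd = 1,
                         flip_prob = 0.25, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(n_nodes, n_modules, module_size, n1, n2,
                        delta = delta, rho_target = rho_target,
                        noise_sd = noise_sd, flip_prob = flip_prob,
                        seed = seed)
  expr_path <- file.path(out_dir, "expression.tsv")
  labels_path <- file.path(out_dir, "labels.tsv")
  net_path <- file.path(out_dir, "network.tsv")
  truth_path <- file.path(out_dir, "truth.json")
  write_expression(sim$expression, expr_path, labels_path)
  write_network(sim$network, net_path)
  jsonlite::write_json(
    list(modules = sim$truth$modules, delta = sim$truth$delta,
         rho_target = sim$truth$rho_target,
         background = sim$truth$background,
         signs = as.list(attr(sim$expression, "signs"))),
    truth_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(out_dir, "simulate",
                  list(n_nodes = n_nodes, n_modules = n_modules,
                       module_size = module_size, n1 = n1, n2 = n2,
                       delta = delta, rho_target = rho_target,
                       noise_sd = noise_sd, flip_prob = flip_prob),
                  list(), list(expr_path, labels_path, net_path, truth_path),
                  seed)
  invisible(sim)
}

#' Run marker discovery on files and write GMT + provenance
#'
#' Reads an expression matrix, labels and a network, runs
#' [identify_markers()], and writes `markers.gmt`, a per-marker provenance
#' JSON (source paths and the greedy accept/reject trace with R values) and
#' a manifest into `out_dir`.
#'
#' @param expression_path,labels_path,network_path Input files (see
#'   [read_expression()], [read_network()]).
#' @param out_dir Output directory.
#' @param config A [marker_config()].
#' @param dialect Network file dialect.
#' @param seed Integer seed (discovery is deterministic, but recorded).
#' @return Invisibly, the fitted `marker_set`.
#' @export
run_identify <- function(expression_path, labels_path, network_path,
                         out_dir, config = marker_config(),
                         dialect = "edge_list", seed = config$rng_seed) {
  for (p in c(expression_path, labels_path, network_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  expression <- read_expression(expression_path, labels_path)
  network <- read_network(network_path, dialect = dialect)
  fit <- identify_markers(expression, network, config)
  if (length(fit$markers) == 0L) stop("no marker could be identified")
  gmt_path <- file.path(out_dir, "markers.gmt")
  write_markers_gmt(fit, gmt_path)
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    lapply(seq_along(fit$markers), function(i) {
      m <- fit$markers[[i]]
      list(marker = sprintf("marker_%03d", i), members = m$members,
           R = m$R,
           source_paths = lapply(m$source_paths, function(p)
             list(genes = p$genes, S = p$S)),
           trace = m$trace)
    }),
    prov_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  .write_manifest(out_dir, "identify", unclass(config),
                  list(expression_path, labels_path, network_path),
                  list(gmt_path, prov_path), seed)
  invisible(fit)
}

#' Score markers from a GMT file on a dataset
#'
#' Writes `marker_scores.tsv` (per-marker signed activity t-score, sorted by
#' |t|) and `topk_summary.tsv` (mean absolute t of the top K markers,
#' K = 10, 20, 30, 40, 50 clipped to the pool) plus a manifest.
#'
#' @inheritParams run_identify
#' @param markers_path GMT file of markers.
#' @param K_values K grid for the top-K summary.
#' @param var_equal Use the pooled-variance t-statistic.
#' @return Invisibly, the per-marker score data frame.
#' @export
run_score <- function(expression_path, labels_path, markers_path, out_dir,
                      K_values = c(10L, 20L, 30L, 40L, 50L),
                      var_equal = FALSE, seed = 1L) {
  for (p in c(expression_path, labels_path, markers_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expression <- read_expression(expression_path, labels_path)
  sets <- read_markers_gmt(markers_path)
  sets <- .drop_unmeasured(sets, rownames(expression$values))
  params <- estimate_params(expression)
  llr <- compute_llr(expression, params)
  scores <- marker_t_scores(sets, llr, expression$labels, var_equal)
  K_values <- K_values[K_values <= length(sets)]
  if (length(K_values) == 0L) K_values <- length(sets)
  topk <- mean_topk_tscore(sets, llr, expression$labels, K_values, var_equal)
  score_path <- file.path(out_dir, "marker_scores.tsv")
  topk_path <- file.path(out_dir, "topk_summary.tsv")
  utils::write.table(scores, score_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(topk, topk_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_manifest(out_dir, "score", list(K_values = K_values),
                  list(expression_path, labels_path, markers_path),
                  list(score_path, topk_path), seed)
  invisible(scores)
}

#' Cross-validate GMT markers on a dataset
#'
#' Runs [nested_cv()] with the chosen activity scheme on markers read from a
#' GMT file (which may have been discovered on a different dataset,
#' supporting cross-dataset evaluation). Writes `cv_folds.tsv`,
#' `error_curve.tsv` and `cv_summary.json` plus a manifest.
#'
#' @inheritParams run_score
#' @param scheme `"llr_sum"` or `"mean_expression"`.
#' @param n_repeats Number of random 10-fold splits.
#' @return Invisibly, the `cv_result`.
#' @export
run_evaluate <- function(expression_path, labels_path, markers_path, out_dir,
                         scheme = "llr_sum", n_repeats = 5L,
                         var_equal = FALSE, seed = 1L) {
  for (p in c(expression_path, labels_path, markers_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  expression <- read_expression(expression_path, labels_path)
  sets <- read_markers_gmt(markers_path)
  sets <- .drop_unmeasured(sets, rownames(expression$values))
  cv <- nested_cv(expression, sets, scheme = scheme, n_repeats = n_repeats,
                  var_equal = var_equal)
  folds_path <- file.path(out_dir, "cv_folds.tsv")
  curve_path <- file.path(out_dir, "error_curve.tsv")
  summary_path <- file.path(out_dir, "cv_summary.json")
  utils::write.table(cv$folds, folds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cv$curve, curve_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ci <- stats::quantile(cv$folds$test_auc, c(0.025, 0.975), names = FALSE)
  jsonlite::write_json(
    list(scheme = scheme, n_repeats = n_repeats, mean_auc = cv$mean_auc,
         auc_q025 = ci[1L], auc_q975 = ci[2L],
         mean_features = mean(cv$folds$n_features)),
    summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(out_dir, "evaluate",
                  list(scheme = scheme, n_repeats = n_repeats),
                  list(expression_path, labels_path, markers_path),
                  list(folds_path, curve_path, summary_path), seed)
  invisible(cv)
}

# drop marker genes absent from the measured genes; drop emptied markers
.drop_unmeasured <- function(sets, measured) {
  out <- lapply(names(sets), function(nm) {
    kept <- intersect(sets[[nm]], measured)
    if (length(kept) < length(sets[[nm]]))
      warning("marker '", nm, "': ", length(sets[[nm]]) - length(kept),
              " gene(s) absent from the expression data dropped")
    kept
  })
  names(out) <- names(sets)
  out[vapply(out, length, 1L) > 0L]
}
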