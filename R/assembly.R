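#' Greedily merge overlapping top paths into one subnetwork
#'
#' Starting from the top-ranked path, the remaining paths are scanned once in
#' rank order. A path sharing at least one gene with the current subnetwork
#' is tentatively unioned in; the union is kept iff the absolute t-statistic
#' of its summed-LLR activity strictly exceeds `(1 + epsilon)` times the
#' current value. Paths disjoint from the subnetwork at their turn are
#' skipped. An optional multi-pass mode rescans the pool until no merge is
#' accepted.
#'
#' @param paths List of path records (from [collect_top_paths()]), sorted by
#'   decreasing score.
#' @param llr LLR matrix.
#' @param labels Phenotype labels in `{1, 2}`.
#' @param epsilon Required relative improvement of a merge.
#' @param var_equal Passed to [t_statistic()].
#' @param multi_pass Rescan until convergence instead of one ordered pass.
#' @return A list of class `"subnetwork"` with `members`, `source_paths`,
#'   `activity`, `R`, and a merge `trace` (one row per considered path).
#' @export
greedy_combine <- function(paths, llr, labels, epsilon = 0.01,
                           var_equal = FALSE, multi_pass = FALSE) {
  if (length(paths) == 0L) stop("empty path list")
  power <- function(members) {
    act <- subnetwork_activity(members, llr)
    abs(t_statistic(act, labels, var_equal = var_equal))
  }
  members <- paths[[1L]]$genes
  source_paths <- list(paths[[1L]])
  R <- power(members)
  trace <- data.frame(path = integer(0), action = character(0),
                      R_before = numeric(0), R_after = numeric(0))
  scan <- function() {
    changed <- FALSE
    for (i in seq_along(paths)[-1L]) {
      pg <- paths[[i]]$genes
      if (length(intersect(pg, members)) == 0L) {
        trace[nrow(trace) + 1L, ] <<- list(i, "disjoint", R, NA_real_)
        next
      }
      cand <- union(members, pg)
      if (length(cand) == length(members)) {
        trace[nrow(trace) + 1L, ] <<- list(i, "subsumed", R, NA_real_)
        next
      }
      R_new <- power(cand)
      if (R_new > (1 + epsilon) * R) {
        trace[nrow(trace) + 1L, ] <<- list(i, "accepted", R, R_new)
        members <<- cand
        source_paths[[length(source_paths) + 1L]] <<- paths[[i]]
        R <<- R_new
        changed <- TRUE
      } else {
        trace[nrow(trace) + 1L, ] <<- list(i, "rejected", R, R_new)
      }
    }
    changed
  }
  repeat {
    changed <- scan()
    if (!multi_pass || !changed) break
  }
  structure(list(members = members, source_paths = source_paths,
                 activity = subnetwork_activity(members, llr),
                 R = R, trace = trace),
            class = "subnetwork")
}

#' Remove a subnetwork's footprint from the search network
#'
#' All edges incident to the subnetwork's member genes are removed, leaving
#' the members isolated; the node set is unchanged. Pruning is idempotent.
#'
#' @param network An undirected igraph.
#' @param subnetwork A `"subnetwork"` or any object with a `members` element,
#'   or a plain character vector of gene identifiers.
#' @return The pruned igraph.
#' @export
prune_network <- function(network, subnetwork) {
  members <- if (is.character(subnetwork)) subnetwork else subnetwork$members
  hit <- intersect(members, igraph::V(network)$name)
  if (length(hit) == 0L) return(network)
  inc <- igraph::incident_edges(network, hit)
  eids <- unique(unlist(lapply(inc, igraph::as_ids)))
  if (length(eids) == 0L) return(network)
  igraph::delete_edges(network, eids)
}

#' Identify non-overlapping discriminative subnetwork markers
#'
#' The main fitting function. Gene expression is overlaid on a
#' protein-protein interaction network restricted to the measured genes;
#' per-gene log-likelihood ratios and their t-statistics are computed once;
#' then, up to `k` times: a dynamic-programming beam search finds the
#' top-scoring linear paths, the top `m` admissible-length paths are greedily
#' merged into one subnetwork maximizing the absolute t-statistic of its
#' summed-LLR activity, and the subnetwork is cut out of the network before
#' the next round. The loop stops early (with a warning) when no admissible
#' path remains.
#'
#' @param expression An [expression_set()] (or the result of
#'   [read_expression()]).
#' @param network Undirected igraph PPI network; identifiers must share the
#'   expression gene namespace.
#' @param config A [marker_config()].
#' @return An object of class `"marker_set"`: a list with `markers` (each a
#'   `"subnetwork"`), the per-gene `t_alpha` vector, the Gaussian `params`,
#'   `config`, and the matched `call`. Markers are in discovery order and
#'   pairwise disjoint.
#' @seealso [summary.marker_set()], [predict.marker_set()],
#'   [plot.marker_set()], [write_markers_gmt()]
#' @examples
#' sim <- simulate_study(n_nodes = 60, n_modules = 2, module_size = 4,
#'                       n1 = 20, n2 = 20, delta = 2, rho_target = 0.6,
#'                       seed = 1)
#' cfg <- marker_config(marker_count = 2, length_range = c(3, 5),
#'                      max_path_length = 5)
#' fit <- identify_markers(sim$expression, sim$network, cfg)
#' fit
#' @export
identify_markers <- function(expression, network, config = marker_config()) {
  cl <- match.call()
  net <- induce_network(network, expression)
  params <- estimate_params(expression)
  llr <- compute_llr(expression, params)
  t_alpha <- gene_t_scores(llr, expression$labels,
                           var_equal = config$var_equal)
  markers <- list()
  used <- character(0)
  for (iter in seq_len(config$marker_count)) {
    tab <- finalize_scores(dp_search(net, t_alpha, llr, config))
    pool <- tryCatch(collect_top_paths(tab), error = function(e) NULL)
    if (!is.null(pool) && length(used) > 0L)
      pool <- Filter(function(p) length(intersect(p$genes, used)) == 0L, pool)
    if (is.null(pool) || length(pool) == 0L) {
      warning("path pool exhausted after ", length(markers),
              " marker(s); stopping early")
      break
    }
    sn <- greedy_combine(pool, llr, expression$labels,
                         epsilon = config$epsilon,
                         var_equal = config$var_equal,
                         multi_pass = config$multi_pass)
    markers[[length(markers) + 1L]] <- sn
    used <- c(used, sn$members)
    net <- prune_network(net, sn)
  }
  structure(list(markers = markers, t_alpha = t_alpha, params = params,
                 config = config, labels = expression$labels, call = cl),
            class = "marker_set")
}
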