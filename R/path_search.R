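# Beam-style dynamic programming over simple linear paths.
#
# The path score is not additive in the path (the correlation weights couple
# all members), so no score recurrence is assumed: every candidate extension
# is re-scored exactly. The table cell (v, l) keeps the top-M candidates by
# raw score s; exactness holds whenever M is at least the number of simple
# paths of length l ending at v, because every simple path arises by
# extending a simple path at a neighbour.

# raw score of a path given |t| vector and full correlation matrix (indices)
.raw_score <- function(idx, tv, P, theta) {
  l <- length(idx)
  st <- sum(tv[idx])
  if (l == 1L) return(st)
  if (is.infinite(theta)) return(st)
  Psub <- P[idx, idx, drop = FALSE]
  (sum(tv[idx] * rowSums(Psub)) + (theta - 1) * st) / (l - 1 + theta)
}

#' Dynamic-programming search for top discriminative linear paths
#'
#' For every node v and every length `l <= L` (length counts nodes), maintains
#' the `M` highest raw-scoring simple paths that end at v, growing length-l
#' candidates by appending v to the length-(l-1) paths stored at its
#' neighbours. Ties in the raw score are broken by the lexicographic order of
#' the path's gene-identifier tuple, which makes the search deterministic.
#'
#' @param network Undirected igraph whose vertex names all appear among the
#'   rows of `llr`; vertices missing from `llr` are skipped with a message.
#' @param t_alpha Named per-gene t vector (see [gene_t_scores()]); absolute
#'   values are used.
#' @param llr LLR matrix; member correlations are computed from it once.
#' @param config A [marker_config()].
#' @return An object of class `"path_table"`: a list with `nodes` (character),
#'   `table` (per node, per length: `paths` as integer-index lists and raw
#'   scores `s`), the correlation matrix `P`, `t_abs`, and the config.
#' @export
dp_search <- function(network, t_alpha, llr, config = marker_config()) {
  nodes <- igraph::V(network)$name
  known <- nodes %in% rownames(llr) & nodes %in% names(t_alpha)
  if (!all(known)) {
    message(sum(!known), " network node(s) without expression data skipped")
    network <- igraph::induced_subgraph(network, nodes[known])
    nodes <- igraph::V(network)$name
  }
  n <- length(nodes)
  L <- config$max_path_length
  M <- config$beam_width
  theta <- config$theta
  tv <- abs(t_alpha[nodes])
  P <- llr_correlation(nodes, llr)
  adj <- lapply(igraph::as_adj_list(network, mode = "all"), as.integer)

  empty_cell <- list(paths = list(), s = numeric(0))
  tab <- vector("list", n)
  for (v in seq_len(n)) {
    tab[[v]] <- rep(list(empty_cell), L)
    tab[[v]][[1L]] <- list(paths = list(v), s = unname(tv[v]))
  }
  if (L >= 2L && n > 0L) {
    for (l in 2:L) {
      new_cells <- vector("list", n)
      for (v in seq_len(n)) {
        cand <- list()
        for (u in adj[[v]]) {
          prev <- tab[[u]][[l - 1L]]$paths
          if (length(prev) == 0L) next
          for (p in prev) if (!v %in% p) cand[[length(cand) + 1L]] <- c(p, v)
        }
        if (length(cand) == 0L) { new_cells[[v]] <- empty_cell; next }
        s <- vapply(cand, .raw_score, 0, tv = tv, P = P, theta = theta)
        key <- vapply(cand, function(p) paste(nodes[p], collapse = "\x01"), "")
        ord <- order(-s, key)[seq_len(min(M, length(cand)))]
        new_cells[[v]] <- list(paths = cand[ord], s = s[ord])
      }
      for (v in seq_len(n)) tab[[v]][[l]] <- new_cells[[v]]
    }
  }
  structure(list(nodes = nodes, table = tab, P = P, t_abs = tv,
                 config = config),
            class = "path_table")
}

#' Attach length-normalized scores to every stored path
#'
#' Converts each cell's raw scores s into the reported `S = s / l^exponent`
#' using the configured normalization exponent.
#'
#' @param table A `"path_table"` from [dp_search()].
#' @return The table with a per-cell `S` vector added.
#' @export
finalize_scores <- function(table) {
  ex <- table$config$norm_exponent
  for (v in seq_along(table$table))
    for (l in seq_along(table$table[[v]]))
      table$table[[v]][[l]]$S <- table$table[[v]][[l]]$s / l^ex
  table
}

#' Pool, deduplicate and rank the top stored paths
#'
#' Pools every stored path whose node count lies in `length_range`,
#' removes duplicates (a path and its reversal count once; the score is
#' orientation-free), and returns the top `m` by normalized score S.
#'
#' @param table A finalized `"path_table"`.
#' @param m Number of paths to return.
#' @param length_range Closed integer range of admissible node counts.
#' @return A list of path records `list(genes, s, S)` sorted by decreasing S.
#' @export
collect_top_paths <- function(table, m = table$config$top_paths,
                              length_range = table$config$length_range) {
  nodes <- table$nodes
  pool_paths <- list(); pool_s <- numeric(0); pool_S <- numeric(0)
  for (v in seq_along(table$table)) {
    for (l in seq_along(table$table[[v]])) {
      if (l < length_range[1L] || l > length_range[2L]) next
      cell <- table$table[[v]][[l]]
      if (length(cell$paths) == 0L) next
      if (is.null(cell$S))
        cell$S <- cell$s / l^table$config$norm_exponent
      pool_paths <- c(pool_paths, cell$paths)
      pool_s <- c(pool_s, cell$s)
      pool_S <- c(pool_S, cell$S)
    }
  }
  if (length(pool_paths) == 0L)
    stop("no stored path has a length inside [", length_range[1L], ", ",
         length_range[2L], "]; relax 'length_range' or increase ",
         "'max_path_length'")
  canon <- vapply(pool_paths, function(p) {
    fwd <- paste(nodes[p], collapse = "\x01")
    rev <- paste(nodes[base::rev(p)], collapse = "\x01")
    if (fwd <= rev) fwd else rev
  }, "")
  keep <- !duplicated(canon)
  pool_paths <- pool_paths[keep]; pool_s <- pool_s[keep]
  pool_S <- pool_S[keep]; canon <- canon[keep]
  ord <- order(-pool_S, canon)[seq_len(min(m, length(pool_paths)))]
  lapply(ord, function(i)
    list(genes = nodes[pool_paths[[i]]], s = pool_s[i], S = pool_S[i]))
}
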