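# oracle-driven checks of the beam DP

# best stored path per (node, length) must equal exhaustive enumeration when
# the beam is wide enough to be lossless
check_dp_against_enumeration <- function(seed, n, p, L, theta) {
  set.seed(seed)
  g <- generate_network(n, p = p)
  es <- random_expression(n, 10, 10, seed = seed + 1000)
  rownames(es$values) <- igraph::V(g)$name
  params <- estimate_params(es)
  llr <- compute_llr(es, params)
  t_alpha <- gene_t_scores(llr, es$labels)
  cfg <- marker_config(theta = theta, max_path_length = L,
                       beam_width = 100000L)
  tab <- dp_search(g, t_alpha, llr, cfg)
  adj <- adj_list(g)
  P <- llr_correlation(igraph::V(g)$name, llr)
  buckets <- oracle_enumerate_paths(adj, L)
  ids <- igraph::V(g)$name
  for (v in seq_len(igraph::vcount(g))) {
    for (l in seq_len(L)) {
      enum <- buckets[[v]][[l]]
      cell <- tab$table[[v]][[l]]
      expect_equal(length(cell$paths), length(enum),
                   info = sprintf("seed %d cell (%d, %d)", seed, v, l))
      if (length(enum) == 0L) next
      s_enum <- vapply(enum, function(pp)
        oracle_raw_score(ids[pp], t_alpha, P, theta), 0)
      best_set <- enum[s_enum >= max(s_enum) - 1e-9 * max(1, abs(max(s_enum)))]
      expect_true(any(vapply(best_set, identical, TRUE, cell$paths[[1L]])),
                  info = sprintf("seed %d best path (%d, %d)", seed, v, l))
      expect_equal(cell$s[[1L]], max(s_enum), tolerance = 1e-12)
    }
  }
}

test_that("a two-node graph yields the single candidate with its exact score", {
  g <- igraph::graph_from_edgelist(cbind("a", "b"), directed = FALSE)
  llr <- rbind(a = c(1, 2, -1, -2.5), b = c(0.5, 1.5, -0.6, -1.2))
  colnames(llr) <- paste0("s", 1:4)
  labels <- c(1L, 1L, 2L, 2L)
  t_alpha <- gene_t_scores(llr, labels)
  cfg <- marker_config(theta = 8, max_path_length = 2, beam_width = 1)
  tab <- dp_search(g, t_alpha, llr, cfg)
  b_idx <- which(tab$nodes == "b")
  cell <- tab$table[[b_idx]][[2]]
  expect_equal(tab$nodes[cell$paths[[1]]], c("a", "b"))
  P <- llr_correlation(c("a", "b"), llr)
  expect_equal(cell$s[1],
               path_score(c("a", "b"), t_alpha, P, 8)$s)
})

test_that("isolated nodes store only their singleton path", {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, 3)
  igraph::V(g)$name <- c("a", "b", "c")
  g <- igraph::add_edges(g, c("a", "b"))
  es <- random_expression(3, 5, 5, seed = 2)
  rownames(es$values) <- c("a", "b", "c")
  llr <- compute_llr(es, estimate_params(es))
  t_alpha <- gene_t_scores(llr, es$labels)
  tab <- dp_search(g, t_alpha, llr,
                   marker_config(max_path_length = 3, beam_width = 5))
  c_idx <- which(tab$nodes == "c")
  expect_equal(length(tab$table[[c_idx]][[1]]$paths), 1L)
  expect_equal(length(tab$table[[c_idx]][[2]]$paths), 0L)
  expect_equal(length(tab$table[[c_idx]][[3]]$paths), 0L)
})

test_that("the lossless beam reproduces exhaustive enumeration", {
  for (seed in 1:6)
    check_dp_against_enumeration(seed, n = 9, p = 0.35, L = 4, theta = 8)
  check_dp_against_enumeration(7, n = 8, p = 0.4, L = 4, theta = Inf)
  check_dp_against_enumeration(8, n = 8, p = 0.4, L = 4, theta = 0)
})

test_that("every stored path is simple, adjacent, sorted, and within the beam", {
  sim <- std_sim()
  params <- estimate_params(sim$expression)
  llr <- compute_llr(sim$expression, params)
  t_alpha <- gene_t_scores(llr, sim$expression$labels)
  cfg <- marker_config(max_path_length = 5, beam_width = 7)
  net <- induce_network(sim$network, sim$expression)
  tab <- dp_search(net, t_alpha, llr, cfg)
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  for (v in seq_along(tab$table)) {
    for (l in seq_along(tab$table[[v]])) {
      cell <- tab$table[[v]][[l]]
      expect_lte(length(cell$paths), 7L)
      if (length(cell$paths) == 0L) next
      expect_true(all(diff(cell$s) <= 1e-12))
      for (p in cell$paths) {
        expect_equal(length(p), l)
        expect_equal(p[length(p)], v)
        expect_equal(anyDuplicated(p), 0L)
        if (l > 1L)
          expect_true(all(A[cbind(p[-l], p[-1L])] == 1))
      }
    }
  }
})

test_that("widening the beam never lowers the best stored score", {
  sim <- std_sim()
  llr <- compute_llr(sim$expression, estimate_params(sim$expression))
  t_alpha <- gene_t_scores(llr, sim$expression$labels)
  net <- induce_network(sim$network, sim$expression)
  best_of <- function(M) {
    tab <- dp_search(net, t_alpha, llr,
                     marker_config(max_path_length = 4, beam_width = M))
    vapply(tab$table, function(cells)
      vapply(cells, function(c) if (length(c$s)) c$s[1] else -Inf, 0),
      numeric(4))
  }
  b2 <- best_of(2); b10 <- best_of(10)
  # emptiness of a cell does not depend on the beam width
  expect_identical(is.finite(b2), is.finite(b10))
  both <- is.finite(b2) & is.finite(b10)
  expect_true(all(b10[both] - b2[both] >= -1e-12))
})

test_that("search is deterministic and ties break lexicographically", {
  sim <- std_sim()
  llr <- compute_llr(sim$expression, estimate_params(sim$expression))
  t_alpha <- gene_t_scores(llr, sim$expression$labels)
  net <- induce_network(sim$network, sim$expression)
  cfg <- marker_config(max_path_length = 4, beam_width = 5)
  t1 <- dp_search(net, t_alpha, llr, cfg)
  t2 <- dp_search(net, t_alpha, llr, cfg)
  expect_identical(t1$table, t2$table)
})

test_that("finalize_scores applies the configured normalization exponent", {
  g <- igraph::graph_from_edgelist(cbind(c("a", "b", "c"), c("b", "c", "d")),
                                   directed = FALSE)
  es <- random_expression(4, 5, 5, seed = 4)
  rownames(es$values) <- c("a", "b", "c", "d")
  llr <- compute_llr(es, estimate_params(es))
  t_alpha <- gene_t_scores(llr, es$labels)
  for (ex in c(1L, 2L)) {
    cfg <- marker_config(max_path_length = 4, beam_width = 3,
                         norm_exponent = ex)
    tab <- finalize_scores(dp_search(g, t_alpha, llr, cfg))
    for (v in seq_along(tab$table))
      for (l in seq_along(tab$table[[v]])) {
        cell <- tab$table[[v]][[l]]
        if (length(cell$s))
          expect_equal(cell$S, cell$s / l^ex)
      }
  }
})

test_that("collect_top_paths pools, deduplicates reversals and sorts by S", {
  g <- igraph::graph_from_edgelist(cbind(c("a", "b", "c"), c("b", "c", "d")),
                                   directed = FALSE)
  es <- random_expression(4, 6, 6, seed = 14)
  rownames(es$values) <- c("a", "b", "c", "d")
  llr <- compute_llr(es, estimate_params(es))
  t_alpha <- gene_t_scores(llr, es$labels)
  cfg <- marker_config(max_path_length = 4, beam_width = 10,
                       length_range = c(2L, 4L), top_paths = 100L)
  tab <- finalize_scores(dp_search(g, t_alpha, llr, cfg))
  top <- collect_top_paths(tab)
  # strictly admissible lengths, no reversal duplicates, descending S
  lens <- vapply(top, function(p) length(p$genes), 1L)
  expect_true(all(lens >= 2L & lens <= 4L))
  keys <- vapply(top, function(p) {
    fwd <- paste(p$genes, collapse = "|")
    bwd <- paste(rev(p$genes), collapse = "|")
    min(fwd, bwd)
  }, "")
  expect_equal(anyDuplicated(keys), 0L)
  S <- vapply(top, function(p) p$S, 0)
  expect_true(all(diff(S) <= 1e-12))
  # the full path a-b-c-d is found exactly once though stored at both ends
  expect_equal(sum(keys == "a|b|c|d"), 1L)
  # m smaller than pool truncates
  expect_equal(length(collect_top_paths(tab, m = 2)), 2L)
  # empty admissible window errors with guidance
  cfg2 <- marker_config(max_path_length = 2, length_range = c(5L, 8L))
  tab2 <- finalize_scores(dp_search(g, t_alpha, llr, cfg2))
  expect_error(collect_top_paths(tab2), "length")
})
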