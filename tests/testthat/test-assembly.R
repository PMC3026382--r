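# hand-built LLR fixture with known merge behaviour: genes a-c carry a
# moderate coherent signal, d a strong one, z pure noise
merge_fixture <- function() {
  set.seed(71)
  n <- 30
  labels <- rep(c(1L, 2L), each = n)
  cvec <- ifelse(labels == 1L, 1, -1)
  mk <- function(strength) strength * cvec + rnorm(2 * n, sd = 1)
  llr <- rbind(a = mk(0.8), b = mk(0.8), c = mk(0.8), d = mk(3), z = rnorm(2 * n))
  colnames(llr) <- sprintf("s%02d", seq_len(2 * n))
  list(llr = llr, labels = labels)
}

test_that("greedy merge follows the overlap and improvement rules", {
  fx <- merge_fixture()
  llr <- fx$llr; labels <- fx$labels

  # single path -> subnetwork is that path with R = |t| of its activity
  p1 <- list(genes = c("a", "b", "c"), s = 1, S = 1)
  sn <- greedy_combine(list(p1), llr, labels)
  expect_setequal(sn$members, c("a", "b", "c"))
  expect_equal(sn$R, abs(oracle_t(subnetwork_activity(c("a", "b", "c"), llr),
                                  labels)))

  # disjoint second path is skipped untouched
  p_dis <- list(genes = c("d", "z"), s = 1, S = 1)
  sn2 <- greedy_combine(list(p1, p_dis), llr, labels)
  expect_setequal(sn2$members, c("a", "b", "c"))
  expect_equal(sn2$trace$action, "disjoint")

  # overlapping path bringing in the strong gene: merge accepted, and the
  # improvement verified by recomputing both t-statistics independently
  p3 <- list(genes = c("c", "d"), s = 1, S = 1)
  sn3 <- greedy_combine(list(p1, p3), llr, labels, epsilon = 0.01)
  expect_setequal(sn3$members, c("a", "b", "c", "d"))
  R_before <- abs(oracle_t(subnetwork_activity(c("a", "b", "c"), llr), labels))
  R_after <- abs(oracle_t(subnetwork_activity(c("a", "b", "c", "d"), llr),
                          labels))
  expect_equal(sn3$R, R_after)
  expect_gt(R_after, (1 + 0.01) * R_before)
  expect_equal(sn3$trace$action, "accepted")

  expect_error(greedy_combine(list(), llr, labels), "empty")
})

test_that("the greedy decision always matches the printed (1 + eps) rule", {
  fx <- merge_fixture()
  llr <- fx$llr; labels <- fx$labels
  # scan many two-path configurations; for each, the accept/reject decision
  # must equal an independent recomputation of the rule
  pool <- list(c("a", "b"), c("b", "c"), c("c", "z"), c("a", "z"),
               c("b", "d"), c("c", "d", "z"))
  for (second in pool) {
    p1 <- list(genes = c("a", "b", "c"), s = 1, S = 1)
    p2 <- list(genes = second, s = 1, S = 1)
    sn <- greedy_combine(list(p1, p2), llr, labels, epsilon = 0.01)
    base <- c("a", "b", "c")
    if (length(intersect(second, base)) == 0L) {
      expect_setequal(sn$members, base)
      expect_equal(sn$trace$action, "disjoint")
      next
    }
    uni <- union(base, second)
    R0 <- abs(oracle_t(subnetwork_activity(base, llr), labels))
    if (length(uni) == length(base)) {
      expect_equal(sn$trace$action, "subsumed")
      next
    }
    R1 <- abs(oracle_t(subnetwork_activity(uni, llr), labels))
    if (R1 > 1.01 * R0) {
      expect_equal(sn$trace$action, "accepted")
      expect_setequal(sn$members, uni)
      expect_equal(sn$R, R1)
    } else {
      expect_equal(sn$trace$action, "rejected")
      expect_setequal(sn$members, base)
      expect_equal(sn$R, R0)
    }
  }
})

test_that("pruning removes exactly the incident edges and is idempotent", {
  g <- igraph::graph_from_edgelist(cbind(c("a", "b"), c("b", "c")),
                                   directed = FALSE)
  sn <- list(members = "b")
  g2 <- prune_network(g, sn)
  expect_equal(igraph::ecount(g2), 0L)
  expect_equal(igraph::vcount(g2), 3L)
  # disjoint subnetwork leaves the network unchanged
  g3 <- prune_network(g, list(members = "zz"))
  expect_equal(igraph::ecount(g3), 2L)
  # idempotence
  g4 <- prune_network(g2, sn)
  expect_equal(igraph::ecount(g4), 0L)
  # character-vector input also accepted
  expect_equal(igraph::ecount(prune_network(g, "b")), 0L)
})

test_that("identify_markers returns disjoint markers covered by the network", {
  sim <- std_sim()
  fit <- identify_markers(sim$expression, sim$network, std_cfg())
  expect_s3_class(fit, "marker_set")
  expect_lte(length(fit$markers), 2L)
  members <- lapply(fit$markers, `[[`, "members")
  # pairwise disjoint
  for (i in seq_along(members)) for (j in seq_len(i - 1L))
    expect_equal(length(intersect(members[[i]], members[[j]])), 0L)
  # conservation: only genes in the induced network
  net_nodes <- igraph::V(induce_network(sim$network, sim$expression))$name
  expect_true(all(unlist(members) %in% net_nodes))
  # R recomputes from current members
  llr <- compute_llr(sim$expression, estimate_params(sim$expression))
  for (m in fit$markers)
    expect_equal(m$R, abs(t_statistic(subnetwork_activity(m$members, llr),
                                      sim$expression$labels)))
})

test_that("k = 1 yields exactly one marker", {
  sim <- std_sim()
  fit <- identify_markers(sim$expression, sim$network,
                          std_cfg(marker_count = 1))
  expect_equal(length(fit$markers), 1L)
})

test_that("marker discovery is byte-reproducible through GMT output", {
  sim <- std_sim()
  f1 <- tempfile(); f2 <- tempfile()
  write_markers_gmt(identify_markers(sim$expression, sim$network, std_cfg()),
                    f1)
  write_markers_gmt(identify_markers(sim$expression, sim$network, std_cfg()),
                    f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an exhausted path pool stops discovery early with a warning", {
  sim <- std_sim()
  # absurdly large k on a small network
  cfg <- std_cfg(marker_count = 30)
  expect_warning(fit <- identify_markers(sim$expression, sim$network, cfg),
                 "exhausted")
  expect_lt(length(fit$markers), 30L)
  expect_gte(length(fit$markers), 1L)
})

test_that("summary, predict and plot methods work on a fit", {
  sim <- std_sim()
  fit <- identify_markers(sim$expression, sim$network, std_cfg())
  s <- summary(fit)
  expect_equal(nrow(s), length(fit$markers))
  expect_true(all(s$size >= 1))
  act <- predict(fit, sim$expression)
  expect_equal(dim(act), c(length(fit$markers), ncol(sim$expression$values)))
  # activities of marker 1 separate the classes
  expect_gt(abs(t_statistic(act[1, ], sim$expression$labels)), 3)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
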