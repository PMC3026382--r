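# Shared fixtures, all built in code at test time.

# small deterministic expression set: 4 genes x 8 samples, two clearly
# separated genes (one up in class 1, one down), two null genes
tiny_expression <- function() {
  set.seed(11)
  vals <- rbind(
    up   = c(3, 3.5, 2.8, 3.2, -3, -2.7, -3.3, -3.1),
    down = c(-2, -2.4, -1.8, -2.2, 2, 2.3, 1.9, 2.1),
    null1 = rnorm(8, sd = 0.5),
    null2 = rnorm(8, sd = 0.5)
  )
  colnames(vals) <- paste0("s", 1:8)
  expression_set(vals, c(1, 1, 1, 1, 2, 2, 2, 2))
}

# line graph a-b-c-d over the tiny expression genes
tiny_network <- function() {
  igraph::graph_from_edgelist(
    cbind(c("up", "down", "null1"), c("down", "null1", "null2")),
    directed = FALSE)
}

# the standard planted-module study used by assembly / evaluation tests:
# small enough to run in seconds, strong enough that signal genes dominate
std_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(n_nodes = 120, n_modules = 2, module_size = 5,
                               n1 = 60, n2 = 60, delta = 2, rho_target = 0.6,
                               seed = 101)
    cache
  }
})

std_cfg <- function(...) {
  args <- list(marker_count = 2L, length_range = c(4L, 6L),
               max_path_length = 6L)
  over <- list(...)
  args[names(over)] <- over
  do.call(marker_config, args)
}

random_expression <- function(n_genes, n1, n2, seed) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * (n1 + n2)), nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%03d", seq_len(n1 + n2))))
  expression_set(vals, rep(c(1L, 2L), c(n1, n2)))
}
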