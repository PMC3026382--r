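#' Generate a random undirected network
#'
#' Erdos-Renyi G(n, p) or Barabasi-Albert preferential attachment, with node
#' identifiers `g0001`, `g0002`, ...
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param model `"erdos_renyi"` or `"barabasi_albert"`.
#' @param p Edge probability (Erdos-Renyi). Default gives mean degree 4.
#' @param m_attach Edges added per new node (Barabasi-Albert).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return An undirected simple igraph.
#' @export
generate_network <- function(n_nodes,
                             model = c("erdos_renyi", "barabasi_albert"),
                             p = min(1, 4 / (n_nodes - 1)), m_attach = 2L,
                             seed = NULL) {
  model <- match.arg(model)
  if (n_nodes < 2L) stop("'n_nodes' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  g <- if (model == "erdos_renyi") {
    if (!is.numeric(p) || p < 0 || p > 1) stop("'p' must lie in [0, 1]")
    igraph::sample_gnp(n_nodes, p, directed = FALSE)
  } else {
    if (as.integer(m_attach) < 1L) stop("'m_attach' must be >= 1")
    igraph::as_undirected(igraph::sample_pa(n_nodes, m = m_attach,
                                            directed = FALSE))
  }
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("g%04d", seq_len(n_nodes))
  g
}

#' Plant disjoint connected modules in a network
#'
#' Selects `n_modules` pairwise-disjoint connected subgraphs of
#' `module_size` nodes by random-walk growth from random seeds. If growth
#' stalls (no unused neighbour remains), an edge to a random unused node is
#' added and reported, so the requested packing always succeeds when enough
#' nodes exist.
#'
#' @param network Undirected igraph.
#' @param n_modules,module_size Module count and size.
#' @param delta Per-module class-mean shift, in units of the within-class
#'   noise SD; recycled to `n_modules`.
#' @param rho_target Desired within-module LLR correlation; recycled.
#' @param seed Optional integer seed.
#' @return A list of class `"planted_truth"`: `modules` (list of gene-id
#'   vectors), `delta`, `rho_target`, the (possibly augmented) `network`,
#'   `background` (unplanted gene ids), and `seed`.
#' @export
plant_modules <- function(network, n_modules, module_size, delta = 2,
                          rho_target = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(network)
  if (n < n_modules * module_size)
    stop("network too small to pack ", n_modules, " modules of size ",
         module_size)
  ids <- igraph::V(network)$name
  used <- character(0)
  modules <- vector("list", n_modules)
  added <- 0L
  for (q in seq_len(n_modules)) {
    mod <- sample(setdiff(ids, used), 1L)
    while (length(mod) < module_size) {
      nb <- setdiff(ids[unlist(lapply(mod, function(v)
        as.integer(igraph::neighbors(network, v))))], c(mod, used))
      if (length(nb) == 0L) {
        free <- setdiff(ids, c(mod, used))
        if (length(free) == 0L)
          stop("cannot grow module ", q, ": no free node left")
        new <- sample(free, 1L)
        network <- igraph::add_edges(
          network, c(sample(mod, 1L), new))
        added <- added + 1L
        nb <- new
      }
      mod <- c(mod, if (length(nb) == 1L) nb else sample(nb, 1L))
    }
    modules[[q]] <- sort(mod)
    used <- c(used, mod)
  }
  if (added > 0L) message("added ", added, " edge(s) to keep modules connected")
  structure(list(
    modules = modules,
    delta = rep_len(delta, n_modules),
    rho_target = rep_len(rho_target, n_modules),
    network = network,
    background = setdiff(ids, used),
    seed = seed
  ), class = "planted_truth")
}

# latent loading b_q so that the pooled LLR correlation of two same-sign
# module genes hits rho_target:
#   rho = (delta^2/4 + b^2) / (delta^2/4 + b^2 + noise_sd^2)
.latent_loading <- function(delta, rho_target, noise_sd) {
  floor_rho <- (delta^2 / 4) / (delta^2 / 4 + noise_sd^2)
  if (rho_target >= 1 || rho_target < floor_rho - 1e-12)
    stop(sprintf(
      "rho_target = %.3f unattainable with delta = %g, noise_sd = %g; ",
      rho_target, delta, noise_sd),
      sprintf("feasible range is [%.3f, 1)", floor_rho))
  b2 <- rho_target * noise_sd^2 / (1 - rho_target) - delta^2 / 4
  sqrt(max(b2, 0))
}

#' Generate two-phenotype expression data with planted modules
#'
#' Background genes are `Normal(0, noise_sd)` in both classes. A planted gene
#' g of module q takes `s_g * (delta_q / 2) * c + b_q * z + Normal(0,
#' noise_sd)`, where `c` is +1 for class 1 and -1 for class 2, `s_g` is a
#' per-gene sign (allowing oppositely regulated members), and `z` is a
#' per-sample latent factor shared within the module whose loading `b_q` is
#' chosen so that the pooled LLR correlation of same-sign member pairs hits
#' `rho_target`.
#'
#' @param truth A `"planted_truth"` from [plant_modules()].
#' @param n1,n2 Samples per class (>= 3 each).
#' @param noise_sd Within-class noise SD.
#' @param flip_prob Probability that a planted gene is down-regulated in
#'   class 1 (`s_g = -1`).
#' @param seed Optional integer seed.
#' @return An [expression_set()] with attribute `"signs"` recording each
#'   planted gene's orientation.
#' @export
generate_expression <- function(truth, n1, n2, noise_sd = 1,
                                flip_prob = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n1 < 3L || n2 < 3L) stop("need at least 3 samples per class")
  ids <- igraph::V(truth$network)$name
  n <- n1 + n2
  labels <- rep(c(1L, 2L), c(n1, n2))
  cvec <- ifelse(labels == 1L, 1, -1)
  vals <- matrix(stats::rnorm(length(ids) * n, sd = noise_sd),
                 nrow = length(ids),
                 dimnames = list(ids, sprintf("s%04d", seq_len(n))))
  signs <- stats::setNames(numeric(0), character(0))
  for (q in seq_along(truth$modules)) {
    delta <- truth$delta[q]
    b <- .latent_loading(delta, truth$rho_target[q], noise_sd)
    z <- stats::rnorm(n)
    for (g in truth$modules[[q]]) {
      s_g <- if (stats::runif(1) < flip_prob) -1 else 1
      signs[g] <- s_g
      vals[g, ] <- vals[g, ] + s_g * (delta / 2) * cvec + b * z
    }
  }
  out <- expression_set(vals, labels)
  attr(out, "signs") <- signs
  out
}

#' Simulate a full planted-module study
#'
#' Convenience wrapper: random network, planted connected modules, and
#' two-phenotype expression data, reproducible from one seed.
#'
#' @param n_nodes Network size.
#' @param n_modules,module_size Planted module count and size.
#' @param n1,n2 Samples per class.
#' @param delta Class-mean shift of planted genes (noise-SD units).
#' @param rho_target Within-module LLR correlation target.
#' @param noise_sd Within-class noise SD.
#' @param flip_prob Down-regulation probability per planted gene.
#' @param model,p Passed to [generate_network()].
#' @param seed Integer seed for the whole simulation.
#' @return List with `network` (igraph, including any edges added to keep
#'   modules connected), `truth` (`"planted_truth"`), and `expression`
#'   ([expression_set()]).
#' @export
simulate_study <- function(n_nodes, n_modules, module_size, n1, n2,
                           delta = 2, rho_target = 0.5, noise_sd = 1,
                           flip_prob = 0.25,
                           model = "erdos_renyi",
                           p = min(1, 4 / (n_nodes - 1)), seed = 1L) {
  set.seed(seed)
  net <- generate_network(n_nodes, model = model, p = p)
  truth <- plant_modules(net, n_modules, module_size,
                         delta = delta, rho_target = rho_target)
  expression <- generate_expression(truth, n1 = n1, n2 = n2,
                                    noise_sd = noise_sd,
                                    flip_prob = flip_prob)
  list(network = truth$network, truth = truth, expression = expression)
}
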