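# Independent oracles, deliberately written from the definitions rather than
# by calling the implementation under test.

# textbook Welch / pooled t from the closed-form expressions
oracle_t <- function(x, labels, var_equal = FALSE) {
  x1 <- x[labels == 1L]; x2 <- x[labels == 2L]
  n1 <- length(x1); n2 <- length(x2)
  if (var_equal) {
    sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
    (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    (mean(x1) - mean(x2)) / sqrt(var(x1) / n1 + var(x2) / n2)
  }
}

# hand-expanded Gaussian log-density difference
oracle_llr <- function(x, mu1, sd1, mu2, sd2) {
  log(sd2 / sd1) - (x - mu1)^2 / (2 * sd1^2) + (x - mu2)^2 / (2 * sd2^2)
}

# literal matrix-algebra path score: |t|' Sigma' J with Sigma' built from
# its definition
oracle_raw_score <- function(ids, t_alpha, P, theta) {
  l <- length(ids)
  tv <- matrix(abs(t_alpha[ids]), ncol = 1)
  Sg <- if (l == 1L) matrix(1, 1, 1)
        else if (is.infinite(theta)) diag(l)
        else (P[ids, ids, drop = FALSE] + (theta - 1) * diag(l)) / (l - 1 + theta)
  drop(t(tv) %*% Sg %*% matrix(1, l, 1))
}

# exhaustive enumeration of all simple paths with <= L nodes, bucketed by
# (terminal node, node count); returns list[[v]][[l]] = list of integer paths
oracle_enumerate_paths <- function(adj, L) {
  n <- length(adj)
  buckets <- lapply(seq_len(n), function(v) lapply(seq_len(L), function(l) list()))
  grow <- function(path) {
    v <- path[length(path)]
    l <- length(path)
    buckets[[v]][[l]][[length(buckets[[v]][[l]]) + 1L]] <<- path
    if (l == L) return(invisible())
    for (u in adj[[v]]) if (!u %in% path) grow(c(path, u))
  }
  for (v in seq_len(n)) grow(v)
  buckets
}

# exhaustive concordant-pair AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 2L]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

adj_list <- function(g) lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
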