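# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (dense matrices, exhaustive
# enumeration, long-hand formulas) and never calls the code paths it checks.

# Build a knn_graph-shaped object from explicit edge vectors.
graph_from_edges <- function(i, j, w = rep(1, length(i)), n = max(c(i, j))) {
  edges <- data.frame(i = pmin(i, j), j = pmax(i, j), w = w)
  loops <- edges$i == edges$j
  deg <- numeric(n)
  for (r in seq_len(nrow(edges))) {
    if (loops[r]) {
      deg[edges$i[r]] <- deg[edges$i[r]] + 2 * edges$w[r]
    } else {
      deg[edges$i[r]] <- deg[edges$i[r]] + edges$w[r]
      deg[edges$j[r]] <- deg[edges$j[r]] + edges$w[r]
    }
  }
  structure(list(n = n, edges = edges, degree = deg, m = sum(edges$w),
                 ids = as.character(seq_len(n))),
            class = "knn_graph")
}

two_triangles <- function() {
  graph_from_edges(c(1, 2, 1, 4, 5, 4), c(2, 3, 3, 5, 6, 6))
}

two_k4_bridge <- function() {
  cmb <- utils::combn(4, 2)
  graph_from_edges(c(cmb[1, ], cmb[1, ] + 4, 1),
                   c(cmb[2, ], cmb[2, ] + 4, 5))
}

# Dense-matrix modularity: Q = (1/2m) sum_ij (A_ij - g k_i k_j / 2m) d(ci,cj).
# Self-loop weight w sits on the diagonal as 2w (so rowSums gives the degree).
dense_modularity <- function(graph, memb, gamma = 1) {
  n <- graph$n
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[r]; j <- graph$edges$j[r]; w <- graph$edges$w[r]
    if (i == j) A[i, i] <- A[i, i] + 2 * w
    else { A[i, j] <- A[i, j] + w; A[j, i] <- A[j, i] + w }
  }
  k <- rowSums(A)
  m2 <- sum(k)
  same <- outer(memb, memb, "==")
  sum((A - gamma * outer(k, k) / m2) * same) / m2
}

# All set partitions of 1..n as membership vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    at <- length(prefix) + 1L
    if (at > n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (c in seq_len(maxc + 1L)) rec(c(prefix, c), max(maxc, c))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum-modularity search (the Louvain oracle).
best_partition_bruteforce <- function(graph, gamma = 1) {
  parts <- all_partitions(graph$n)
  qs <- vapply(parts, function(p) dense_modularity(graph, p, gamma), 0)
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

random_small_graph <- function(n) {
  repeat {
    cmb <- utils::combn(n, 2)
    keep <- stats::runif(ncol(cmb)) < 0.55
    if (sum(keep) >= n - 1) {
      return(graph_from_edges(cmb[1, keep], cmb[2, keep],
                              stats::runif(sum(keep), 0.2, 1), n = n))
    }
  }
}

# Long-hand cluster-robust sandwich: naive loops, explicit solve().
sandwich_oracle <- function(X, y, cluster) {
  beta <- solve(t(X) %*% X) %*% t(X) %*% y
  u <- y - X %*% beta
  groups <- unique(cluster)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in groups) {
    rows <- which(cluster == g)
    sg <- t(X[rows, , drop = FALSE]) %*% u[rows]
    meat <- meat + sg %*% t(sg)
  }
  n <- nrow(X); p <- ncol(X); G <- length(groups)
  adj <- G / (G - 1) * (n - 1) / (n - p)
  bread <- solve(t(X) %*% X)
  adj * bread %*% meat %*% bread
}

# Small cohort config used in many tests.
test_config <- function(n = 200, seed = 42, ...) {
  cohort_config(n_subjects = n, seed = seed, ...)
}
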