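#' @title Louvain community detection
#' @description Multi-level greedy modularity optimization on the weighted
#'   K-NN network: repeated single-node moves (phase 1) alternating with
#'   community aggregation into super-node graphs (phase 2), until no move
#'   improves modularity. Written against the standard weighted
#'   Newman-Girvan modularity
#'   \deqn{Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \gamma\frac{k_i k_j}{2m}\right]\delta(c_i, c_j).}
#' @name louvain
NULL

# Internal: normalize a graph argument to list(n, edges(i,j,w), degree, m).
# Self-loop rows (i == j) are allowed: weight counts once in m and in the
# community-internal weight, twice in the node's degree.
as_louvain_graph <- function(graph) {
  if (inherits(graph, "knn_graph")) return(graph)
  stopifnot(is.list(graph), !is.null(graph$edges))
  graph
}

graph_degree <- function(n, edges) {
  loops <- edges$i == edges$j
  deg <- numeric(n)
  agg <- rowsum(c(edges$w[!loops], edges$w[!loops], 2 * edges$w[loops]),
                c(edges$i[!loops], edges$j[!loops], edges$i[loops]))
  deg[as.integer(rownames(agg))] <- agg[, 1]
  deg
}

#' Modularity of a partition
#'
#' @param graph a `knn_graph` (or list with `n` and `edges` columns
#'   `i`, `j`, `w`; rows with `i == j` are self-loops).
#' @param membership community label per node (any atomic vector), or a
#'   `louvain_partition`.
#' @param gamma resolution parameter (default 1).
#' @return the modularity Q in `[-1, 1]`.
#' @export
modularity_q <- function(graph, membership, gamma = 1) {
  g <- as_louvain_graph(graph)
  if (inherits(membership, "louvain_partition")) {
    membership <- membership$membership
  }
  if (length(membership) != g$n) stopf("membership must cover all %d nodes", g$n)
  if (nrow(g$edges) == 0 || sum(g$edges$w) <= 0) {
    stopf("modularity undefined on a graph with no edge weight")
  }
  m <- sum(g$edges$w)
  deg <- graph_degree(g$n, g$edges)
  comm <- as.integer(factor(membership))
  within <- comm[g$edges$i] == comm[g$edges$j]
  w_in <- rowsum(g$edges$w[within], comm[g$edges$i][within])
  sig_tot <- rowsum(deg, comm)
  sum(w_in) / m - gamma * sum((sig_tot / (2 * m))^2)
}

# Phase 1: greedy local moving on one level's graph. Returns the community
# assignment (1-based, not contiguous) after no single-node move improves
# modularity by more than tol. Sweep order is the caller-supplied permutation.
local_moving <- function(n, adj_idx, adj_w, deg, m, gamma, order, tol,
                         init = NULL) {
  comm <- init %||% seq_len(n)
  sig_tot <- numeric(n)
  agg0 <- rowsum(deg, comm)
  sig_tot[as.integer(rownames(agg0))] <- agg0[, 1]
  repeat {
    moved <- FALSE
    for (i in order) {
      nb <- adj_idx[[i]]
      if (!length(nb)) next
      c_old <- comm[i]
      wts <- adj_w[[i]]
      # weight from i to each neighbouring community (self excluded by adj)
      links <- rowsum(wts, comm[nb])
      cand <- as.integer(rownames(links))
      sig_tot[c_old] <- sig_tot[c_old] - deg[i]
      k_to <- links[, 1]
      if (!(c_old %in% cand)) { cand <- c(cand, c_old); k_to <- c(k_to, 0) }
      ord2 <- order(cand)                       # ascending id => deterministic ties
      cand <- cand[ord2]; k_to <- k_to[ord2]
      gain <- k_to - gamma * deg[i] * sig_tot[cand] / (2 * m)
      stay <- gain[cand == c_old]
      best <- which.max(gain)
      if (gain[best] > stay + tol && cand[best] != c_old) {
        comm[i] <- cand[best]
        sig_tot[cand[best]] <- sig_tot[cand[best]] + deg[i]
        moved <- TRUE
      } else {
        sig_tot[c_old] <- sig_tot[c_old] + deg[i]
      }
    }
    if (!moved) break
  }
  comm
}

# Phase 2: collapse communities into super-nodes; intra-community weight
# becomes a self-loop (counted once), inter-community weights are summed.
aggregate_graph <- function(edges, comm) {
  ci <- comm[edges$i]; cj <- comm[edges$j]
  a <- pmin(ci, cj); b <- pmax(ci, cj)
  agg <- rowsum(edges$w, paste(a, b))
  ij <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]), w = agg[, 1])
}

build_adjacency <- function(n, edges) {
  loops <- edges$i == edges$j
  ii <- c(edges$i[!loops], edges$j[!loops])
  jj <- c(edges$j[!loops], edges$i[!loops])
  ww <- c(edges$w[!loops], edges$w[!loops])
  list(idx = split(jj, factor(ii, levels = seq_len(n))),
       w = split(ww, factor(ii, levels = seq_len(n))))
}

louvain_once <- function(g, gamma, seed, max_passes, tol, init = NULL) {
  n0 <- g$n
  assign_orig <- seq_len(n0)      # node -> community of the *current* level
  edges <- g$edges
  n <- n0
  trace <- numeric(0)
  q_prev <- -Inf
  for (pass in seq_len(max_passes)) {
    deg <- graph_degree(n, edges)
    m <- sum(edges$w)
    adj <- build_adjacency(n, edges)
    ord <- with_seed(sub_seed(seed, paste0("sweep", pass)), sample.int(n))
    comm <- local_moving(n, adj$idx, adj$w, deg, m, gamma, ord, tol,
                         init = if (pass == 1) init)
    comm <- as.integer(factor(comm))           # contiguous 1..k
    assign_orig <- comm[assign_orig]
    q <- modularity_q(list(n = n, edges = edges), comm, gamma)
    trace <- c(trace, q)
    if (max(comm) == n || q <= q_prev + tol) break
    q_prev <- q
    edges <- aggregate_graph(edges, comm)
    n <- max(comm)
  }
  # multilevel refinement: single-node moves on the original graph starting
  # from the coarse solution, escaping optima locked in by aggregation
  deg0 <- graph_degree(n0, g$edges)
  adj0 <- build_adjacency(n0, g$edges)
  ord0 <- with_seed(sub_seed(seed, "refine"), sample.int(n0))
  refined <- local_moving(n0, adj0$idx, adj0$w, deg0, sum(g$edges$w),
                          gamma, ord0, tol, init = assign_orig)
  refined <- as.integer(factor(refined))
  q_ref <- modularity_q(g, refined, gamma)
  if (q_ref > trace[length(trace)] + tol) {
    assign_orig <- refined
    trace <- c(trace, q_ref)
  }
  list(membership = assign_orig, trace = trace, q = trace[length(trace)])
}

#' Louvain community detection
#'
#' Runs multi-level modularity optimization, restarting from `n_restarts`
#' seeded node-visit orders and keeping the partition with the highest
#' modularity (sweep order is Louvain's only stochastic element; restarts
#' reduce its chance of settling in a poor local optimum). Fully
#' deterministic given `seed`.
#'
#' @param graph a `knn_graph`.
#' @param gamma resolution (default 1).
#' @param seed integer seed controlling the node-visit orders.
#' @param max_passes cap on level passes (default 50).
#' @param tol minimal modularity gain counted as an improvement (default 1e-7).
#' @param n_restarts independent restarts, best-Q wins (default 5).
#' @return a `louvain_partition`: list with `membership` (0-based contiguous
#'   community per node, named by subject id), `q`, `n_communities`, `sizes`,
#'   `trace` (per-pass Q of the winning restart), `gamma`, `seed`.
#' @export
louvain <- function(graph, gamma = 1, seed = 1L, max_passes = 50,
                    tol = 1e-7, n_restarts = 5) {
  g <- as_louvain_graph(graph)
  if (gamma <= 0 || tol <= 0) stopf("gamma and tol must be positive")
  if (nrow(g$edges) == 0 || sum(g$edges$w) <= 0) {
    stopf("cannot run Louvain on a graph with no edge weight")
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- louvain_once(g, gamma, sub_seed(seed, paste0("restart", r)),
                        max_passes, tol)
    if (is.null(best) || res$q > best$q + 1e-12) best <- res
    if (r > 1) {
      # a second candidate started from a random coarse partition: escapes
      # singleton-start local optima that sweep-order diversity cannot
      init <- with_seed(sub_seed(seed, paste0("randinit", r)), {
        as.integer(factor(sample.int(max(2L, g$n %/% 2L), g$n, replace = TRUE)))
      })
      res2 <- louvain_once(g, gamma, sub_seed(seed, paste0("restartR", r)),
                           max_passes, tol, init = init)
      if (res2$q > best$q + 1e-12) best <- res2
    }
  }
  memb <- as.integer(factor(best$membership)) - 1L
  ids <- g$ids %||% as.character(seq_len(g$n))
  structure(list(membership = stats::setNames(memb, ids),
                 q = best$q,
                 n_communities = max(memb) + 1L,
                 sizes = as.integer(table(memb)),
                 trace = best$trace,
                 gamma = gamma, seed = seed),
            class = "louvain_partition")
}

#' @export
print.louvain_partition <- function(x, ...) {
  cat(sprintf("louvain_partition: %d communities, Q = %.4f (gamma %.2f)\n",
              x$n_communities, x$q, x$gamma))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Relabel communities in decreasing size order
#'
#' Community 0 becomes the largest; ties are broken by the smallest member
#' index. Idempotent.
#'
#' @param partition a `louvain_partition`.
#' @return the partition with relabelled `membership` and reordered `sizes`.
#' @export
relabel_by_size <- function(partition) {
  stopifnot(inherits(partition, "louvain_partition"))
  memb <- partition$membership
  ids <- sort(unique(memb))
  size <- sapply(ids, function(c) sum(memb == c))
  first <- sapply(ids, function(c) which(memb == c)[1])
  new_order <- ids[order(-size, first)]
  remap <- match(memb, new_order) - 1L
  partition$membership <- stats::setNames(as.integer(remap), names(memb))
  partition$sizes <- as.integer(size[order(-size, first)])
  partition
}

#' Write a partition as CSV
#'
#' @param partition a `louvain_partition`.
#' @param path CSV path.
#' @param label_prefix prefix for display labels (e.g. `"FA"` or `"S"`).
#' @return the written data.frame, invisibly.
#' @export
write_partition <- function(partition, path, label_prefix = "C") {
  out <- data.frame(subject_id = names(partition$membership),
                    cluster_id = unname(partition$membership),
                    cluster_label = paste0(label_prefix,
                                           unname(partition$membership)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
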