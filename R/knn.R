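#' @title K-nearest-neighbour network construction
#' @description Exact K-NN search over the subject-by-intake matrix, cosine
#'   edge weighting and symmetrization into an undirected weighted graph for
#'   community detection.
#' @name knn
NULL

#' Exact K-nearest-neighbour search
#'
#' Full pairwise Euclidean distances (exact search; cohort sizes here make
#' approximate indexing pointless), ties broken by smaller subject index so
#' results are deterministic.
#'
#' @param matrix numeric matrix, one row per subject (an `intake_matrix`).
#' @param k neighbours per subject, `1 <= k < nrow(matrix)`.
#' @return integer matrix n x k; row i lists the row indices of the k nearest
#'   other subjects, nearest first.
#' @export
knn_search <- function(matrix, k = 20) {
  m <- unclass(matrix)
  n <- nrow(m)
  if (anyNA(m)) stopf("intake matrix contains missing values")
  if (k < 1 || k >= n) stopf("need 1 <= k < n (k=%d, n=%d)", k, n)
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    # order() with the index as tie-breaker: smaller index wins on equal distance
    out[i, ] <- order(d[i, ], seq_len(n))[seq_len(k)]
  }
  out
}

#' Cosine similarity of two intake vectors
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return `sum(u*v) / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stopf("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Build the weighted K-NN network
#'
#' Links every pair of subjects that are K-nearest neighbours of one another
#' in at least one direction (`symmetrization = "union"`, default) or in both
#' (`"mutual"`), and weights each retained edge by the cosine similarity of
#' the two subjects' intake vectors. Edges with weight `<= min_similarity`
#' are dropped (Louvain modularity assumes non-negative weights). An
#' SNN-style alternative weights edges by the Jaccard overlap of the two
#' subjects' neighbour lists instead.
#'
#' @param matrix the `intake_matrix` used for the search.
#' @param k neighbours per subject (default 20).
#' @param symmetrization `"union"` or `"mutual"`.
#' @param min_similarity drop edges with weight at or below this (default 0).
#' @param weighting `"cosine"` (default) or `"snn_jaccard"`.
#' @param neighbors optional precomputed [knn_search()] result for `matrix`.
#' @return a `knn_graph`: list with `n`, `edges` (data.frame `i`, `j`, `w`
#'   with `i < j`), `degree` (weighted), `m` (total edge weight) and `ids`
#'   (rownames of `matrix`).
#' @export
build_knn_graph <- function(matrix, k = 20,
                            symmetrization = c("union", "mutual"),
                            min_similarity = 0,
                            weighting = c("cosine", "snn_jaccard"),
                            neighbors = NULL) {
  symmetrization <- match.arg(symmetrization)
  weighting <- match.arg(weighting)
  m0 <- unclass(matrix)
  n <- nrow(m0)
  if (is.null(neighbors)) neighbors <- knn_search(m0, k)
  k <- ncol(neighbors)

  i <- rep(seq_len(n), each = k)
  j <- as.integer(t(neighbors))
  a <- pmin(i, j); b <- pmax(i, j)
  key <- (a - 1) * n + b
  if (symmetrization == "union") {
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
  } else {
    dup <- duplicated(key)           # pair seen twice = linked in both directions
    a <- a[dup]; b <- b[dup]
  }

  if (weighting == "cosine") {
    norms <- sqrt(rowSums(m0^2))
    if (any(norms == 0)) stopf("zero intake vector(s): row %s",
                               paste(which(norms == 0), collapse = ", "))
    w <- rowSums(m0[a, , drop = FALSE] * m0[b, , drop = FALSE]) /
      (norms[a] * norms[b])
  } else {
    nb <- lapply(seq_len(n), function(x) neighbors[x, ])
    w <- mapply(function(x, y) {
      inter <- length(intersect(nb[[x]], nb[[y]]))
      inter / (2 * k - inter)
    }, a, b)
  }

  keep <- w > min_similarity
  edges <- data.frame(i = a[keep], j = b[keep], w = w[keep])
  degree <- numeric(n)
  agg <- rowsum(c(edges$w, edges$w), c(edges$i, edges$j))
  degree[as.integer(rownames(agg))] <- agg[, 1]
  structure(list(n = n, edges = edges, degree = degree,
                 m = sum(edges$w), ids = rownames(m0) %||% as.character(seq_len(n))),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("knn_graph: %d nodes, %d edges, total weight %.3f\n",
              x$n, nrow(x$edges), x$m))
  invisible(x)
}

#' Export a graph as an edge-list data.frame / CSV
#'
#' @param graph a `knn_graph`.
#' @param path optional CSV path; when given the edge list is written there.
#' @return data.frame `node_i`, `node_j`, `weight` (subject ids, not indices).
#' @export
graph_edgelist <- function(graph, path = NULL) {
  out <- data.frame(node_i = graph$ids[graph$edges$i],
                    node_j = graph$ids[graph$edges$j],
                    weight = graph$edges$w)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
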