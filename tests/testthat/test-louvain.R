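test_that("modularity closed forms hold exactly", {
  g <- two_triangles()
  expect_equal(modularity_q(g, rep(1, 6)), 0, tolerance = 1e-14)
  expect_equal(modularity_q(g, c(1, 1, 1, 2, 2, 2)), 0.5, tolerance = 1e-14)
  # singleton partition: Q = -sum (k_i / 2m)^2
  expect_equal(modularity_q(g, 1:6),
               -sum((g$degree / (2 * g$m))^2), tolerance = 1e-14)
  # agreement with the dense-matrix oracle on arbitrary partitions
  set.seed(4)
  for (i in 1:20) {
    memb <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_q(g, memb), dense_modularity(g, memb),
                 tolerance = 1e-12)
  }
  expect_error(modularity_q(g, rep(1, 3)), "cover all")
})

test_that("louvain recovers canonical small structures at the brute-force optimum", {
  g <- two_triangles()
  p <- louvain(g, seed = 1)
  expect_equal(p$n_communities, 2L)
  expect_equal(p$q, 0.5, tolerance = 1e-12)
  expect_equal(ari(p$membership, c(0, 0, 0, 1, 1, 1)), 1)

  g2 <- two_k4_bridge()
  p2 <- louvain(g2, seed = 1)
  oracle <- best_partition_bruteforce(g2)
  expect_equal(p2$n_communities, 2L)
  expect_equal(ari(p2$membership, rep(c(0, 1), each = 4)), 1)
  expect_equal(p2$q, oracle$q, tolerance = 1e-12)
})

test_that("on random small graphs louvain attains the exhaustive optimum", {
  set.seed(31)
  exact <- 0
  for (i in 1:30) {
    g <- random_small_graph(sample(4:7, 1))
    oracle <- best_partition_bruteforce(g)
    p <- louvain(g, seed = i)
    expect_lte(p$q, oracle$q + 1e-9)        # never exceeds the true maximum
    if (abs(p$q - oracle$q) < 1e-9) exact <- exact + 1
  }
  expect_gte(exact, 28)
})

test_that("aggregation preserves modularity and Q never decreases over passes", {
  co <- generate_cohort(test_config(n = 250, seed = 17))
  g <- build_knn_graph(build_intake_matrix(co, "fatty_acids"), k = 15)
  p <- louvain(g, seed = 2)
  expect_true(all(diff(p$trace) >= -1e-9))
  expect_gte(p$q, modularity_q(g, seq_len(g$n)))   # beats singleton partition

  # aggregating the current partition leaves Q unchanged on the super-graph
  memb <- as.integer(factor(p$membership))
  agg <- dietnet:::aggregate_graph(g$edges, memb)
  q_sup <- modularity_q(list(n = max(memb), edges = agg),
                        seq_len(max(memb)))
  expect_equal(q_sup, p$q, tolerance = 1e-12)
})

test_that("fixed seed gives identical partitions; partitions are stable across seeds", {
  co <- generate_cohort(test_config(n = 300, seed = 23))
  g <- build_knn_graph(build_intake_matrix(co, "fatty_acids"), k = 20)
  p1 <- louvain(g, seed = 5)
  p2 <- louvain(g, seed = 5)
  expect_identical(p1$membership, p2$membership)

  parts <- lapply(1:8, function(s) louvain(g, seed = s)$membership)
  pair_ari <- utils::combn(8, 2, function(ix) {
    ari(parts[[ix[1]]], parts[[ix[2]]])
  })
  expect_gte(min(pair_ari), 0.95)
})

test_that("louvain agrees with the igraph reference on the cohort graph", {
  skip_if_not_installed("igraph")
  co <- generate_cohort(test_config(n = 300, seed = 29))
  g <- build_knn_graph(build_intake_matrix(co, "fatty_acids"), k = 20)
  p <- louvain(g, seed = 1)
  ig <- igraph::graph_from_edgelist(cbind(g$edges$i, g$edges$j),
                                    directed = FALSE)
  igraph::E(ig)$weight <- g$edges$w
  ref <- igraph::cluster_louvain(ig)
  expect_gte(p$q, igraph::modularity(ref) - 0.01)
  expect_gte(ari(p$membership, igraph::membership(ref)), 0.9)
})

test_that("relabel_by_size orders communities by size then first member", {
  p <- structure(list(membership = stats::setNames(c(1L, 1L, 1L, 0L, 0L, 2L,
                                                     2L, 2L, 2L), letters[1:9]),
                      q = 0.1, n_communities = 3L,
                      sizes = c(2L, 3L, 4L), trace = 0.1,
                      gamma = 1, seed = 1L),
                 class = "louvain_partition")
  r <- relabel_by_size(p)
  expect_equal(unname(r$membership), c(1L, 1L, 1L, 2L, 2L, 0L, 0L, 0L, 0L))
  expect_equal(r$sizes, c(4L, 3L, 2L))
  expect_identical(relabel_by_size(r)$membership, r$membership)  # idempotent

  # equal sizes: community containing the earliest member gets the lower id
  p$membership <- stats::setNames(c(2L, 1L, 2L, 1L), letters[1:4])
  p$sizes <- c(2L, 2L)
  r2 <- relabel_by_size(p)
  expect_equal(unname(r2$membership), c(0L, 1L, 0L, 1L))
})

test_that("degenerate graphs are rejected", {
  empty <- graph_from_edges(integer(0), integer(0), numeric(0), n = 3)
  expect_error(louvain(empty), "no edge weight")
  expect_error(modularity_q(empty, 1:3), "no edge weight")
})
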