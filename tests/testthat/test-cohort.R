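test_that("a fixed seed reproduces the cohort exactly and structure holds", {
  cfg <- test_config(n = 120)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  counts <- table(a$subject_id)
  expect_true(all(counts == 2L))
  fa <- as.matrix(a[, intersect(dietnet:::FA_NAMES, names(a))])
  expect_equal(ncol(fa), 31L)
  expect_true(all(fa >= 0))
  sp <- as.matrix(a[, dietnet:::SPREAD_NAMES])
  expect_true(all(sp >= 0))
  expect_false(anyNA(a[, c(paste0("sbp_r", 1:6), paste0("dbp_r", 1:6),
                           "trig", "chol", "hdl", "glucose", "insulin")]))
  expect_true(all(a$None %in% 0:1))

  c2 <- generate_cohort(cohort_config(n_subjects = 120, seed = 43))
  expect_false(identical(a$true_fa_cluster, c2$true_fa_cluster))
})

test_that("planted truth labels are exposed and stable under permutation", {
  co <- generate_cohort(test_config(n = 150))
  tf <- planted_truth(co, "fatty_acids")
  ts <- planted_truth(co, "spreads")
  expect_length(tf, 150)
  expect_equal(length(unique(tf)), 8L)
  expect_equal(length(unique(ts)), 10L)
  perm <- (tf + 3L) %% 8L               # relabelled copy of the same partition
  expect_equal(ari(tf, perm), 1)
  no_truth <- co
  no_truth$true_fa_cluster <- NULL
  expect_error(planted_truth(no_truth, "fatty_acids"), "planted labels")
})

test_that("log-intake moments match the configured means and covariance", {
  cfg <- cohort_config(n_subjects = 5000, cluster_separation = 0, seed = 11)
  co <- generate_cohort(cfg)
  v1 <- co[co$visit == "age20", ]
  lg <- log(as.matrix(v1[, dietnet:::FA_NAMES]))
  mu_hat <- colMeans(lg)
  mu_cfg <- dietnet:::fa_log_means(31)
  expect_lt(max(abs(mu_hat - mu_cfg)), 0.05 * max(abs(mu_cfg)))
  S_hat <- stats::cov(lg)
  S_cfg <- cfg$fa_sigma
  expect_lt(norm(S_hat - S_cfg, "F") / norm(S_cfg, "F"), 0.05)
})

test_that("visit-to-visit correlation and MAR rates are calibrated", {
  # separation 0 so between-cluster mean shifts cannot inflate the correlation
  cfg <- cohort_config(n_subjects = 2000, within_subject_corr = 0.7,
                       cluster_separation = 0, seed = 5)
  co <- generate_cohort(cfg)
  ordc <- co[order(co$subject_id, co$visit), ]
  v1 <- ordc[ordc$visit == "age20", ]
  v2 <- ordc[ordc$visit == "age22", ]
  cors <- vapply(dietnet:::FA_NAMES,
                 function(v) stats::cor(log(v1[[v]]), log(v2[[v]])), 0)
  expect_lt(max(abs(cors - 0.7)), 0.05)

  rates <- vapply(names(cfg$missing_rates),
                  function(v) mean(is.na(v1[[v]])), 0)
  expect_lt(max(abs(rates - cfg$missing_rates)), 0.02)
})

test_that("sex-specific SBP baselines yield the configured contrast", {
  co <- derive_outcomes(generate_cohort(test_config(n = 800, seed = 9)))
  v1 <- co[co$visit == "age20", ]
  gap <- mean(v1$derived_sbp[v1$sex == "male"]) -
    mean(v1$derived_sbp[v1$sex == "female"])
  expect_lt(abs(gap - 10.5), 2)        # configured 122.2 - 111.7 within sim error
})

test_that("zero separation leaves planted fatty-acid labels unrecoverable", {
  co <- generate_cohort(cohort_config(n_subjects = 500, cluster_separation = 0,
                                      seed = 21))
  m <- build_intake_matrix(co, "fatty_acids")
  part <- louvain(build_knn_graph(m, k = 20), seed = 1)
  truth <- planted_truth(co, "fatty_acids")
  expect_lt(abs(ari(part$membership[names(truth)], truth)), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_fa_clusters = 1), ">= 2")
  expect_error(cohort_config(within_subject_corr = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(missing_rates = c(sodium = 1.5)), "\\[0, 1\\]")
  expect_error(cohort_config(missing_rates = c(nonexistent = 0.1)), "unknown")
  expect_error(cohort_config(effect_table = data.frame(
    exposure = "fa", cluster = 99, outcome = "sbp", effect = 5)),
    "outside the planted range")
  expect_error(cohort_config(effect_table = data.frame(
    exposure = "fa", cluster = 0, outcome = "bogus", effect = 5)),
    "unknown outcomes")
})

test_that("cohort CSV round-trips with its sidecar", {
  co <- generate_cohort(test_config(n = 30))
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(co, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_cohort(path)
  expect_equal(dim(back), dim(co))
  expect_equal(back$trig, co$trig, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".meta.json")))
})
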