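test_that("a complete table passes through imputation unchanged", {
  co <- generate_cohort(test_config(n = 80, missing_rates = c()))
  stack <- impute(co, imputation_spec(m = 3, seed = 1))
  expect_length(stack$data, 3)
  for (d in stack$data) {
    expect_identical(d[dietnet:::COVARIATE_NAMES], co[dietnet:::COVARIATE_NAMES])
  }
})

test_that("observed cells are never altered and PMM respects the donor set", {
  co <- generate_cohort(test_config(n = 300, seed = 3))
  stack <- impute(co, imputation_spec(m = 4, n_cycles = 5, seed = 2))
  for (v in c("sodium", "pa_category", "smoking")) {
    obs <- !is.na(co[[v]])
    for (d in stack$data) {
      expect_identical(d[[v]][obs], co[[v]][obs])
      expect_false(anyNA(d[[v]]))
    }
  }
  # PMM draws only observed category values
  for (d in stack$data) {
    expect_true(all(d$pa_category %in% 0:2))
    expect_true(all(d$smoking %in% 0:1))
    expect_true(all(d$family_history %in% 0:1))
  }
})

test_that("MAR-missing sodium is recovered near the generator truth", {
  cfg <- cohort_config(n_subjects = 600, seed = 8,
                       missing_rates = c(sodium = 0.2))
  co <- generate_cohort(cfg)
  full <- generate_cohort(cohort_config(n_subjects = 600, seed = 8,
                                        missing_rates = c()))
  stack <- impute(co, imputation_spec(m = 5, n_cycles = 5, seed = 4))
  first <- !duplicated(co$subject_id)
  pooled_mean <- mean(vapply(stack$data,
                             function(d) mean(d$sodium[first]), 0))
  truth_mean <- mean(full$sodium[first])
  se <- stats::sd(full$sodium[first]) / sqrt(600)
  expect_lt(abs(pooled_mean - truth_mean), 2 * se)
})

test_that("Rubin's rules reproduce hand-computed pooling", {
  r <- pool_rubin(c(1, 3), c(0.5, 0.5))
  expect_equal(r$estimate, 2)
  expect_equal(r$W, 0.5)
  expect_equal(r$B, 2)
  expect_equal(r$T, 0.5 + 1.5 * 2)

  same <- pool_rubin(rep(1.7, 5), rep(0.3, 5), dfcom = 100)
  expect_equal(same$B, 0)
  expect_equal(same$T, same$W)
  expect_equal(same$df, 100)

  # long-hand oracle at m = 20
  set.seed(12)
  est <- rnorm(20); va <- runif(20, 0.2, 0.5)
  r20 <- pool_rubin(est, va, dfcom = 500)
  W <- sum(va) / 20
  B <- sum((est - mean(est))^2) / 19
  expect_equal(r20$T, W + (1 + 1/20) * B, tolerance = 1e-12)
  lam <- (1 + 1/20) * B / (W + (1 + 1/20) * B)
  df_old <- 19 / lam^2
  df_obs <- 501 / 503 * 500 * (1 - lam)
  expect_equal(r20$df, 1 / (1/df_old + 1/df_obs), tolerance = 1e-12)

  expect_error(pool_rubin(1, 0.5), "m >= 2")
  expect_error(pool_rubin(c(1, 2), c(0.5, -1)), "positive")
})

test_that("D1 pooling matches a long-hand multi-parameter computation", {
  set.seed(5)
  m <- 6; k <- 3
  coefs <- lapply(1:m, function(i) rnorm(k))
  vcovs <- lapply(1:m, function(i) { A <- matrix(rnorm(9), 3); crossprod(A) + diag(3) })
  d1 <- pool_wald_d1(coefs, vcovs)
  qbar <- Reduce(`+`, coefs) / m
  ubar <- Reduce(`+`, vcovs) / m
  B <- Reduce(`+`, lapply(coefs, function(q) tcrossprod(q - qbar))) / (m - 1)
  r <- (1 + 1/m) * sum(diag(B %*% solve(ubar))) / k
  expect_equal(d1$D1,
               drop(t(qbar) %*% solve(ubar) %*% qbar) / (k * (1 + r)),
               tolerance = 1e-12)
  expect_true(d1$p >= 0 && d1$p <= 1)
})

test_that("errors: missing predictors, unimputable and all-missing variables", {
  co <- generate_cohort(test_config(n = 60, seed = 2))
  broken <- co
  broken$sodium <- NA_real_
  expect_error(impute(broken, imputation_spec(m = 2)), "100% missing")
  expect_error(imputation_spec(m = 1), "m >= 2")
  expect_error(imputation_spec(methods = c(sodium = "magic")), "pmm")
})

test_that("imputation diagnostics summarize observed vs imputed means", {
  co <- generate_cohort(test_config(n = 200, seed = 6))
  stack <- impute(co, imputation_spec(m = 2, n_cycles = 3, seed = 3))
  dg <- stack$diagnostics
  expect_true(all(c("variable", "n_missing", "mean_observed",
                    "mean_imputed") %in% names(dg)))
  expect_true(all(dg$n_missing > 0))
  expect_false(anyNA(dg$mean_imputed))
})
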