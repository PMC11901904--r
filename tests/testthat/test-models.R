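make_modelled_cohort <- function(n, seed, effects = NULL) {
  co <- generate_cohort(cohort_config(n_subjects = n, seed = seed,
                                      effect_table = effects,
                                      missing_rates = c()))
  co <- derive_outcomes(co)
  tf <- planted_truth(co, "fatty_acids")
  ts <- planted_truth(co, "spreads")
  co$fa_cluster <- factor(tf[as.character(co$subject_id)])
  co$spread_cluster <- factor(ts[as.character(co$subject_id)])
  co
}

test_that("cluster-robust covariance equals the long-hand oracle", {
  co <- make_modelled_cohort(150, 31)
  fit <- fit_glm_cluster(derived_sbp ~ fa_cluster + spread_cluster, co,
                         co$subject_id)
  X <- stats::model.matrix(derived_sbp ~ fa_cluster + spread_cluster, co)
  V <- sandwich_oracle(X, co$derived_sbp, co$subject_id)
  expect_lt(max(abs(fit$vcov - V)) / max(abs(V)), 1e-8)
  # positive semi-definite
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("robust covariance matches the sandwich package's CR1 estimator", {
  skip_if_not_installed("sandwich")
  co <- make_modelled_cohort(120, 37)
  f <- derived_dbp ~ fa_cluster + age + whr
  fit <- fit_glm_cluster(f, co, co$subject_id)
  lmfit <- stats::lm(f, co)
  Vref <- sandwich::vcovCL(lmfit, cluster = co$subject_id, type = "HC1",
                           cadjust = TRUE)
  expect_equal(unname(fit$vcov), unname(Vref), tolerance = 1e-8)
})

test_that("groups of size one reduce the sandwich to HC1", {
  set.seed(5)
  n <- 90
  d <- data.frame(y = rnorm(n), x = rnorm(n), z = rnorm(n))
  fit <- fit_glm_cluster(y ~ x + z, d, seq_len(n))
  X <- cbind(1, d$x, d$z)
  u <- stats::residuals(stats::lm(y ~ x + z, d))
  hc1 <- n / (n - 3) * solve(crossprod(X)) %*%
    (t(X * u^2) %*% X) %*% solve(crossprod(X))
  expect_equal(unname(fit$vcov), unname(hc1), tolerance = 1e-10)
})

test_that("duplicating each subject's row leaves point estimates unchanged", {
  set.seed(6)
  d <- data.frame(y = rnorm(40), x = rnorm(40))
  single <- fit_glm_cluster(y ~ x, d, seq_len(40))
  dup <- d[rep(1:40, each = 2), ]
  doubled <- fit_glm_cluster(y ~ x, dup, rep(1:40, each = 2))
  expect_equal(doubled$coefficients, single$coefficients, tolerance = 1e-12)
})

test_that("a planted +5 mmHg cluster effect is recovered", {
  eff <- data.frame(exposure = "fa", cluster = 1, outcome = "sbp", effect = 5)
  co <- make_modelled_cohort(600, 41, eff)
  fit <- fit_glm_cluster(derived_sbp ~ fa_cluster + spread_cluster, co,
                         co$subject_id)
  b <- fit$coefficients["fa_cluster1"]
  se <- fit$se["fa_cluster1"]
  expect_lt(abs(b - 5), 2 * se)
})

test_that("singular designs and malformed clusters are rejected", {
  set.seed(8)
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  d$x2 <- 2 * d$x
  expect_error(fit_glm_cluster(y ~ x + x2, d, 1:30), "collinear.*x2")
  expect_error(fit_glm_cluster(y ~ x, d, 1:10), "one id per row")
})

test_that("ratio reporting inverts the log-scale coefficients exactly", {
  r0 <- ratio_report(0, 0.1)
  expect_equal(r0$ratio, 1)
  expect_equal(r0$pct_change, 0)

  r <- ratio_report(log(1.264), 0.05)
  expect_equal(r$pct_change, 26.4, tolerance = 1e-10)

  rneg <- ratio_report(-log(1.25), 0.05)
  expect_equal(rneg$pct_change, 100 * (1 / 1.25 - 1), tolerance = 1e-10)
  expect_equal(rneg$ci_lo, exp(-log(1.25) - 1.96 * 0.05), tolerance = 1e-12)
  expect_equal(rneg$ci_hi, exp(-log(1.25) + 1.96 * 0.05), tolerance = 1e-12)
  expect_error(ratio_report(Inf, 1), "finite")
})

test_that("the familywise gate rejects single-level factors", {
  co <- make_modelled_cohort(150, 43)
  co$binary <- factor(ifelse(as.integer(as.character(co$fa_cluster)) < 4,
                             "lo", "hi"))
  fit <- fit_glm_cluster(derived_sbp ~ binary + spread_cluster, co,
                         co$subject_id)
  expect_error(familywise_gate(fit, "binary"), "fewer than 2")
  gate <- familywise_gate(fit, "spread_cluster")
  expect_equal(gate$df, 9L)
  expect_true(gate$p >= 0 && gate$p <= 1)
})

test_that("estimates are invariant to cluster relabeling", {
  co <- make_modelled_cohort(200, 47)
  fit1 <- fit_glm_cluster(derived_sbp ~ fa_cluster, co, co$subject_id)
  relab <- co
  # rotate labels but keep the same reference group at the front
  lv <- levels(co$fa_cluster)
  relab$fa_cluster <- factor(paste0("x", co$fa_cluster),
                             levels = paste0("x", lv))
  fit2 <- fit_glm_cluster(derived_sbp ~ fa_cluster, relab, relab$subject_id)
  expect_equal(unname(fit1$coefficients), unname(fit2$coefficients),
               tolerance = 1e-12)
  g1 <- familywise_gate(fit1, "fa_cluster")
  g2 <- familywise_gate(fit2, "fa_cluster")
  expect_equal(g1$statistic, g2$statistic, tolerance = 1e-10)
})

test_that("pooled analysis on a 0%-missing stack equals the single fit", {
  co <- make_modelled_cohort(200, 53)
  stack <- impute(co, imputation_spec(m = 2, seed = 1))
  res <- run_analysis(stack, model_spec("sbp", "model1"), by_sex = FALSE)
  fit <- fit_glm_cluster(derived_sbp ~ fa_cluster + spread_cluster, co,
                         co$subject_id)
  row <- res[res$exposure == "fa_cluster" & res$level == "1", ]
  expect_equal(row$estimate, unname(fit$coefficients["fa_cluster1"]),
               tolerance = 1e-10)
  expect_equal(row$se, unname(fit$se["fa_cluster1"]), tolerance = 1e-10)
})

test_that("sex-specific and ratio-scale planted effects are recovered", {
  eff <- data.frame(exposure = c("spread", "fa"),
                    cluster = c(2, 3),
                    outcome = c("sbp", "trig"),
                    effect = c(8, log(1.3)),
                    sex = c("male", "both"))
  co <- make_modelled_cohort(700, 59, eff)
  stack <- impute(co, imputation_spec(m = 2, seed = 2))
  res <- run_analysis(stack, list(model_spec("sbp", "model1"),
                                  model_spec("trig", "model1")))

  male_gate <- unique(res$gate_p[res$outcome == "sbp" & res$sex == "male" &
                                   res$exposure == "spread_cluster"])
  expect_lt(male_gate, 0.05)
  male_b <- res[res$outcome == "sbp" & res$sex == "male" &
                  res$exposure == "spread_cluster" & res$level == "2", ]
  expect_lt(abs(male_b$estimate - 8), 3 * male_b$se)

  tr <- res[res$outcome == "trig" & res$exposure == "fa_cluster" &
              res$level == "3", ]
  for (i in seq_len(nrow(tr))) {
    expect_lt(abs(tr$estimate[i] - log(1.3)), 3 * tr$se[i])
  }
  expect_true(all(res$ci_lo[res$scale == "log"] > 0))
})
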