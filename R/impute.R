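#' @title Multiple imputation by chained equations
#' @description Chained-equation imputation of incomplete covariates with
#'   predictive mean matching (categorical covariates) and Bayesian linear
#'   regression (continuous covariates), plus Rubin's rules and the D1
#'   multi-parameter statistic for pooling across completed datasets.
#' @name impute
NULL

default_methods <- function() {
  c(family_history = "pmm", smoking = "pmm", pa_category = "pmm",
    whr = "linear", healthy_score = "linear", western_score = "linear",
    fruit = "linear", vegetable = "linear", alcohol = "linear",
    sodium = "linear", mets = "linear")
}

#' Imputation specification
#'
#' @param m number of completed datasets (default 20, >= 2).
#' @param methods named map covariate -> `"pmm"` or `"linear"`; defaults use
#'   PMM for the categorical covariates (family history, smoking, physical
#'   activity category) and Bayesian linear regression for the rest.
#' @param pmm_donors donor pool size for PMM (default 5).
#' @param n_cycles chained-equation sweeps per dataset (default 10).
#' @param seed integer seed.
#' @return an `imputation_spec` list.
#' @export
imputation_spec <- function(m = 20, methods = default_methods(),
                            pmm_donors = 5, n_cycles = 10, seed = 1L) {
  if (m < 2) stopf("need m >= 2 imputed datasets")
  if (!all(methods %in% c("pmm", "linear"))) {
    stopf("methods must be 'pmm' or 'linear'")
  }
  structure(list(m = as.integer(m), methods = methods,
                 pmm_donors = as.integer(pmm_donors),
                 n_cycles = as.integer(n_cycles), seed = as.integer(seed)),
            class = "imputation_spec")
}

# Bayesian draw of (sigma, beta) from the standard noninformative posterior of
# a linear regression; returns the drawn coefficients and residual SD.
bayes_lm_draw <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  } else keep <- seq_len(ncol(X))
  beta_hat <- qr.coef(qrX, y)
  res <- y - X %*% beta_hat
  df <- max(1, nrow(X) - ncol(X))
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrX)
  V <- chol2inv(R)
  beta_draw <- beta_hat + t(chol(sigma2 * (V + t(V)) / 2 +
                                   diag(1e-12, ncol(X)))) %*% stats::rnorm(ncol(X))
  list(beta_hat = beta_hat, beta_draw = drop(beta_draw),
       sigma = sqrt(sigma2), keep = keep)
}

impute_one <- function(sub, vars, pred_cols, methods, pmm_donors, n_cycles) {
  obs_idx <- lapply(vars, function(v) which(!is.na(sub[[v]])))
  mis_idx <- lapply(vars, function(v) which(is.na(sub[[v]])))
  names(obs_idx) <- names(mis_idx) <- vars
  cur <- sub
  # initialize by random draws from the observed margin
  for (v in vars) {
    cur[[v]][mis_idx[[v]]] <- sample(sub[[v]][obs_idx[[v]]],
                                     length(mis_idx[[v]]), replace = TRUE)
  }
  for (cyc in seq_len(n_cycles)) {
    for (v in vars) {
      oi <- obs_idx[[v]]; mi <- mis_idx[[v]]
      if (!length(mi)) next
      rhs <- setdiff(c(vars, pred_cols), v)
      X <- cbind(1, as.matrix(cur[rhs]))
      y <- sub[[v]][oi]
      dr <- bayes_lm_draw(X[oi, , drop = FALSE], y)
      Xm <- X[mi, dr$keep, drop = FALSE]
      if (methods[[v]] == "pmm") {
        yhat_obs <- drop(X[oi, dr$keep, drop = FALSE] %*% dr$beta_hat)
        yhat_mis <- drop(Xm %*% dr$beta_draw)
        d <- abs(outer(yhat_mis, yhat_obs, "-"))
        pick <- apply(d, 1, function(row) {
          pool <- order(row)[seq_len(min(pmm_donors, length(row)))]
          pool[sample.int(length(pool), 1)]
        })
        cur[[v]][mi] <- y[pick]
      } else {
        cur[[v]][mi] <- drop(Xm %*% dr$beta_draw) +
          stats::rnorm(length(mi), 0, dr$sigma)
      }
    }
  }
  cur
}

#' Impute incomplete covariates by chained equations
#'
#' Covariates are subject-level (constant across the two visit rows), so the
#' chained equations run on a one-row-per-subject table whose complete
#' predictors are sex and both visits' mean systolic and diastolic blood
#' pressure — the group-mean form of subject and visit indicators. Each of
#' the `m` completed datasets is a full copy of the input cohort with the
#' covariate columns completed; observed cells are never altered.
#'
#' @param cohort a `cohort_table` (two rows per subject); derived BP columns
#'   are computed on the fly if absent.
#' @param spec an [imputation_spec()].
#' @return an `imputed_stack`: list with `data` (list of `m` completed
#'   cohorts), `diagnostics` (per-variable observed/imputed means and missing
#'   counts) and `spec`.
#' @export
impute <- function(cohort, spec = imputation_spec()) {
  stopifnot(inherits(spec, "imputation_spec"))
  if (!"derived_sbp" %in% names(cohort)) cohort <- derive_outcomes(cohort)
  vars <- intersect(names(spec$methods), names(cohort))
  vars <- vars[vapply(vars, function(v) anyNA(cohort[[v]]), logical(1))]
  for (v in vars) {
    if (all(is.na(cohort[[v]]))) stopf("covariate '%s' is 100%% missing", v)
  }
  # order by increasing missingness (stabilizes the chained sweeps)
  vars <- vars[order(vapply(vars, function(v) sum(is.na(cohort[[v]])),
                            numeric(1)))]

  ord <- order(cohort$subject_id, cohort$visit)
  co <- cohort[ord, ]
  first <- !duplicated(co$subject_id)
  second <- duplicated(co$subject_id)
  sub <- co[first, c("subject_id", "sex", COVARIATE_NAMES), drop = FALSE]
  sub$sex_male <- as.numeric(sub$sex == "male")
  sub$sbp_v1 <- co$derived_sbp[first];  sub$sbp_v2 <- co$derived_sbp[second]
  sub$dbp_v1 <- co$derived_dbp[first];  sub$dbp_v2 <- co$derived_dbp[second]
  pred_cols <- c("sex_male", "sbp_v1", "sbp_v2", "dbp_v1", "dbp_v2")
  if (anyNA(sub[pred_cols])) stopf("imputation predictors must be complete")
  other_cov <- setdiff(intersect(COVARIATE_NAMES, names(sub)), vars)
  if (length(other_cov) && anyNA(sub[other_cov])) {
    stopf("covariates with missing values but no imputation method: %s",
          paste(other_cov[vapply(other_cov, function(v) anyNA(sub[[v]]),
                                 logical(1))], collapse = ", "))
  }
  pred_cols <- c(pred_cols, other_cov)

  completed <- vector("list", spec$m)
  if (!length(vars)) {
    for (j in seq_len(spec$m)) completed[[j]] <- cohort
    return(structure(list(data = completed, diagnostics = NULL, spec = spec),
                     class = "imputed_stack"))
  }
  diagnostics <- data.frame(variable = vars,
                            n_missing = vapply(vars, function(v)
                              sum(is.na(sub[[v]])), numeric(1)),
                            mean_observed = vapply(vars, function(v)
                              mean(sub[[v]], na.rm = TRUE), numeric(1)),
                            mean_imputed = NA_real_)
  imp_means <- matrix(0, spec$m, length(vars))
  for (j in seq_len(spec$m)) {
    filled <- with_seed(sub_seed(spec$seed, paste0("imp", j)),
                        impute_one(sub, vars, pred_cols, spec$methods,
                                   spec$pmm_donors, spec$n_cycles))
    out <- cohort
    for (v in seq_along(vars)) {
      vv <- vars[v]
      out[[vv]] <- filled[[vv]][match(cohort$subject_id, sub$subject_id)]
      imp_means[j, v] <- mean(filled[[vv]][is.na(sub[[vv]])])
    }
    completed[[j]] <- out
  }
  diagnostics$mean_imputed <- colMeans(imp_means)
  structure(list(data = completed, diagnostics = diagnostics, spec = spec),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("imputed_stack: m = %d completed datasets\n", length(x$data)))
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  invisible(x)
}

#' Pool scalar estimates across imputations (Rubin's rules)
#'
#' Combines per-imputation point estimates and variances: pooled estimate
#' Qbar = mean, within-variance W = mean variance, between-variance B, total
#' T = W + (1 + 1/m) B, with Barnard-Rubin small-sample degrees of freedom.
#'
#' @param estimates numeric vector of per-imputation estimates (length m >= 2).
#' @param variances matching squared standard errors (> 0).
#' @param dfcom complete-data degrees of freedom (default `Inf`).
#' @return list with `estimate`, `W`, `B`, `T`, `se`, `df`, `riv`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf) {
  m <- length(estimates)
  if (m < 2) stopf("Rubin pooling needs m >= 2")
  if (length(variances) != m || any(variances <= 0)) {
    stopf("variances must be positive and match estimates in length")
  }
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1/m) * B
  riv <- (1 + 1/m) * B / W
  lambda <- riv / (1 + riv)
  if (B == 0) {
    df <- dfcom
  } else {
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else df <- df_old
  }
  list(estimate = qbar, W = W, B = B, T = Tv, se = sqrt(Tv), df = df,
       riv = riv)
}

#' Pool a multi-parameter Wald test across imputations (D1 statistic)
#'
#' @param coefs list of length m; each a numeric vector of the tested
#'   coefficients from one imputation.
#' @param vcovs list of matching covariance matrices.
#' @return list with `D1` (F statistic), `df1`, `df2`, `p`.
#' @export
pool_wald_d1 <- function(coefs, vcovs) {
  m <- length(coefs)
  if (m < 2) stopf("D1 pooling needs m >= 2")
  k <- length(coefs[[1]])
  qbar <- Reduce(`+`, coefs) / m
  ubar <- Reduce(`+`, vcovs) / m
  B <- matrix(0, k, k)
  for (j in seq_len(m)) {
    d <- coefs[[j]] - qbar
    B <- B + tcrossprod(d)
  }
  B <- B / (m - 1)
  ubar_inv <- solve(ubar)
  r <- (1 + 1/m) * sum(diag(B %*% ubar_inv)) / k
  D1 <- drop(t(qbar) %*% ubar_inv %*% qbar) / (k * (1 + r))
  t <- k * (m - 1)
  df2 <- if (r <= .Machine$double.eps) {
    Inf
  } else if (t > 4) {
    4 + (t - 4) * (1 + (1 - 2/t) / r)^2
  } else {
    t * (1 + 1/k) * (1 + 1/r)^2 / 2
  }
  list(D1 = D1, df1 = k, df2 = df2,
       p = stats::pf(D1, k, df2, lower.tail = FALSE))
}
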