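#' @title Synthetic cohort generation
#' @description Generator for long-format subject-by-visit cohorts carrying the
#'   statistical structure the downstream analysis assumes: correlated
#'   log-normal fatty-acid intake profiles with planted cluster structure,
#'   zero-inflated fat-spread usage with cluster-specific usage patterns, two
#'   visits per subject with within-subject correlation, outcome panels with
#'   known additive cluster effects, and missing-at-random covariates.
#' @name cohort
NULL

# 31 dietary fatty acids: common name + carbon-chain shorthand.
FA_NAMES <- c(
  "butyric_4_0", "caproic_6_0", "caprylic_8_0", "capric_10_0", "lauric_12_0",
  "myristic_14_0", "pentadecanoic_15_0", "palmitic_16_0", "margaric_17_0",
  "stearic_18_0", "arachidic_20_0", "behenic_22_0", "lignoceric_24_0",
  "myristoleic_14_1n7", "pentadecenoic_15_1", "palmitoleic_16_1n7",
  "civetic_17_1n9", "oleic_18_1n9", "elaidic_18_1n9t", "gondoic_20_1n9",
  "erucic_22_1n9", "linoleic_18_2n6", "linoelaidic_18_2n6t",
  "alpha_linolenic_18_3n3", "dihomolinoleic_20_2n6", "mead_20_3n6",
  "arachidonic_20_4n6", "eicosapentaenoic_20_5n3", "adrenic_22_4n6",
  "docosapentaenoic_22_5n3", "docosahexaenoic_22_6n3"
)

# Typical adult intakes in g/day (geometric means for the log-normal model);
# majors (palmitic, oleic, stearic, linoleic) dominate, long-chain n-3 are small.
FA_GM <- c(
  0.70, 0.45, 0.30, 0.60, 1.20,
  2.50, 0.25, 24.0, 0.30,
  11.0, 0.10, 0.08, 0.05,
  0.20, 0.03, 1.30,
  0.10, 32.0, 1.00, 0.15,
  0.05, 11.0, 0.15,
  1.30, 0.05, 0.03,
  0.10, 0.15, 0.02,
  0.10, 0.25
)

# Fat spread intake columns, labelled as in the source food-frequency survey.
SPREAD_NAMES <- c("Marg", "Polyunsaturated_marg", "Monounsaturated_marg",
                  "Marg_butter_blends", "Butter")

# Subject-level covariates eligible for missingness (sex, age, WHR stay complete).
COVARIATE_NAMES <- c("whr", "family_history", "healthy_score", "western_score",
                     "fruit", "vegetable", "alcohol", "sodium", "smoking",
                     "mets", "pa_category")

OUTCOME_SCALES <- c(sbp = "identity", dbp = "identity", trig = "log",
                    chol = "log", hdl = "log", glucose = "log", insulin = "log")

default_missing_rates <- function() {
  c(family_history = 0.08, healthy_score = 0.06, western_score = 0.06,
    fruit = 0.19, vegetable = 0.19, alcohol = 0.135, sodium = 0.10,
    smoking = 0.08, mets = 0.10, pa_category = 0.10)
}

#' Configuration for the synthetic cohort generator
#'
#' Holds every knob of [generate_cohort()]. Defaults reproduce the conditions
#' the analysis was designed for: n = 785 subjects at two visits, 31 fatty
#' acids with 8 planted intake clusters, 5 spread types with 10 planted usage
#' patterns, sex-specific systolic blood pressure baselines (male 122.2,
#' female 111.7 mmHg), and realistic missing-at-random covariate rates.
#'
#' @param n_subjects number of subjects (each contributes two visit rows).
#' @param n_fatty_acids number of fatty-acid intake columns (default 31).
#' @param n_spread_types number of fat-spread intake columns (default 5).
#' @param n_fa_clusters planted fatty-acid profile clusters (>= 2, default 8).
#' @param n_spread_clusters planted spread usage patterns (>= 2, default 10);
#'   pattern 0 is always "no spreads" (all spread intakes structurally zero).
#' @param cluster_separation mean shift, in units of the log-scale SD, applied
#'   to each of a cluster's distinguishing fatty acids; 0 means no planted
#'   signal.
#' @param within_subject_corr correlation in `[0,1]` between the two visits'
#'   log intakes (and, analogously, outcome panels).
#' @param effect_table `NULL` for no planted outcome effects, or a data.frame
#'   with columns `exposure` ("fa" or "spread"), `cluster` (0-based planted
#'   id), `outcome` (one of sbp, dbp, trig, chol, hdl, glucose, insulin),
#'   `effect` (mmHg for identity-scale outcomes, log-ratio for log-scale ones)
#'   and optionally `sex` ("both", "male", "female"; default "both").
#' @param missing_rates named vector of MAR missingness proportions per
#'   covariate (subset of `family_history, healthy_score, western_score,
#'   fruit, vegetable, alcohol, sodium, smoking, mets, pa_category`).
#' @param fa_log_sd marginal SD of log fatty-acid intake (scalar or length-p).
#' @param n_factors latent factors inducing intake correlation
#'   (multicollinearity); factor loadings are drawn once per seed.
#' @param sbp_mean named c(male=, female=) baseline systolic BP, mmHg.
#' @param seed integer; the same seed yields a byte-identical cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 785,
                          n_fatty_acids = 31,
                          n_spread_types = 5,
                          n_fa_clusters = 8,
                          n_spread_clusters = 10,
                          cluster_separation = 3,
                          within_subject_corr = 0.7,
                          effect_table = NULL,
                          missing_rates = default_missing_rates(),
                          fa_log_sd = 0.35,
                          n_factors = 3,
                          sbp_mean = c(male = 122.2, female = 111.7),
                          seed = 1L) {
  stopifnot(n_subjects >= 4, n_fatty_acids >= 2, n_spread_types >= 2)
  if (n_fa_clusters < 2 || n_spread_clusters < 2) {
    stopf("n_fa_clusters and n_spread_clusters must be >= 2")
  }
  if (within_subject_corr < 0 || within_subject_corr > 1) {
    stopf("within_subject_corr must lie in [0, 1]")
  }
  if (length(missing_rates)) {
    if (any(missing_rates < 0 | missing_rates > 1)) {
      stopf("missing_rates must lie in [0, 1]")
    }
    bad <- setdiff(names(missing_rates), COVARIATE_NAMES)
    if (length(bad)) stopf("unknown covariates in missing_rates: %s",
                           paste(bad, collapse = ", "))
  }
  max_patterns <- 1 + n_spread_types + choose(n_spread_types, 2)
  if (n_spread_clusters > max_patterns) {
    stopf("n_spread_clusters = %d exceeds the %d distinct usage patterns available",
          n_spread_clusters, max_patterns)
  }
  effect_table <- validate_effect_table(effect_table, n_fa_clusters,
                                        n_spread_clusters)
  fa_log_sd <- rep_len(fa_log_sd, n_fatty_acids)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    n_fatty_acids = as.integer(n_fatty_acids),
    n_spread_types = as.integer(n_spread_types),
    n_fa_clusters = as.integer(n_fa_clusters),
    n_spread_clusters = as.integer(n_spread_clusters),
    cluster_separation = cluster_separation,
    within_subject_corr = within_subject_corr,
    effect_table = effect_table,
    missing_rates = missing_rates,
    fa_log_sd = fa_log_sd,
    n_factors = as.integer(n_factors),
    sbp_mean = sbp_mean,
    seed = as.integer(seed)
  ), class = "cohort_config")
  # Latent-factor correlation of log intakes, fixed per seed; reject any
  # numerically non-positive-definite construction outright.
  cfg$fa_corr <- with_seed(sub_seed(seed, "fa_corr"), {
    p <- cfg$n_fatty_acids
    L <- matrix(stats::runif(p * cfg$n_factors, 0.15, 0.55), p, cfg$n_factors)
    C <- tcrossprod(L)
    diag(C) <- 1
    C
  })
  ch <- tryCatch(chol(cfg$fa_corr), error = function(e) NULL)
  if (is.null(ch)) stopf("intake correlation matrix is not positive definite")
  cfg$fa_sigma <- cfg$fa_corr * tcrossprod(fa_log_sd)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "cohort_config: %d subjects x 2 visits | %d fatty acids (%d planted clusters), %d spreads (%d patterns)\n",
    x$n_subjects, x$n_fatty_acids, x$n_fa_clusters, x$n_spread_types,
    x$n_spread_clusters))
  cat(sprintf("  separation %.2f SD, visit corr %.2f, seed %d\n",
              x$cluster_separation, x$within_subject_corr, x$seed))
  invisible(x)
}

validate_effect_table <- function(et, n_fa, n_spread) {
  if (is.null(et)) return(NULL)
  et <- as.data.frame(et)
  need <- c("exposure", "cluster", "outcome", "effect")
  if (!all(need %in% names(et))) {
    stopf("effect_table needs columns %s", paste(need, collapse = ", "))
  }
  if (!"sex" %in% names(et)) et$sex <- "both"
  if (!all(et$exposure %in% c("fa", "spread"))) {
    stopf("effect_table$exposure must be 'fa' or 'spread'")
  }
  if (!all(et$outcome %in% names(OUTCOME_SCALES))) {
    stopf("unknown outcomes in effect_table: %s",
          paste(setdiff(et$outcome, names(OUTCOME_SCALES)), collapse = ", "))
  }
  if (!all(et$sex %in% c("both", "male", "female"))) {
    stopf("effect_table$sex must be both/male/female")
  }
  kmax <- ifelse(et$exposure == "fa", n_fa, n_spread)
  if (any(et$cluster < 0 | et$cluster >= kmax)) {
    stopf("effect_table names a cluster id outside the planted range")
  }
  et
}

fa_colnames <- function(p) {
  if (p == length(FA_NAMES)) FA_NAMES else sprintf("fa_%02d", seq_len(p))
}

spread_colnames <- function(k) {
  if (k == length(SPREAD_NAMES)) SPREAD_NAMES else sprintf("spread_%d", seq_len(k))
}

fa_log_means <- function(p) {
  if (p == length(FA_GM)) log(FA_GM) else log(seq(0.1, 20, length.out = p))
}

# Usage pattern for each planted spread cluster: pattern 0 uses nothing, then
# the singletons, then distinct pairs. Structural zeros outside the support.
spread_patterns <- function(n_clusters, n_types) {
  pats <- list(integer(0))
  for (i in seq_len(n_types)) pats[[length(pats) + 1L]] <- i
  if (n_types >= 2) {
    prs <- utils::combn(n_types, 2, simplify = FALSE)
    # interleave distant pairs first so neighbouring patterns share less support
    for (pr in prs) pats[[length(pats) + 1L]] <- pr
  }
  pats[seq_len(n_clusters)]
}

# Correlated two-visit draws: n x p standard normal pair with column
# correlation structure `chol_R` and visit-1/visit-2 correlation rho.
two_visit_mvn <- function(n, p, chol_R, rho) {
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol_R
  e1 <- matrix(stats::rnorm(n * p), n, p) %*% chol_R
  e2 <- matrix(stats::rnorm(n * p), n, p) %*% chol_R
  list(v1 = sqrt(rho) * z + sqrt(1 - rho) * e1,
       v2 = sqrt(rho) * z + sqrt(1 - rho) * e2)
}

# Calibrate the MAR intercept so the expected missingness rate matches `rate`
# given linear predictor `lp`, then draw indicator.
mar_indicator <- function(rate, lp) {
  if (rate <= 0) return(rep(FALSE, length(lp)))
  f <- function(a) mean(stats::plogis(a + lp)) - rate
  a <- stats::uniroot(f, c(-20, 20))$root
  stats::runif(length(lp)) < stats::plogis(a + lp)
}

#' Generate a synthetic cohort
#'
#' Draws a long-format cohort table (two rows per subject, visits `age20` and
#' `age22`) from the model described in the methods vignette: log-normal
#' fatty-acid intakes with a latent-factor correlation structure and planted
#' cluster mean shifts; zero-inflated spread usage with cluster-specific
#' supports; outcome panels (six seated BP readings per pressure, lipids,
#' glucose, insulin) built from sex-specific baselines, planted cluster
#' effects, a subject random intercept and visit noise; and subject-level
#' covariates with missingness imposed MAR given sex and systolic BP.
#'
#' @param config a [cohort_config()] object.
#' @return a `cohort_table` (data.frame, 2 rows per subject) with planted
#'   labels in `true_fa_cluster` / `true_spread_cluster` and the config stored
#'   as an attribute.
#' @seealso [planted_truth()], [derive_outcomes()], [build_intake_matrix()]
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  p <- config$n_fatty_acids
  rho <- config$within_subject_corr
  chol_R <- chol(config$fa_corr)

  with_seed(config$seed, {
    sex <- ifelse(stats::runif(n) < 0.521, "male", "female")

    ## --- planted cluster assignments (sizes mildly uneven, as in real data)
    wfa <- seq(1.8, 0.6, length.out = config$n_fa_clusters)
    fa_cluster <- sample.int(config$n_fa_clusters, n, TRUE, wfa) - 1L
    # balanced planted partition for the usage patterns: equal block sizes,
    # randomly permuted over subjects
    sp_cluster <- sample(rep_len(seq_len(config$n_spread_clusters) - 1L, n))

    ## --- fatty-acid intakes: exp(MVN), cluster mean shifts on a fixed subset
    n_affected <- min(8L, p)
    delta <- matrix(0, config$n_fa_clusters, p)
    for (c in seq_len(config$n_fa_clusters)) {
      idx <- sample.int(p, n_affected)
      delta[c, idx] <- sample(c(-1, 1), n_affected, TRUE) *
        config$cluster_separation * config$fa_log_sd[idx]
    }
    mu0 <- fa_log_means(p)
    vis <- two_visit_mvn(n, p, chol_R, rho)
    sdmat <- matrix(config$fa_log_sd, n, p, byrow = TRUE)
    mu <- matrix(mu0, n, p, byrow = TRUE) + delta[fa_cluster + 1L, , drop = FALSE]
    fa1 <- exp(mu + sdmat * vis$v1)
    fa2 <- exp(mu + sdmat * vis$v2)

    ## --- spread intakes: structural zeros outside the cluster's support
    k <- config$n_spread_types
    pats <- spread_patterns(config$n_spread_clusters, k)
    # usage level differs by cluster (moderate vs high users of the same
    # spread are distinct patterns, as in real spread data)
    sp_levels <- c(6, 25, 12)
    sp_log_sd <- 0.15
    spv <- two_visit_mvn(n, k, diag(k), rho)
    sp1 <- sp2 <- matrix(0, n, k)
    for (c in seq_len(config$n_spread_clusters)) {
      rows <- which(sp_cluster == c - 1L)
      used <- pats[[c]]
      if (length(rows) && length(used)) {
        gm <- log(sp_levels[(c %% length(sp_levels)) + 1L])
        sp1[rows, used] <- exp(gm + sp_log_sd * spv$v1[rows, used])
        sp2[rows, used] <- exp(gm + sp_log_sd * spv$v2[rows, used])
      }
    }
    none1 <- as.integer(rowSums(sp1) == 0)
    none2 <- as.integer(rowSums(sp2) == 0)

    ## --- planted outcome effects per subject
    eff <- matrix(0, n, length(OUTCOME_SCALES),
                  dimnames = list(NULL, names(OUTCOME_SCALES)))
    et <- config$effect_table
    if (!is.null(et)) {
      for (i in seq_len(nrow(et))) {
        lab <- if (et$exposure[i] == "fa") fa_cluster else sp_cluster
        rows <- lab == et$cluster[i]
        if (et$sex[i] != "both") rows <- rows & (sex == et$sex[i])
        eff[rows, et$outcome[i]] <- eff[rows, et$outcome[i]] + et$effect[i]
      }
    }

    ## --- blood pressure: 6 seated readings per visit; first reading runs high
    sbp_base <- unname(config$sbp_mean[ifelse(sex == "male", "male", "female")])
    u_sbp <- stats::rnorm(n, 0, 7)
    u_dbp <- stats::rnorm(n, 0, 4.5)
    sbp_true <- cbind(sbp_base + eff[, "sbp"] + u_sbp + stats::rnorm(n, 0, 8.5),
                      sbp_base + 1.7 + eff[, "sbp"] + u_sbp + stats::rnorm(n, 0, 8.5))
    dbp_true <- cbind(65.5 + eff[, "dbp"] + u_dbp + stats::rnorm(n, 0, 5.5),
                      67.0 + eff[, "dbp"] + u_dbp + stats::rnorm(n, 0, 5.5))
    readings <- function(truth) {
      # column r1 carries the settling-in (alerting) offset the averaging drops
      sapply(1:6, function(r) truth + (r == 1) * 6 + stats::rnorm(n, 0, 4))
    }
    sbp_r <- list(readings(sbp_true[, 1]), readings(sbp_true[, 2]))
    dbp_r <- list(readings(dbp_true[, 1]), readings(dbp_true[, 2]))

    ## --- log-scale outcomes with within-subject correlation
    log_out <- function(mlog1, mlog2, sdlog, effcol, rho_o = 0.6) {
      u <- stats::rnorm(n, 0, sdlog * sqrt(rho_o))
      e1 <- stats::rnorm(n, 0, sdlog * sqrt(1 - rho_o))
      e2 <- stats::rnorm(n, 0, sdlog * sqrt(1 - rho_o))
      cbind(exp(mlog1 + effcol + u + e1), exp(mlog2 + effcol + u + e2))
    }
    trig <- log_out(log(0.98), log(1.00), 0.42, eff[, "trig"])
    hdl_m <- ifelse(sex == "male", log(1.22), log(1.43))
    hdl_sd <- ifelse(sex == "male", 0.185, 0.25)
    u_h <- stats::rnorm(n, 0, 1)
    hdl <- cbind(exp(hdl_m + eff[, "hdl"] + hdl_sd * (sqrt(0.6) * u_h + sqrt(0.4) * stats::rnorm(n))),
                 exp(hdl_m + 0.015 + eff[, "hdl"] + hdl_sd * (sqrt(0.6) * u_h + sqrt(0.4) * stats::rnorm(n))))
    # total cholesterol = HDL + non-HDL so the derived non-HDL is never
    # negative; the planted chol effect scales the total multiplicatively
    nonhdl <- log_out(log(2.91), log(3.17), 0.235, 0)
    chol_ <- (hdl + nonhdl) * exp(eff[, "chol"])
    glucose <- log_out(log(4.7), log(4.7), 0.075, eff[, "glucose"])
    insulin <- log_out(log(7.5), log(7.5), 0.45, eff[, "insulin"])

    ## --- subject-level covariates
    age20 <- stats::rnorm(n, 19.95, 0.42)
    age22 <- age20 + stats::rnorm(n, 2.16, 0.30)
    whr <- stats::rnorm(n, ifelse(sex == "male", 0.84, 0.77), 0.06)
    family_history <- as.integer(stats::runif(n) < 0.311)
    western <- stats::rnorm(n, ifelse(sex == "male", 0.26, -0.36),
                            ifelse(sex == "male", 0.83, 0.68))
    healthy <- stats::rnorm(n, ifelse(sex == "male", 0.01, 0.13),
                            ifelse(sex == "male", 0.92, 0.89))
    fruit <- sample(0:4, n, TRUE, c(0.02, 0.05, 0.16, 0.37, 0.40))
    vegetable <- sample(0:4, n, TRUE, c(0.01, 0.02, 0.09, 0.33, 0.55))
    alcohol <- ifelse(stats::runif(n) < 0.25, 0,
                      exp(stats::rnorm(n, log(12), 0.9)))
    sodium <- pmax(300, stats::rnorm(n, ifelse(sex == "male", 3441, 2530),
                                     ifelse(sex == "male", 1245, 999)))
    smoking <- as.integer(stats::runif(n) < 0.143)
    mets <- exp(stats::rnorm(n, log(1200), 0.8))
    pa_category <- sample(0:2, n, TRUE, c(0.25, 0.45, 0.30))

    cov_tab <- data.frame(whr = whr, family_history = family_history,
                          healthy_score = healthy, western_score = western,
                          fruit = fruit, vegetable = vegetable,
                          alcohol = alcohol, sodium = sodium,
                          smoking = smoking, mets = mets,
                          pa_category = pa_category)

    ## --- MAR missingness given sex and (always observed) mean SBP
    mean_sbp <- rowMeans(cbind(rowMeans(sbp_r[[1]][, 2:6]),
                               rowMeans(sbp_r[[2]][, 2:6])))
    lp <- 0.6 * as.numeric(scale(mean_sbp)) + 0.5 * (sex == "male")
    for (v in names(config$missing_rates)) {
      miss <- mar_indicator(config$missing_rates[[v]], lp)
      cov_tab[[v]][miss] <- NA
    }

    ## --- assemble long table (visit rows interleaved per subject)
    mk_visit <- function(vidx, fa, sp, none, sbp6, dbp6, age) {
      d <- data.frame(subject_id = seq_len(n),
                      visit = c("age20", "age22")[vidx],
                      sex = sex, age = age,
                      stringsAsFactors = FALSE)
      fa <- as.data.frame(fa); names(fa) <- fa_colnames(p)
      sp <- as.data.frame(sp); names(sp) <- spread_colnames(k)
      sbp6 <- as.data.frame(sbp6); names(sbp6) <- paste0("sbp_r", 1:6)
      dbp6 <- as.data.frame(dbp6); names(dbp6) <- paste0("dbp_r", 1:6)
      cbind(d, fa, sp, None = none, sbp6, dbp6,
            data.frame(trig = trig[, vidx], chol = chol_[, vidx],
                       hdl = hdl[, vidx], glucose = glucose[, vidx],
                       insulin = insulin[, vidx]),
            cov_tab,
            data.frame(true_fa_cluster = fa_cluster,
                       true_spread_cluster = sp_cluster))
    }
    tab <- rbind(mk_visit(1, fa1, sp1, none1, sbp_r[[1]], dbp_r[[1]], age20),
                 mk_visit(2, fa2, sp2, none2, sbp_r[[2]], dbp_r[[2]], age22))
    tab <- tab[order(tab$subject_id, tab$visit), ]
    rownames(tab) <- NULL
    attr(tab, "config") <- config
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

#' Planted cluster labels of a generated cohort
#'
#' Returns the generator's ground-truth labels (one per subject) for recovery
#' scoring against detected communities.
#'
#' @param cohort a `cohort_table` from [generate_cohort()].
#' @param which `"fatty_acids"` or `"spreads"`.
#' @return named integer vector, one label per subject (names = subject ids).
#' @export
planted_truth <- function(cohort, which = c("fatty_acids", "spreads")) {
  which <- match.arg(which)
  col <- if (which == "fatty_acids") "true_fa_cluster" else "true_spread_cluster"
  if (!col %in% names(cohort)) {
    stopf("cohort carries no planted labels (column '%s' missing)", col)
  }
  first <- !duplicated(cohort$subject_id)
  stats::setNames(cohort[[col]][first], cohort$subject_id[first])
}

#' Write / read the cohort CSV contract
#'
#' `write_cohort()` writes the long-format table as CSV together with a JSON
#' sidecar (column dictionary + generator config echo) for provenance;
#' `read_cohort()` reads it back.
#'
#' @param cohort a `cohort_table`.
#' @param path CSV file path; the sidecar is written as `<path>.meta.json`.
#' @return `write_cohort()` the path invisibly; `read_cohort()` a
#'   `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  cfg <- attr(cohort, "config")
  meta <- list(columns = names(cohort),
               n_subjects = length(unique(cohort$subject_id)),
               config = if (!is.null(cfg)) {
                 cfg$fa_corr <- cfg$fa_sigma <- NULL
                 unclass(cfg)
               })
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
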