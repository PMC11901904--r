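#' @title Pipeline orchestration and descriptive reporting
#' @description One-call orchestration of the full analysis — generate or
#'   load a cohort, derive outcomes, run the two clustering passes (fatty
#'   acids; spreads), cross-tabulate them, impute covariates and fit the
#'   pooled association models — plus Table-1-style cohort description and
#'   per-cluster intake profiles.
#' @name pipeline
NULL

DESCRIBE_TYPES <- c(
  age = "normal", whr = "normal", derived_sbp = "normal",
  derived_dbp = "normal", derived_pp = "normal", trig = "skewed",
  chol = "normal", hdl = "normal", derived_non_hdl = "normal",
  glucose = "skewed", insulin = "skewed", derived_homa_ir = "skewed",
  healthy_score = "normal", western_score = "normal", sodium = "normal",
  alcohol = "skewed", mets = "skewed", fruit = "skewed",
  vegetable = "skewed", family_history = "categorical",
  smoking = "categorical", pa_category = "categorical")

#' Run the full dietary-pattern analysis pipeline
#'
#' generate/load -> derive -> K-NN + Louvain on fatty acids and on spreads ->
#' cross-tabulate the two partitions (chi-square association) -> impute
#' covariates -> fit and pool the association models -> cluster profiles.
#' All randomness flows from `seed` through named sub-streams, so a fixed
#' seed and config reproduce the result bundle byte for byte.
#'
#' @param config a [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort optionally a pre-built `cohort_table` (e.g. [read_cohort()]).
#' @param k neighbours for the K-NN graphs (default 20).
#' @param gamma Louvain resolution (default 1).
#' @param m_imputations completed datasets for MICE (default 20).
#' @param outcomes outcome names to model (see [model_spec()]).
#' @param models `"model1"` (unadjusted) and/or `"model2"` (adjusted).
#' @param fa_reference optional fatty-acid reference cluster id; default is
#'   the largest cluster after size relabelling (id 0).
#' @param spread_reference optional spread reference cluster id; default is
#'   the detected cluster with the highest share of spread-free visits (the
#'   "no spreads" pattern).
#' @param outdir optional directory; when given, partitions, edge lists,
#'   profiles, results and a provenance file are written there as CSV/JSON.
#' @param seed master seed (default: the config's seed).
#' @return a `dietnet_run` bundle: list with `cohort`, `partitions`
#'   (`$fa`, `$spread`), `graphs`, `crosstab`, `stack`, `results`,
#'   `profiles`, `seed`.
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         k = 20, gamma = 1, m_imputations = 20,
                         outcomes = c("sbp", "dbp", "pp", "trig", "chol",
                                      "hdl", "non_hdl", "homa_ir"),
                         models = c("model1", "model2"),
                         fa_reference = NULL, spread_reference = NULL,
                         outdir = NULL, seed = NULL) {
  if (is.null(cohort)) {
    stopifnot(inherits(config, "cohort_config"))
    cohort <- generate_cohort(config)
  }
  seed <- seed %||% (attr(cohort, "config")$seed %||% 1L)
  cohort <- derive_outcomes(cohort)

  fa_mat <- build_intake_matrix(cohort, "fatty_acids")
  sp_mat <- build_intake_matrix(cohort, "spreads")
  fa_graph <- build_knn_graph(fa_mat, k = k)
  sp_graph <- build_knn_graph(sp_mat, k = k)
  fa_part <- relabel_by_size(louvain(fa_graph, gamma = gamma,
                                     seed = sub_seed(seed, "louvain_fa")))
  sp_part <- relabel_by_size(louvain(sp_graph, gamma = gamma,
                                     seed = sub_seed(seed, "louvain_spread")))

  crosstab <- cross_tab_clusters(fa_part, sp_part)

  ## attach detected cluster factors (subject-level) with chosen references
  ids <- as.character(cohort$subject_id)
  fa_lab <- fa_part$membership[ids]
  sp_lab <- sp_part$membership[ids]
  if (is.null(spread_reference)) {
    none_share <- tapply(cohort$None, sp_lab, mean)
    spread_reference <- as.integer(names(none_share)[which.max(none_share)])
  }
  fa_reference <- fa_reference %||% 0L
  cohort$fa_cluster <- stats::relevel(factor(fa_lab),
                                      ref = as.character(fa_reference))
  cohort$spread_cluster <- stats::relevel(factor(sp_lab),
                                          ref = as.character(spread_reference))

  stack <- impute(cohort, imputation_spec(m = m_imputations,
                                          seed = sub_seed(seed, "mice")))
  specs <- list()
  for (mo in models) for (oc in outcomes) {
    specs[[length(specs) + 1L]] <- model_spec(oc, model = mo)
  }
  results <- run_analysis(stack, specs)

  profiles <- list(fa = profile_clusters(fa_mat, fa_part),
                   spread = profile_clusters(sp_mat, sp_part))

  bundle <- structure(list(cohort = cohort,
                           graphs = list(fa = fa_graph, spread = sp_graph),
                           partitions = list(fa = fa_part, spread = sp_part),
                           crosstab = crosstab, stack = stack,
                           results = results, profiles = profiles,
                           seed = seed,
                           references = c(fa = fa_reference,
                                          spread = spread_reference)),
                      class = "dietnet_run")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' @export
print.dietnet_run <- function(x, ...) {
  cat("dietnet_run\n")
  cat(sprintf("  fatty acids : %d clusters, Q = %.3f\n",
              x$partitions$fa$n_communities, x$partitions$fa$q))
  cat(sprintf("  fat spreads : %d clusters, Q = %.3f\n",
              x$partitions$spread$n_communities, x$partitions$spread$q))
  cat(sprintf("  cross-tab   : chi-square = %.1f, %d df, p %s\n",
              x$crosstab$statistic, x$crosstab$df,
              format.pval(x$crosstab$p, digits = 3)))
  cat(sprintf("  models      : %d pooled contrasts, %d under a passing gate\n",
              nrow(x$results), sum(x$results$gate_passed)))
  invisible(x)
}

#' Cross-tabulate two partitions with a chi-square association test
#'
#' @param p1,p2 `louvain_partition` objects over the same subjects.
#' @return list with `table`, `statistic`, `df` (= (k1-1)(k2-1)), `p`.
#' @export
cross_tab_clusters <- function(p1, p2) {
  ids <- intersect(names(p1$membership), names(p2$membership))
  if (!length(ids)) stopf("partitions share no subjects")
  tab <- table(fa = p1$membership[ids], spread = p2$membership[ids])
  ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ch$statistic),
       df = unname(ch$parameter), p = ch$p.value)
}

#' Table-1-style cohort description with sex comparisons
#'
#' Summarizes each variable per sex (mean +/- SD for variables declared
#' normal, median and IQR for skewed ones, counts for categorical ones) and
#' tests the sex difference with Welch's t test, the Mann-Whitney U test, or
#' the (uncorrected) chi-square test respectively.
#'
#' @param cohort a `cohort_table` (derived columns added if absent).
#' @param visit `"age20"`, `"age22"` or `"both"`.
#' @param types named character vector variable -> `normal` / `skewed` /
#'   `categorical`; defaults cover the standard panel.
#' @return data.frame: variable, type, per-sex summary strings, test, p.
#' @export
describe_cohort <- function(cohort, visit = "age20", types = DESCRIBE_TYPES) {
  if (!"derived_sbp" %in% names(cohort) &&
      all(paste0("sbp_r", 1:6) %in% names(cohort))) {
    cohort <- derive_outcomes(cohort)
  }
  d <- if (visit == "both") cohort else cohort[cohort$visit == visit, ]
  vars <- intersect(names(types), names(d))
  out <- lapply(vars, function(v) {
    x <- d[[v]]; sex <- d$sex
    xm <- x[sex == "male"]; xf <- x[sex == "female"]
    type <- types[[v]]
    if (type == "normal") {
      sm <- function(z) sprintf("%.2f ± %.2f", mean(z, na.rm = TRUE),
                                stats::sd(z, na.rm = TRUE))
      p <- tryCatch(stats::t.test(xm, xf)$p.value, error = function(e) NA)
      test <- "t"
    } else if (type == "skewed") {
      sm <- function(z) {
        q <- stats::quantile(z, c(0.25, 0.5, 0.75), na.rm = TRUE)
        sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
      }
      p <- tryCatch(stats::wilcox.test(xm, xf, exact = FALSE)$p.value,
                    error = function(e) NA)
      test <- "mann-whitney"
    } else {
      sm <- function(z) paste(names(table(z)), table(z), sep = ":",
                              collapse = " ")
      tab <- table(x, sex)
      p <- tryCatch(suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value),
        error = function(e) NA)
      test <- "chi-square"
    }
    data.frame(variable = v, type = type, all = sm(x), male = sm(xm),
               female = sm(xf), test = test, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-cluster intake profiles
#'
#' Standardized and raw mean intake of every variable within each detected
#' cluster, with a one-way ANOVA p-value per variable for differences across
#' clusters. The long output is plot-ready (one row per cluster x variable).
#'
#' @param matrix the `intake_matrix` that was clustered (standardized).
#' @param partition the `louvain_partition` over its rows.
#' @return a `cluster_profile` data.frame: `cluster`, `size`, `variable`,
#'   `mean_std`, `mean_raw`, `p_across_clusters`.
#' @export
profile_clusters <- function(matrix, partition) {
  memb <- if (inherits(partition, "louvain_partition")) {
    partition$membership
  } else partition
  ids <- rownames(matrix)
  if (!all(names(memb) %in% ids)) {
    stopf("partition references subjects absent from the matrix: %s",
          paste(utils::head(setdiff(names(memb), ids), 5), collapse = ", "))
  }
  z <- unclass(matrix)[names(memb), , drop = FALSE]
  raw <- if (!is.null(attr(matrix, "center"))) {
    destandardize(matrix)[names(memb), , drop = FALSE]
  } else z
  cl <- factor(memb)
  sizes <- table(cl)
  pvals <- if (nlevels(cl) < 2) {
    rep(NA_real_, ncol(z))
  } else {
    apply(z, 2, function(col) {
      # a structurally separated column fits perfectly; its p is effectively 0
      suppressWarnings(stats::anova(stats::lm(col ~ cl))[["Pr(>F)"]][1])
    })
  }
  mean_std <- rowsum(z, cl) / as.vector(sizes)
  mean_raw <- rowsum(raw, cl) / as.vector(sizes)
  out <- data.frame(
    cluster = rep(as.integer(levels(cl)), times = ncol(z)),
    size = rep(as.integer(sizes), times = ncol(z)),
    variable = rep(colnames(z), each = nlevels(cl)),
    mean_std = as.vector(mean_std),
    mean_raw = as.vector(mean_raw),
    p_across_clusters = rep(unname(pvals), each = nlevels(cl)),
    stringsAsFactors = FALSE)
  class(out) <- c("cluster_profile", "data.frame")
  out
}

#' Write a result bundle to disk
#'
#' Emits `partition_fa.csv`, `partition_spread.csv`, `edges_fa.csv`,
#' `edges_spread.csv`, `results.csv`, `profile_fa.csv`, `profile_spread.csv`,
#' `crosstab.csv` and `provenance.json` (config echo, seed, package version).
#' Deterministic: identical bundles produce identical bytes.
#'
#' @param bundle a `dietnet_run`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_partition(bundle$partitions$fa, fp("partition_fa.csv"), "FA")
  write_partition(bundle$partitions$spread, fp("partition_spread.csv"), "S")
  utils::write.csv(graph_edgelist(bundle$graphs$fa), fp("edges_fa.csv"),
                   row.names = FALSE)
  utils::write.csv(graph_edgelist(bundle$graphs$spread),
                   fp("edges_spread.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$results), fp("results.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$profiles$fa), fp("profile_fa.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$profiles$spread),
                   fp("profile_spread.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$crosstab$table), fp("crosstab.csv"),
                   row.names = FALSE)
  cfg <- attr(bundle$cohort, "config")
  prov <- list(seed = bundle$seed,
               package_version = as.character(utils::packageVersion("dietnet")),
               fa = list(n_communities = bundle$partitions$fa$n_communities,
                         modularity = bundle$partitions$fa$q),
               spread = list(n_communities = bundle$partitions$spread$n_communities,
                             modularity = bundle$partitions$spread$q),
               references = as.list(bundle$references),
               config = if (!is.null(cfg)) {
                 cfg$fa_corr <- cfg$fa_sigma <- cfg$effect_table <- NULL
                 unclass(cfg)
               })
  jsonlite::write_json(prov, fp("provenance.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(outdir)
}
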