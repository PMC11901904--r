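#' @title Derived outcome and exposure measures
#' @description Blood-pressure averaging (discarding the first seated
#'   reading), HOMA-IR, non-HDL cholesterol, hypertension staging,
#'   visit-averaged intake matrices and their standardization.
#' @name derive
NULL

#' Average a six-reading blood pressure panel
#'
#' Seated clinic BP is recorded six times, two minutes apart; the first
#' reading is systematically elevated (settling-in effect) and is discarded.
#' The mean of readings 2-6 is the analysis value.
#'
#' @param readings numeric vector of exactly 6 readings, in time order.
#' @return arithmetic mean of readings 2 through 6 (mmHg).
#' @export
average_bp <- function(readings) {
  if (length(readings) != 6L) {
    stopf("expected exactly 6 readings, got %d", length(readings))
  }
  if (any(!is.finite(readings)) || any(readings <= 0)) {
    stopf("readings must be positive and finite")
  }
  mean(readings[2:6])
}

#' HOMA-IR insulin-resistance index
#'
#' @param insulin fasting insulin, mU/L (> 0).
#' @param glucose fasting plasma glucose, mmol/L (> 0).
#' @return insulin x glucose / 22.5 (dimensionless). Vectorized.
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(!is.finite(insulin)) || any(!is.finite(glucose)) ||
      any(insulin <= 0) || any(glucose <= 0)) {
    stopf("insulin and glucose must be positive")
  }
  insulin * glucose / 22.5
}

#' Non-HDL cholesterol
#'
#' @param total_chol total cholesterol, mmol/L.
#' @param hdl HDL cholesterol, mmol/L; must not exceed `total_chol`.
#' @return total minus HDL, mmol/L. Vectorized.
#' @export
non_hdl <- function(total_chol, hdl) {
  if (any(hdl < 0) || any(total_chol < hdl)) {
    stopf("need total_chol >= hdl >= 0")
  }
  total_chol - hdl
}

#' Hypertension stage from mean clinic pressures
#'
#' Stage 2: SBP >= 140 or DBP >= 90; stage 1: SBP in 130-139.99 or DBP in
#' 80-89.99; otherwise none.
#'
#' @param sbp,dbp mean systolic / diastolic pressure, mmHg (> 0). Vectorized.
#' @return character vector in `{"none","stage1","stage2"}`.
#' @export
stage_hypertension <- function(sbp, dbp) {
  if (any(sbp <= 0) || any(dbp <= 0)) stopf("pressures must be positive")
  ifelse(sbp >= 140 | dbp >= 90, "stage2",
         ifelse(sbp >= 130 | dbp >= 80, "stage1", "none"))
}

#' Append derived outcome columns to a cohort table
#'
#' Adds, per visit row: `derived_sbp` / `derived_dbp` (mean of readings 2-6),
#' `derived_pp` (pulse pressure, SBP - DBP), `derived_homa_ir`,
#' `derived_non_hdl` and `derived_ht_stage`.
#'
#' @param cohort a `cohort_table` (or any data.frame with the outcome panel
#'   columns `sbp_r1..6`, `dbp_r1..6`, `trig`, `chol`, `hdl`, `glucose`,
#'   `insulin`).
#' @return the table with `derived_` columns appended.
#' @export
derive_outcomes <- function(cohort) {
  sbp_cols <- paste0("sbp_r", 1:6)
  dbp_cols <- paste0("dbp_r", 1:6)
  if (!all(c(sbp_cols, dbp_cols) %in% names(cohort))) {
    stopf("cohort lacks the six-reading BP panel columns")
  }
  cohort$derived_sbp <- rowMeans(as.matrix(cohort[sbp_cols])[, 2:6, drop = FALSE])
  cohort$derived_dbp <- rowMeans(as.matrix(cohort[dbp_cols])[, 2:6, drop = FALSE])
  cohort$derived_pp <- cohort$derived_sbp - cohort$derived_dbp
  cohort$derived_homa_ir <- homa_ir(cohort$insulin, cohort$glucose)
  cohort$derived_non_hdl <- non_hdl(cohort$chol, cohort$hdl)
  cohort$derived_ht_stage <- stage_hypertension(cohort$derived_sbp,
                                                cohort$derived_dbp)
  cohort
}

#' Build the subject-by-intake matrix used for neighbour search
#'
#' Averages each intake over the subject's two visits, then z-standardizes
#' each column (zero mean, unit SD). For the spread variables the default
#' layout keeps the two visits as separate columns (5 spread intakes plus the
#' "no spread" indicator per visit, 12 columns in total); `layout =
#' "averaged"` collapses them to 6 visit-averaged columns.
#'
#' @param cohort a `cohort_table` with two rows per subject.
#' @param variable_set `"fatty_acids"` or `"spreads"`.
#' @param standardize z-score columns (default TRUE). Raw g/day when FALSE.
#' @param layout spreads only: `"age_specific"` (default, 12 columns) or
#'   `"averaged"` (6 columns).
#' @return an `intake_matrix`: numeric matrix, one row per subject (rownames =
#'   subject ids), with attributes `center`/`scale` when standardized.
#' @export
build_intake_matrix <- function(cohort,
                                variable_set = c("fatty_acids", "spreads"),
                                standardize = TRUE,
                                layout = c("age_specific", "averaged")) {
  variable_set <- match.arg(variable_set)
  layout <- match.arg(layout)
  counts <- table(cohort$subject_id)
  bad <- names(counts)[counts != 2L]
  if (length(bad)) {
    stopf("subjects without exactly 2 visits: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  ord <- order(cohort$subject_id, cohort$visit)
  cohort <- cohort[ord, ]
  ids <- unique(cohort$subject_id)
  v1 <- cohort[seq(1, nrow(cohort), by = 2), ]
  v2 <- cohort[seq(2, nrow(cohort), by = 2), ]

  if (variable_set == "fatty_acids") {
    cols <- intersect(c(FA_NAMES, grep("^fa_\\d", names(cohort), value = TRUE)),
                      names(cohort))
    if (!length(cols)) stopf("no fatty-acid intake columns found")
    m <- (as.matrix(v1[cols]) + as.matrix(v2[cols])) / 2
  } else {
    cols <- intersect(c(SPREAD_NAMES, grep("^spread_\\d", names(cohort),
                                           value = TRUE)), names(cohort))
    if (!length(cols)) stopf("no spread intake columns found")
    cols <- c(cols, "None")
    if (layout == "age_specific") {
      m <- cbind(as.matrix(v1[cols]), as.matrix(v2[cols]))
      colnames(m) <- c(paste0(cols, "_age20"), paste0(cols, "_age22"))
    } else {
      m <- (as.matrix(v1[cols]) + as.matrix(v2[cols])) / 2
    }
  }
  rownames(m) <- ids
  if (standardize) {
    ctr <- colMeans(m)
    scl <- apply(m, 2, stats::sd)
    if (any(scl == 0)) {
      stopf("cannot standardize zero-variance column(s): %s",
            paste(colnames(m)[scl == 0], collapse = ", "))
    }
    m <- scale(m, center = ctr, scale = scl)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
    attr(m, "center") <- ctr
    attr(m, "scale") <- scl
  }
  class(m) <- c("intake_matrix", class(m))
  m
}

#' Undo the z-standardization of an intake matrix
#'
#' @param matrix an `intake_matrix` with `center`/`scale` attributes.
#' @return matrix on the raw g/day scale.
#' @export
destandardize <- function(matrix) {
  ctr <- attr(matrix, "center")
  scl <- attr(matrix, "scale")
  if (is.null(ctr) || is.null(scl)) stopf("matrix was not standardized")
  out <- sweep(sweep(unclass(matrix), 2, scl, "*"), 2, ctr, "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}
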