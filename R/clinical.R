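# Screening rules and clinical correlation analysis.
#
# Eligibility mirrors the study's screening: exclude cognitive impairment
# (MMSE < 24) and clinically relevant anxiety or depression (HAMA > 14,
# HAMD > 17). Patients are split by subjective sleep quality: PSQI >= 6 is
# poor sleep (SleET), PSQI < 6 normal sleep (NorET). Associations between
# network metrics and clinical scores use partial correlations adjusted
# for age, sex, education, HAMA and HAMD.

#' Screening rule thresholds
#'
#' @param psqi_poor_sleep_min minimum PSQI defining poor sleep (default 6).
#' @param mmse_exclude_below exclude when MMSE is strictly below this
#'   (default 24).
#' @param hama_exclude_above exclude when HAMA is strictly above this
#'   (default 14).
#' @param hamd_exclude_above exclude when HAMD is strictly above this
#'   (default 17).
#' @return object of class `eligibility_rules`.
#' @export
eligibility_rules <- function(psqi_poor_sleep_min = 6,
                              mmse_exclude_below = 24,
                              hama_exclude_above = 14,
                              hamd_exclude_above = 17) {
  .check_scalar(psqi_poor_sleep_min, "psqi_poor_sleep_min", 0, 21)
  .check_scalar(mmse_exclude_below, "mmse_exclude_below", 0, 30)
  .check_scalar(hama_exclude_above, "hama_exclude_above", 0, 56)
  .check_scalar(hamd_exclude_above, "hamd_exclude_above", 0, 76)
  structure(list(psqi_poor_sleep_min = psqi_poor_sleep_min,
                 mmse_exclude_below = mmse_exclude_below,
                 hama_exclude_above = hama_exclude_above,
                 hamd_exclude_above = hamd_exclude_above),
            class = "eligibility_rules")
}

#' Apply screening rules to one subject record
#'
#' @param record list or one-row data.frame with numeric `MMSE`, `HAMA`
#'   and `HAMD` entries.
#' @param rules an [eligibility_rules()].
#' @return list with `include` (logical) and `reason` (`NA` when
#'   included; otherwise `"cognition"`, `"anxiety"` or `"depression"`,
#'   first matching rule in that order).
#' @export
apply_eligibility <- function(record, rules = eligibility_rules()) {
  stopifnot(inherits(rules, "eligibility_rules"))
  for (f in c("MMSE", "HAMA", "HAMD")) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      stop("missing score required for eligibility: ", f)
    }
  }
  if (record[["MMSE"]] < rules$mmse_exclude_below) {
    return(list(include = FALSE, reason = "cognition"))
  }
  if (record[["HAMA"]] > rules$hama_exclude_above) {
    return(list(include = FALSE, reason = "anxiety"))
  }
  if (record[["HAMD"]] > rules$hamd_exclude_above) {
    return(list(include = FALSE, reason = "depression"))
  }
  list(include = TRUE, reason = NA_character_)
}

#' Classify sleep quality group from the PSQI total
#'
#' @param psqi PSQI total score in `[0, 21]` (vectorized).
#' @param rules an [eligibility_rules()].
#' @return `"SleET"` for PSQI at or above the poor-sleep minimum,
#'   `"NorET"` below it.
#' @export
classify_sleep_group <- function(psqi, rules = eligibility_rules()) {
  stopifnot(inherits(rules, "eligibility_rules"))
  if (any(!is.finite(psqi)) || any(psqi < 0 | psqi > 21)) {
    stop("PSQI scores must lie in [0, 21]")
  }
  ifelse(psqi >= rules$psqi_poor_sleep_min, "SleET", "NorET")
}

#' Partial correlation with covariate adjustment
#'
#' Residualizes `x` and `y` on the covariates (least squares with an
#' intercept; factors and character covariates are expanded to indicator
#' columns), correlates the residuals, and tests
#' `t = r * sqrt((n - k - 2) / (1 - r^2))` against a t distribution with
#' `n - k - 2` degrees of freedom (two-sided), `k` being the number of
#' covariate columns after expansion. With no covariates this reduces to
#' the ordinary Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame, matrix or NULL.
#' @return object of class `correlation_result`: `r`, `p`, `n`, `df`,
#'   `covariates` (column names used).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite")
  }
  if (is.null(covariates) || (!is.null(ncol(covariates)) &&
                              ncol(covariates) == 0)) {
    Z <- matrix(1, n, 1)
    cov_names <- character(0)
  } else {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != n) stop("covariates must have one row per case")
    Z <- stats::model.matrix(~ ., data = covariates)
    cov_names <- colnames(Z)[-1]
  }
  k <- ncol(Z) - 1
  if (n <= k + 2) {
    stop("need n > k + 2 cases (n = ", n, ", covariates = ", k, ")")
  }
  if (qr(Z)$rank < ncol(Z)) stop("rank-deficient covariates")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  # residuals of a (near-)perfect fit are numerical noise, not signal
  degen <- function(res, v) {
    stats::sd(res) <= 1e-10 * max(stats::sd(v), abs(mean(v)),
                                  .Machine$double.xmin)
  }
  if (degen(rx, x) || degen(ry, y)) {
    stop("constant residuals: correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, p = p, n = n, df = df, t = tval,
                 covariates = cov_names),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("partial correlation: r = %.3f, p = %.4g (n = %d, df = %d)\n",
              x$r, x$p, x$n, x$df))
  invisible(x)
}

#' Correlate nodal AUC metrics with clinical variables
#'
#' Computes the covariate-adjusted partial correlation for every
#' requested (region metric, clinical variable) pair within one group.
#' All raw p-values are reported; no multiplicity correction is applied
#' to this exploratory grid.
#'
#' @param auc_nodal matrix of nodal AUC values (subjects x columns named
#'   `metric|region`).
#' @param cohort_table clinical data.frame with a `group` column aligned
#'   to the AUC rows.
#' @param group group to analyze (default `"SleET"`).
#' @param metrics columns of `auc_nodal` to use (default all).
#' @param variables clinical columns to correlate (default `TRS`, `PSQI`,
#'   `onset_age`, `duration`).
#' @param covariate_cols adjustment covariates (default age, sex,
#'   education, HAMA, HAMD).
#' @return data.frame (metric, variable, r, p, n).
#' @export
clinical_correlations <- function(auc_nodal, cohort_table,
                                  group = "SleET", metrics = NULL,
                                  variables = c("TRS", "PSQI",
                                                "onset_age", "duration"),
                                  covariate_cols = c("age", "sex",
                                                     "education", "HAMA",
                                                     "HAMD")) {
  auc_nodal <- as.matrix(auc_nodal)
  if (nrow(auc_nodal) != nrow(cohort_table)) {
    stop("AUC rows must align with the cohort table")
  }
  sel <- cohort_table$group == group
  if (sum(sel) < length(covariate_cols) + 4) {
    stop("too few subjects in group ", group)
  }
  if (is.null(metrics)) metrics <- colnames(auc_nodal)
  rows <- list()
  for (m in metrics) {
    for (v in variables) {
      yv <- cohort_table[[v]][sel]
      ok <- is.finite(yv)
      if (sum(ok) <= length(covariate_cols) + 2) next
      res <- partial_correlation(
        auc_nodal[sel, m][ok], yv[ok],
        covariates = cohort_table[sel, covariate_cols, drop = FALSE][ok, ,
                                                                     drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, variable = v, r = res$r, p = res$p, n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
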