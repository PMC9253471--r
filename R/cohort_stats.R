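#' Z-score a numeric vector
#'
#' Subtracts the mean and divides by the sample SD (n-1 denominator).
#'
#' @param values Numeric vector, length >= 2, nonzero variance.
#' @return Standardized vector (mean 0, sample SD 1).
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-score")
  (values - mean(values)) / s
}

#' Classify EDSS change between baseline and follow-up
#'
#' Clinical change rules on the 0-10 half-point EDSS grid:
#' worsening is an increase of at least 1.0 from a baseline of 5.0 or
#' below, or at least 0.5 from a baseline of 5.5 or above; improvement is a
#' decrease of at least 1.0 from a baseline of 5.0 or below, or at least
#' 0.5 from a baseline above 5.0; stable is a baseline of 5.0 or below with
#' a change of at most 0.5 in either direction. Grid cells the rules leave
#' uncovered (e.g. a high baseline with no change) are labelled
#' `"unclassified"` rather than silently binned.
#'
#' @param baseline,followup EDSS scores on the half-point grid (vectorised).
#' @return Character vector in
#'   `{worsening, stable, improving, unclassified}`.
#' @export
classify_edss_change <- function(baseline, followup) {
  chk <- c(baseline, followup)
  if (any(chk < 0 | chk > 10 | abs(chk * 2 - round(chk * 2)) > 1e-9))
    stop("EDSS values must lie on the 0-10 half-point grid")
  delta <- followup - baseline
  out <- rep("unclassified", length(delta))
  out[(baseline <= 5.0 & delta >= 1.0) |
        (baseline >= 5.5 & delta >= 0.5)] <- "worsening"
  out[(baseline <= 5.0 & delta <= -1.0) |
        (baseline > 5.0 & delta <= -0.5)] <- "improving"
  out[baseline <= 5.0 & abs(delta) <= 0.5] <- "stable"
  out
}

#' One-pass serum NfL outlier removal
#'
#' Flags values strictly greater than `mean + k * SD` of the full input
#' (one-sided; low values are never removed). A single pass only: the rule
#' is not iterated on the kept set.
#'
#' @param values NfL concentrations (pg/ml), length >= 3.
#' @param k SD multiplier (default 3).
#' @return List with `kept` (values), `removed` (indices into the input),
#'   and `threshold`.
#' @export
remove_nfl_outliers <- function(values, k = 3) {
  if (length(values) < 3L) stop("need at least 3 values")
  thr <- mean(values) + k * stats::sd(values)
  removed <- which(values > thr)
  list(kept = values[setdiff(seq_along(values), removed)],
       removed = removed, threshold = thr)
}

#' GD-T2LV association
#'
#' Pearson correlation between global disconnectome and T2 lesion volume,
#' plus a least-squares quadratic fit of GD on T2LV (the curvature captures
#' the saturating growth of disconnectivity with lesion load).
#'
#' @param records Data.frame with `gd` and `t2lv` columns (>= 3 rows),
#'   typically baseline records.
#' @return List with `r` (Pearson), `coef` (intercept, linear, quadratic),
#'   and the fitted `lm` object.
#' @export
gd_t2lv_association <- function(records) {
  if (nrow(records) < 3L) stop("need at least 3 records")
  if (stats::sd(records$gd) == 0 || stats::sd(records$t2lv) == 0)
    stop("degenerate variance in gd or t2lv")
  r <- stats::cor(records$gd, records$t2lv)
  fit <- stats::lm(gd ~ t2lv + I(t2lv^2), data = records)
  list(r = r, coef = unname(stats::coef(fit)), fit = fit)
}

# shared factor coding: reference levels treatment=none, center=Barcelona,
# phenotype=CIS; levels restricted to those observed
code_factors <- function(df) {
  df$sex <- factor(df$sex, levels = intersect(c("F", "M"), unique(df$sex)))
  df$phenotype <- factor(df$phenotype,
                         levels = intersect(c("CIS", "RRMS", "PMS"),
                                            unique(df$phenotype)))
  df$treatment <- factor(df$treatment,
                         levels = intersect(
                           c("none", "effective", "highly-effective"),
                           unique(df$treatment)))
  cn <- c("Barcelona", "Oslo", "Berlin", "Genoa")
  df$center <- factor(df$center,
                      levels = c(intersect(cn, unique(df$center)),
                                 setdiff(unique(df$center), cn)))
  df
}

coef_table <- function(est, se, df_resid = Inf) {
  tval <- est / se
  if (is.finite(df_resid)) {
    p <- 2 * stats::pt(-abs(tval), df_resid)
    q <- stats::qt(0.975, df_resid)
  } else {
    p <- 2 * stats::pnorm(-abs(tval))
    q <- stats::qnorm(0.975)
  }
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_low = unname(est - q * se), ci_high = unname(est + q * se),
             t = unname(tval), p = unname(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cross-sectional multiple linear model at baseline
#'
#' Ordinary least squares of GD or T2LV on serum NfL, disease duration,
#' age, sex, phenotype, treatment and center, with all continuous variables
#' (and the response) z-scored so coefficients are standardized betas.
#' Reference levels: treatment "none", center "Barcelona", phenotype "CIS".
#'
#' @param records Baseline records (one per subject) with the cohort-table
#'   columns.
#' @param response `"gd"` or `"t2lv"`.
#' @param scale_response Z-score the response too (default TRUE).
#' @return List with `table` (term, estimate, se, ci_low, ci_high, t, p),
#'   `fit` (the `lm`), `n`.
#' @export
fit_cross_sectional <- function(records, response = c("gd", "t2lv"),
                                scale_response = TRUE) {
  response <- match.arg(response)
  df <- code_factors(records)
  df$.y <- if (scale_response) zscore(df[[response]]) else df[[response]]
  df$snfl_z <- zscore(df$snfl)
  df$duration_z <- zscore(df$disease_duration)
  df$age_z <- zscore(df$age)
  terms <- c("snfl_z", "duration_z", "age_z", "sex", "phenotype",
             "treatment", "center")
  terms <- terms[vapply(terms, function(v)
    length(unique(df[[v]])) > 1L, logical(1))]
  fml <- stats::reformulate(terms, response = ".y")
  X <- stats::model.matrix(fml, df)
  if (nrow(X) <= ncol(X))
    stop("more model columns than observations")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  list(table = coef_table(stats::coef(fit), sm$coefficients[, 2],
                          df_resid = fit$df.residual),
       fit = fit, n = nrow(df))
}
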