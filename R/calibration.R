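#' Fit a 1/x-weighted linear calibration curve
#'
#' Fits `response_ratio = intercept + slope * nominal_conc` by weighted
#' least squares with weights `1/x` (each point down-weighted by its
#' nominal concentration), the standard weighting for bioanalytical
#' calibration spanning several orders of magnitude. Technical replicates
#' enter as individual points — no pre-averaging — so the weighting
#' semantics are preserved.
#'
#' The reported `r_squared` is, by default, the unweighted coefficient of
#' determination of the fitted line on the (x, y) points, the quantity
#' vendor software usually prints; set `weighted_r2 = TRUE` for the
#' weighted variant (1 minus the ratio of weighted residual to weighted
#' total sum of squares).
#'
#' @param points A data.frame with columns `nominal_conc` (> 0, ng/mL) and
#'   `response_ratio` (analyte quantifier area / IS quantifier area).
#' @param weighting `"1/x"` (default) or `"none"`.
#' @param dilution_label Optional label (`"1:1"` / `"1:4"`) carried into
#'   the result.
#' @param weighted_r2 Report the weighted coefficient of determination
#'   instead of the unweighted one.
#' @return An object of class `calibration_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `weighting`, `dilution_label`, `n`, and
#'   `levels` (per-level back-calculated mean concentration and accuracy %).
#' @examples
#' pts <- data.frame(nominal_conc = c(1, 10, 100),
#'                   response_ratio = c(1.0, 9.0, 105.0))
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points, weighting = c("1/x", "none"),
                            dilution_label = NA_character_,
                            weighted_r2 = FALSE) {
  weighting <- match.arg(weighting)
  x <- points$nominal_conc
  y <- points$response_ratio
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all nominal concentrations must be finite and > 0 (1/x weights undefined at 0)")
  if (any(!is.finite(y)) || any(y < 0))
    stop("response ratios must be finite and >= 0")
  if (length(unique(x)) < 2)
    stop("calibration requires at least 2 distinct nominal levels")

  w <- if (weighting == "1/x") 1 / x else rep(1, length(x))
  fit <- stats::lm(y ~ x, weights = w)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])

  yhat <- a + b * x
  if (weighted_r2) {
    r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - stats::weighted.mean(y, w))^2)
  } else {
    r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }

  back <- (y - a) / b
  lv <- sort(unique(x))
  levels <- data.frame(
    nominal_conc = lv,
    mean_back_calc = vapply(lv, function(l) mean(back[x == l]), numeric(1)))
  levels$accuracy_pct <- 100 * levels$mean_back_calc / levels$nominal_conc

  structure(list(slope = b, intercept = a, r_squared = r2,
                 weighting = weighting, dilution_label = dilution_label,
                 n = length(x), levels = levels),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve%s: y = %.6f * x %s %.6f  (R2 = %.4f, w = %s, n = %d)\n",
              if (is.na(x$dilution_label)) "" else paste0(" [", x$dilution_label, "]"),
              x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
              x$r_squared, x$weighting, x$n))
  invisible(x)
}

#' Predict the response ratio at a concentration
#'
#' @param object A `calibration_curve`.
#' @param newdata Numeric concentrations, ng/mL (or a data.frame with
#'   column `nominal_conc`).
#' @param ... Unused.
#' @return Predicted response ratios.
#' @export
predict.calibration_curve <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$nominal_conc else newdata
  object$intercept + object$slope * x
}

#' Back-calculate concentration from a response ratio
#'
#' Inverts the calibration line: `conc = (ratio - intercept) / slope`.
#' Ratios below the x-axis intercept give negative concentrations; these
#' are reported as 0 with `flag_below_zero = TRUE` rather than propagated.
#'
#' @param curve A `calibration_curve`.
#' @param response_ratio Observed area ratio(s).
#' @return A data.frame with columns `response_ratio`, `conc_ng_ml` and
#'   `flag_below_zero`.
#' @export
back_calculate <- function(curve, response_ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("cannot back-calculate from a zero-slope curve")
  conc <- (response_ratio - curve$intercept) / curve$slope
  below <- !is.na(conc) & conc < 0
  conc[below] <- 0
  data.frame(response_ratio = response_ratio, conc_ng_ml = conc,
             flag_below_zero = below)
}

#' Assess a calibration curve against ICH M10 acceptance rules
#'
#' A curve is accepted when its coefficient of determination exceeds 0.99
#' and at least 75% of the calibration standards back-calculate within
#' +/-20% of nominal at the LLOQ and +/-15% at all other levels (bands
#' inclusive). Per-level flags are returned alongside the overall verdict.
#'
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @param lloq The LLOQ nominal; defaults to the lowest fitted level.
#' @param r2_min Minimum acceptable coefficient of determination.
#' @param band_lloq,band_other Half-widths of the accuracy bands (fractions).
#' @return A list with `pass`, `r_squared`, `r2_pass`, `frac_levels_pass`
#'   and a per-level data.frame `levels` (accuracy and pass flag).
#' @export
assess_curve <- function(curve, lloq = NULL, r2_min = 0.99,
                         band_lloq = 0.20, band_other = 0.15) {
  stopifnot(inherits(curve, "calibration_curve"))
  lv <- curve$levels
  if (is.null(lloq)) lloq <- min(lv$nominal_conc)
  band <- ifelse(lv$nominal_conc == lloq, band_lloq, band_other)
  lv$band_pct <- 100 * band
  lv$pass <- abs(lv$accuracy_pct - 100) <= 100 * band
  frac <- mean(lv$pass)
  r2_pass <- curve$r_squared > r2_min
  list(pass = r2_pass && frac >= 0.75,
       r_squared = curve$r_squared, r2_pass = r2_pass,
       frac_levels_pass = frac, levels = lv)
}

#' Qualifier/quantifier ion-ratio check
#'
#' Confirms analyte identity by comparing the observed qualifier-to-
#' quantifier area ratio against a reference ratio (the mean of passing
#' calibration standards). Passes when the observed ratio is within
#' `tolerance_frac` (default +/-30%, a common bioanalytical convention) of
#' the reference.
#'
#' @param quantifier_area,qualifier_area Observed areas.
#' @param reference_ratio Reference qualifier/quantifier ratio (> 0).
#' @param tolerance_frac Relative tolerance.
#' @return A list with `pass`, `observed_ratio` and `reason` (`"ok"`,
#'   `"ratio outside tolerance"` or `"zero qualifier area"`).
#' @export
ion_ratio_check <- function(quantifier_area, qualifier_area,
                            reference_ratio, tolerance_frac = 0.30) {
  stopifnot(length(quantifier_area) == 1, length(qualifier_area) == 1,
            reference_ratio > 0)
  if (qualifier_area <= 0 || quantifier_area <= 0)
    return(list(pass = FALSE, observed_ratio = NA_real_,
                reason = "zero qualifier area"))
  obs <- qualifier_area / quantifier_area
  ok <- abs(obs / reference_ratio - 1) <= tolerance_frac
  list(pass = ok, observed_ratio = obs,
       reason = if (ok) "ok" else "ratio outside tolerance")
}

#' Response ratios from a peak table
#'
#' Joins analyte and internal-standard quantifier areas per sample and
#' returns the area ratio used for quantification.
#'
#' @param peaks A peak table as produced by [simulate_peak_areas()] or
#'   [read_peaks()] (columns `sample_id`, `analyte`, `role`, `area`).
#' @param analyte,is_analyte Analyte names for the drug and the internal
#'   standard.
#' @return A data.frame with `sample_id`, `area_analyte`, `area_is` and
#'   `response_ratio`.
#' @export
response_ratios <- function(peaks, analyte = "ropivacaine",
                            is_analyte = "d7-ropivacaine") {
  qa <- peaks[peaks$analyte == analyte & peaks$role == "quantifier", ]
  qi <- peaks[peaks$analyte == is_analyte & peaks$role == "quantifier", ]
  m <- merge(qa[, c("sample_id", "area")],
             qi[, c("sample_id", "area")],
             by = "sample_id", suffixes = c("_analyte", "_is"))
  if (any(m$area_is <= 0))
    warning("internal-standard area <= 0 for some samples; ratios are NA there")
  m$response_ratio <- ifelse(m$area_is > 0, m$area_analyte / m$area_is, NA_real_)
  m
}
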