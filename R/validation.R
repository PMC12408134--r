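#' Accuracy as percent of nominal
#'
#' @param mean_measured Mean measured concentration, ng/mL.
#' @param nominal Nominal concentration, ng/mL (> 0).
#' @return `100 * mean_measured / nominal`.
#' @examples
#' accuracy(305.82, 300)  # 101.94
#' @export
accuracy <- function(mean_measured, nominal) {
  if (any(nominal <= 0)) stop("nominal must be > 0")
  100 * mean_measured / nominal
}

#' Precision as coefficient of variation (%)
#'
#' Sample standard deviation (n-1 denominator) over the mean, times 100.
#'
#' @param values Replicate measured concentrations (n >= 2).
#' @return CV in percent.
#' @examples
#' precision_cv(c(1, 2, 3))  # 50
#' @export
precision_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("precision requires at least 2 values")
  m <- mean(values)
  if (m == 0) stop("precision undefined for zero mean")
  100 * stats::sd(values) / m
}

# round half away from zero, as validation tables are presented
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# one QC statistics row; bands are inclusive
qc_stat_row <- function(values, nominal, level_name, scope,
                        acc_band = c(85, 115), cv_max = 15) {
  m <- mean(values)
  s <- if (length(values) >= 2) stats::sd(values) else NA_real_
  acc <- accuracy(m, nominal)
  cv <- if (length(values) >= 2) precision_cv(values) else NA_real_
  pass <- acc >= acc_band[1] && acc <= acc_band[2] &&
    (is.na(cv) || cv <= cv_max)
  data.frame(level_name = level_name, nominal = nominal, n = length(values),
             mean = m, sd = s, accuracy_pct = acc, cv_pct = cv,
             scope = scope, pass = pass, stringsAsFactors = FALSE)
}

# band selection: LLOQ gets 80-120% / 20%, other levels 85-115% / 15%
qc_bands <- function(level_name) {
  if (identical(level_name, "LLOQ")) list(acc = c(80, 120), cv = 20)
  else list(acc = c(85, 115), cv = 15)
}

#' Intra- and inter-run accuracy and precision
#'
#' Computes per-run (intra-run) and pooled (inter-run) accuracy and CV for
#' a QC replicate table, applying the ICH M10 bands: accuracy within
#' 85-115% of nominal and CV <= 15%, widened to 80-120% / 20% at the LLOQ.
#' Inter-run statistics pool all replicates of all runs rather than
#' averaging per-run means. Bands are inclusive. Levels present in
#' `expected_levels` but absent from the data are reported with `n = 0`
#' and `pass = NA`, never silently dropped.
#'
#' @param qc A data.frame with columns `level_name`, `nominal`, `run_day`
#'   and `measured` (ng/mL).
#' @param expected_levels Optional character vector of level names that
#'   must be reported.
#' @return A data.frame of QC statistics, one row per level x run plus one
#'   pooled inter-run row per level, with columns `level_name`, `nominal`,
#'   `n`, `mean`, `sd`, `accuracy_pct`, `cv_pct`, `scope`, `pass`.
#' @export
intra_inter_run <- function(qc, expected_levels = NULL) {
  need <- c("level_name", "nominal", "run_day", "measured")
  if (!all(need %in% names(qc)))
    stop("qc table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  lv_names <- unique(qc$level_name)
  for (lv in lv_names) {
    sub <- qc[qc$level_name == lv, ]
    bands <- qc_bands(lv)
    nominal <- unique(sub$nominal)
    if (length(nominal) != 1)
      stop("level ", lv, " has inconsistent nominal concentrations")
    for (run in sort(unique(sub$run_day))) {
      v <- sub$measured[sub$run_day == run]
      if (length(v) < 2)
        stop("intra-run statistics need >= 2 replicates (level ", lv,
             ", run ", run, ")")
      out[[length(out) + 1L]] <-
        qc_stat_row(v, nominal, lv, sprintf("intra-run %d", run),
                    bands$acc, bands$cv)
    }
    out[[length(out) + 1L]] <-
      qc_stat_row(sub$measured, nominal, lv, "inter-run", bands$acc, bands$cv)
  }
  res <- do.call(rbind, out)
  missing <- setdiff(expected_levels, lv_names)
  for (lv in missing)
    res <- rbind(res, data.frame(level_name = lv, nominal = NA_real_, n = 0L,
                                 mean = NA_real_, sd = NA_real_,
                                 accuracy_pct = NA_real_, cv_pct = NA_real_,
                                 scope = "absent", pass = NA,
                                 stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Matrix-effect assessment across matrix lots
#'
#' Per-lot accuracy and CV for QC replicates prepared in independent
#' matrix lots, with the +/-15% accuracy band and CV < 15% applied to each
#' lot. The design calls for at least 6 lots with at least 3 replicates
#' each; fewer lots yields a warning-level flag but statistics are still
#' computed.
#'
#' @param qc A data.frame with columns `lot`, `level_name`, `nominal` and
#'   `measured`.
#' @param min_lots Minimum number of lots expected.
#' @return A data.frame with one row per lot x level (columns as in
#'   [intra_inter_run()] plus `lot`), with attribute `"enough_lots"`.
#' @export
matrix_effect <- function(qc, min_lots = 6L) {
  need <- c("lot", "level_name", "nominal", "measured")
  if (!all(need %in% names(qc)))
    stop("matrix-effect table must have columns: ", paste(need, collapse = ", "))
  lots <- sort(unique(qc$lot))
  enough <- length(lots) >= min_lots
  if (!enough)
    warning(sprintf("only %d matrix lots present (expected >= %d)",
                    length(lots), min_lots))
  out <- list()
  for (lt in lots) for (lv in unique(qc$level_name)) {
    v <- qc$measured[qc$lot == lt & qc$level_name == lv]
    if (length(v) == 0) next
    if (length(v) < 3)
      warning(sprintf("lot %s level %s has fewer than 3 replicates", lt, lv))
    nominal <- unique(qc$nominal[qc$lot == lt & qc$level_name == lv])
    row <- qc_stat_row(v, nominal, lv, "matrix-lot", c(85, 115), 15)
    row$lot <- lt
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "enough_lots") <- enough
  res
}

#' Carry-over assessment from post-ULOQ blanks
#'
#' Compares blank-injection areas (acquired immediately after a ULOQ
#' standard) with the mean response at the LLOQ: carry-over is acceptable
#' when the blank analyte area is not greater than 20% of the mean LLOQ
#' analyte area and the blank internal-standard area not greater than 5%
#' of the mean internal-standard area. Thresholds are inclusive.
#'
#' @param blank_analyte_areas,blank_is_areas Areas in the blank
#'   injection(s).
#' @param lloq_analyte_areas Analyte areas of the LLOQ standards.
#' @param is_areas Internal-standard areas of regular injections.
#' @return A list with `pass`, `analyte_pass`, `is_pass`, the observed
#'   fractions `analyte_frac` / `is_frac`, and the thresholds applied.
#' @export
carryover_assess <- function(blank_analyte_areas, blank_is_areas,
                             lloq_analyte_areas, is_areas) {
  if (length(blank_analyte_areas) == 0 || length(lloq_analyte_areas) == 0)
    stop("carry-over assessment requires post-ULOQ blank and LLOQ records")
  a_ref <- mean(lloq_analyte_areas)
  i_ref <- mean(is_areas)
  if (a_ref <= 0 || i_ref <= 0)
    stop("reference areas must be positive")
  a_frac <- max(blank_analyte_areas) / a_ref
  i_frac <- max(blank_is_areas) / i_ref
  a_ok <- a_frac <= 0.20
  i_ok <- i_frac <= 0.05
  list(pass = a_ok && i_ok, analyte_pass = a_ok, is_pass = i_ok,
       analyte_frac = a_frac, is_frac = i_frac,
       analyte_threshold = 0.20, is_threshold = 0.05)
}

#' Stability assessment across storage conditions
#'
#' Accuracy and CV per storage condition and QC level; the mean
#' concentration at each level must be within +/-15% of nominal.
#' Recognized conditions: `T0`, `benchtop`, `freeze_thaw`,
#' `longterm_-20C`, `longterm_-80C`, `processed_autosampler`.
#'
#' @param qc A data.frame with columns `condition`, `level_name`,
#'   `nominal`, `measured`.
#' @return A data.frame of QC statistics with a `condition` column.
#' @export
stability_assess <- function(qc) {
  known <- c("T0", "benchtop", "freeze_thaw", "longterm_-20C",
             "longterm_-80C", "processed_autosampler")
  bad <- setdiff(unique(qc$condition), known)
  if (length(bad) > 0)
    stop("unknown storage condition(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(known, collapse = ", "), ")")
  out <- list()
  for (cd in unique(qc$condition)) for (lv in unique(qc$level_name)) {
    v <- qc$measured[qc$condition == cd & qc$level_name == lv]
    if (length(v) == 0) next
    nominal <- unique(qc$nominal[qc$condition == cd & qc$level_name == lv])
    row <- qc_stat_row(v, nominal, lv, "stability", c(85, 115), Inf)
    row$condition <- cd
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare first-injection and reinjection QC statistics
#'
#' Side-by-side accuracies for a run reinjected after autosampler storage.
#' Informational: the individual QC bands still apply to each run, but no
#' additional band is imposed on the difference. Accuracies are reported
#' on both reference bases — against nominal, and the reinjection against
#' the first-injection mean — because table conventions differ.
#'
#' @param first,reinjection Data.frames with columns `level_name`,
#'   `nominal`, `measured`.
#' @return A data.frame with per-level first/reinjection accuracies, their
#'   difference, and the reinjection accuracy relative to the first
#'   injection's mean.
#' @export
reinjection_compare <- function(first, reinjection) {
  lv1 <- sort(unique(first$level_name))
  lv2 <- sort(unique(reinjection$level_name))
  if (!identical(lv1, lv2))
    stop("level mismatch between first injection and reinjection: ",
         paste(setdiff(union(lv1, lv2), intersect(lv1, lv2)), collapse = ", "))
  out <- lapply(lv1, function(lv) {
    v1 <- first$measured[first$level_name == lv]
    v2 <- reinjection$measured[reinjection$level_name == lv]
    nominal <- unique(first$nominal[first$level_name == lv])
    a1 <- accuracy(mean(v1), nominal)
    a2 <- accuracy(mean(v2), nominal)
    data.frame(level_name = lv, nominal = nominal,
               accuracy_first = a1, accuracy_reinjection = a2,
               accuracy_diff = a2 - a1,
               reinjection_vs_first_pct = 100 * mean(v2) / mean(v1),
               cv_first = precision_cv(v1), cv_reinjection = precision_cv(v2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Precipitation and overall recovery (spike before/after design)
#'
#' Three preparations per spike level: (A) matrix spiked before protein
#' precipitation, (B) blank matrix spiked after precipitation, (C) solvent
#' spike. Precipitation recovery is `100 * mean(A)/mean(B)` and overall
#' recovery `100 * mean(A)/mean(C)`, computed for the analyte and the
#' internal standard from mean areas, and additionally on the
#' per-replicate analyte/IS area ratios (the basis of the acceptance
#' rule). The method passes when the overall recoveries of the internal
#' standard and the analyte differ by at most 15 percentage points.
#'
#' @param a,b,c_ Data.frames with columns `area_analyte` and `area_is`,
#'   one row per replicate, for approaches A, B and C.
#' @return A list of class `recovery_result` with per-channel and ratio
#'   recoveries and the `pass` flag.
#' @export
recovery <- function(a, b, c_) {
  for (df in list(a, b, c_))
    if (!all(c("area_analyte", "area_is") %in% names(df)))
      stop("each approach needs columns area_analyte and area_is")
  mean_pos <- function(v, what) {
    m <- mean(v)
    if (m <= 0) stop("zero or negative mean area in approach ", what)
    m
  }
  ma_a <- mean_pos(a$area_analyte, "A"); mi_a <- mean_pos(a$area_is, "A")
  ma_b <- mean_pos(b$area_analyte, "B"); mi_b <- mean_pos(b$area_is, "B")
  ma_c <- mean_pos(c_$area_analyte, "C"); mi_c <- mean_pos(c_$area_is, "C")

  ratio <- function(df) df$area_analyte / df$area_is
  r_a <- mean_pos(ratio(a), "A"); r_b <- mean_pos(ratio(b), "B")
  r_c <- mean_pos(ratio(c_), "C")

  prec_analyte <- 100 * ma_a / ma_b
  prec_is <- 100 * mi_a / mi_b
  over_analyte <- 100 * ma_a / ma_c
  over_is <- 100 * mi_a / mi_c
  structure(list(
    precipitation_analyte_pct = prec_analyte,
    precipitation_is_pct = prec_is,
    overall_analyte_pct = over_analyte,
    overall_is_pct = over_is,
    precipitation_ratio_pct = 100 * r_a / r_b,
    overall_ratio_pct = 100 * r_a / r_c,
    pass = abs(over_is - over_analyte) <= 15),
    class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("recovery: precipitation %.1f%% (analyte) / %.1f%% (IS); overall %.1f%% / %.1f%%\n",
              x$precipitation_analyte_pct, x$precipitation_is_pct,
              x$overall_analyte_pct, x$overall_is_pct))
  cat(sprintf("  ratio recovery: precipitation %.1f%%, overall %.1f%%; %s\n",
              x$precipitation_ratio_pct, x$overall_ratio_pct,
              if (x$pass) "PASS (|IS - analyte| overall <= 15 points)"
              else "FAIL (|IS - analyte| overall > 15 points)"))
  invisible(x)
}

#' Selectivity assessment on blank matrix lots
#'
#' Per-lot interference check on blank injections from independent matrix
#' lots: interference is acceptable when the blank analyte response is
#' equal to or less than 20% of the LLOQ analyte response, and the blank
#' internal-standard response equal to or less than 5% of the reference
#' internal-standard response. Thresholds are inclusive.
#'
#' @param blanks A data.frame with columns `lot`, `area_analyte`,
#'   `area_is` (one row per blank lot injection).
#' @param lloq_analyte_area Mean analyte response at the LLOQ.
#' @param is_reference_area Mean internal-standard response.
#' @param min_lots Minimum number of lots expected.
#' @return A data.frame with per-lot fractions and pass flags.
#' @export
selectivity_assess <- function(blanks, lloq_analyte_area, is_reference_area,
                               min_lots = 6L) {
  if (length(unique(blanks$lot)) < min_lots)
    warning(sprintf("selectivity assessed on %d lots (expected >= %d)",
                    length(unique(blanks$lot)), min_lots))
  stopifnot(lloq_analyte_area > 0, is_reference_area > 0)
  out <- data.frame(lot = blanks$lot,
                    analyte_frac = blanks$area_analyte / lloq_analyte_area,
                    is_frac = blanks$area_is / is_reference_area)
  out$analyte_pass <- out$analyte_frac <= 0.20
  out$is_pass <- out$is_frac <= 0.05
  out$pass <- out$analyte_pass & out$is_pass
  out
}
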