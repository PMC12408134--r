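#' Instrument response model for simulated MRM peak areas
#'
#' A stylized model of the detector response used by the synthetic-data
#' module. For each injection the quantifier analyte area is
#'
#' `area = sensitivity * conc_injected * lot * (1 + e_c) * (1 + e_i) +
#'  e_add + carryover_frac * previous_area`
#'
#' where `e_c` is a proportional error shared between the analyte and the
#' internal-standard channel of the same injection (pipetting and
#' ionization variability, which the area ratio cancels), `e_i` is an
#' independent proportional error per channel (which the ratio does not
#' cancel), `e_add` is additive baseline noise, `lot` is a per-matrix-lot
#' multiplicative factor applied to the analyte channel only (modeling an
#' analyte-specific matrix response relative to the co-eluting labeled
#' internal standard), and the carry-over term bleeds a fraction of the
#' previous injection's area on the same channel into the current one.
#' Qualifier transitions are scaled copies of the quantifier
#' (`qualifier_ratio`). Areas are floored at zero.
#'
#' The absolute area scale is an arbitrary fixture choice (instrument
#' counts). The default sensitivities are anchored so that, with the
#' default prep geometry and internal-standard level, the response-ratio
#' calibration slope against chamber-level concentration is 0.727432 per
#' ng/mL — the regression constant of the assay's 1:1 matrix-matched
#' curve. `sigma_prop = 0.03` per component yields area-ratio CVs in the
#' low single-digit percent range typical of a well-behaved
#' stable-isotope-dilution assay, and `sigma_add` defaults to 0.5% of the
#' analyte area at the 1:1 LLOQ (0.05 ng/mL chamber level).
#'
#' @param sensitivity_analyte Analyte quantifier area per ng/mL injected.
#' @param sensitivity_is Internal-standard quantifier area per ng/mL
#'   injected.
#' @param sigma_prop SD of each proportional error component
#'   (dimensionless).
#' @param sigma_add SD of additive area noise (area units).
#' @param lot_effects Named or unnamed vector of per-lot multiplicative
#'   factors (> 0) on the analyte channel.
#' @param carryover_frac Fraction (0 to 0.05) of the previous injection's
#'   area carried into the next injection on the same channel.
#' @param qualifier_ratio Qualifier/quantifier area ratio per analyte.
#' @return An object of class `response_model`.
#' @export
response_model <- function(sensitivity_analyte = 13093.776,
                           sensitivity_is = 2000,
                           sigma_prop = 0.03,
                           sigma_add = 0.36,
                           lot_effects = rep(1, 6),
                           carryover_frac = 0,
                           qualifier_ratio = 0.4) {
  if (sensitivity_analyte <= 0 || sensitivity_is <= 0)
    stop("sensitivities must be > 0")
  if (carryover_frac < 0 || carryover_frac > 0.05)
    stop("carryover_frac must lie in [0, 0.05]")
  if (any(lot_effects <= 0))
    stop("lot factors must be > 0")
  if (sigma_prop < 0 || sigma_add < 0)
    stop("noise SDs must be >= 0")
  structure(list(sensitivity_analyte = sensitivity_analyte,
                 sensitivity_is = sensitivity_is,
                 sigma_prop = sigma_prop,
                 sigma_add = sigma_add,
                 lot_effects = lot_effects,
                 carryover_frac = carryover_frac,
                 qualifier_ratio = qualifier_ratio),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf(paste0("response model: S_analyte = %g, S_IS = %g area/(ng/mL), ",
                     "sigma_prop = %g, sigma_add = %g, carryover = %g\n"),
              x$sensitivity_analyte, x$sensitivity_is, x$sigma_prop,
              x$sigma_add, x$carryover_frac))
  invisible(x)
}

#' Simulate MRM peak areas for an injection sequence
#'
#' Applies the [response_model()] to a manifest of injections in order
#' (carry-over makes the result order-dependent). Each injection yields
#' four records: quantifier and qualifier for the analyte and for the
#' internal standard.
#'
#' @param manifest A data.frame with one row per injection, ordered by
#'   injection sequence, with columns `sample_id`, `lot` (integer index
#'   into `lot_effects`; `NA` or 0 means no matrix, factor 1).
#' @param injected_conc Analyte concentration in the injected solution,
#'   ng/mL (same length/order as `manifest`).
#' @param is_injected_conc Internal-standard concentration in the injected
#'   solution, ng/mL (recycled).
#' @param response A [response_model()].
#' @param seed Integer seed; the same manifest, concentrations, model and
#'   seed reproduce the table exactly.
#' @return A data.frame of peak records with columns `sample_id`,
#'   `injection_index`, `analyte` (`"ropivacaine"` / `"d7-ropivacaine"`),
#'   `role` (`"quantifier"` / `"qualifier"`) and `area`.
#' @export
simulate_peak_areas <- function(manifest, injected_conc,
                                is_injected_conc = 1,
                                response = response_model(),
                                seed = 1L) {
  stopifnot(inherits(response, "response_model"))
  n <- nrow(manifest)
  if (length(injected_conc) != n)
    stop("injected_conc must have one value per manifest row")
  if (any(injected_conc < 0)) stop("injected concentrations must be >= 0")
  is_conc <- rep_len(is_injected_conc, n)
  lot_idx <- if ("lot" %in% names(manifest)) manifest$lot else rep(NA_integer_, n)
  lot_fac <- ifelse(is.na(lot_idx) | lot_idx == 0, 1,
                    response$lot_effects[lot_idx])

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  e_shared <- stats::rnorm(n, 0, response$sigma_prop)
  e_analyte <- stats::rnorm(n, 0, response$sigma_prop)
  e_is <- stats::rnorm(n, 0, response$sigma_prop)
  add_a <- stats::rnorm(n, 0, response$sigma_add)
  add_i <- stats::rnorm(n, 0, response$sigma_add)

  area_a <- numeric(n)
  area_i <- numeric(n)
  prev_a <- 0
  prev_i <- 0
  for (k in seq_len(n)) {
    a <- response$sensitivity_analyte * injected_conc[k] * lot_fac[k] *
      (1 + e_shared[k]) * (1 + e_analyte[k]) + add_a[k] +
      response$carryover_frac * prev_a
    i <- response$sensitivity_is * is_conc[k] *
      (1 + e_shared[k]) * (1 + e_is[k]) + add_i[k] +
      response$carryover_frac * prev_i
    area_a[k] <- max(a, 0)
    area_i[k] <- max(i, 0)
    prev_a <- area_a[k]
    prev_i <- area_i[k]
  }

  idx <- seq_len(n)
  out <- rbind(
    data.frame(sample_id = manifest$sample_id, injection_index = idx,
               analyte = "ropivacaine", role = "quantifier",
               area = area_a, stringsAsFactors = FALSE),
    data.frame(sample_id = manifest$sample_id, injection_index = idx,
               analyte = "ropivacaine", role = "qualifier",
               area = area_a * response$qualifier_ratio,
               stringsAsFactors = FALSE),
    data.frame(sample_id = manifest$sample_id, injection_index = idx,
               analyte = "d7-ropivacaine", role = "quantifier",
               area = area_i, stringsAsFactors = FALSE),
    data.frame(sample_id = manifest$sample_id, injection_index = idx,
               analyte = "d7-ropivacaine", role = "qualifier",
               area = area_i * response$qualifier_ratio,
               stringsAsFactors = FALSE))
  out <- out[order(out$injection_index, out$analyte, out$role), ]
  rownames(out) <- NULL
  out
}

#' Internal-standard concentration in the injected solution
#'
#' The IS is spiked during prep (after the aliquot is taken), so its
#' injected concentration depends only on the prep volumes, not on the
#' chamber: `v_is * is_working_conc / v_final`, divided by the plasma
#' post-dilution factor for the plasma fraction.
#'
#' @param compartment `"plasma"` or `"buffer"`.
#' @param geometry A [red_geometry()].
#' @param is_working_conc IS working-solution concentration, ng/mL.
#' @return Injected IS concentration, ng/mL.
#' @export
is_injected_conc <- function(compartment = c("plasma", "buffer"),
                             geometry = red_geometry(),
                             is_working_conc = 100) {
  compartment <- match.arg(compartment)
  v_final <- geometry$v_aliquot + geometry$v_complement + geometry$v_acid +
    geometry$v_is + geometry$v_acn
  conc <- geometry$v_is * is_working_conc / v_final
  if (compartment == "plasma") conc / geometry$plasma_post_dilution_factor
  else conc
}
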