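#' Study design for the synthetic validation data set
#'
#' Collects the concentration levels and replication structure of the
#' bioanalytical validation study the simulator emulates: two
#' matrix-matched calibration curves (a 9-level 1:1 curve used for the
#' buffer fraction, 0.05-1000 ng/mL, and a 13-level 1:4 curve used for the
#' plasma fraction, 0.075-1000 ng/mL), QC levels at LLOQ / LQC / MQC / HQC
#' per dilution, two whole-workflow plasma spike levels processed through
#' dialysis, two dose groups sampled over four hours for the
#' pharmacokinetic arm, and the replication counts (technical triplicates
#' per calibration standard, six QC replicates per run, three runs on
#' three days, six matrix lots).
#'
#' @param calibration_levels_1to1,calibration_levels_1to4 Calibration
#'   standard nominals, ng/mL, ascending.
#' @param qc_levels_1to1,qc_levels_1to4 Named QC nominals (LLOQ, LQC, MQC,
#'   HQC), ng/mL.
#' @param spike_levels_workflow Plasma spike levels for whole-workflow
#'   repeatability, ng/mL.
#' @param dose_groups Doses for the PK arm, mg/kg.
#' @param sampling_times PK sampling times, minutes (strictly increasing;
#'   negative = pre-dose).
#' @param n_lots Number of independent matrix lots.
#' @param n_cal_replicates Technical replicates per calibration standard.
#' @param n_qc_replicates QC replicates per run.
#' @param n_runs Number of runs/days.
#' @return An object of class `study_design`.
#' @export
study_design <- function(
    calibration_levels_1to1 = c(0.05, 1, 10, 100, 200, 400, 600, 800, 1000),
    calibration_levels_1to4 = c(0.075, 0.1, 0.25, 0.3, 0.5, 1, 10, 100,
                                200, 400, 600, 800, 1000),
    qc_levels_1to1 = c(LLOQ = 0.05, LQC = 0.15, MQC = 300, HQC = 750),
    qc_levels_1to4 = c(LLOQ = 0.30, LQC = 1.00, MQC = 300, HQC = 750),
    spike_levels_workflow = c(low = 88, high = 1742.50),
    dose_groups = c(1, 3),
    sampling_times = c(-2, 5, 10, 15, 30, 45, 60, 120, 240),
    n_lots = 6L,
    n_cal_replicates = 3L,
    n_qc_replicates = 6L,
    n_runs = 3L) {
  for (lv in list(calibration_levels_1to1, calibration_levels_1to4))
    if (is.unsorted(lv, strictly = TRUE) || any(lv <= 0))
      stop("calibration levels must be positive and strictly ascending")
  check_qc <- function(qc, cal) {
    if (any(qc < min(cal)) || any(qc > max(cal)))
      stop("QC levels must lie within [LLOQ, ULOQ] of their curve")
  }
  check_qc(qc_levels_1to1, calibration_levels_1to1)
  check_qc(qc_levels_1to4, calibration_levels_1to4)
  if (is.unsorted(sampling_times, strictly = TRUE))
    stop("sampling_times must be strictly increasing")
  structure(list(calibration_levels_1to1 = calibration_levels_1to1,
                 calibration_levels_1to4 = calibration_levels_1to4,
                 qc_levels_1to1 = qc_levels_1to1,
                 qc_levels_1to4 = qc_levels_1to4,
                 spike_levels_workflow = spike_levels_workflow,
                 dose_groups = dose_groups,
                 sampling_times = sampling_times,
                 n_lots = as.integer(n_lots),
                 n_cal_replicates = as.integer(n_cal_replicates),
                 n_qc_replicates = as.integer(n_qc_replicates),
                 n_runs = as.integer(n_runs)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study design:\n")
  cat(sprintf("  1:1 curve: %d levels, %g-%g ng/mL\n",
              length(x$calibration_levels_1to1),
              min(x$calibration_levels_1to1), max(x$calibration_levels_1to1)))
  cat(sprintf("  1:4 curve: %d levels, %g-%g ng/mL\n",
              length(x$calibration_levels_1to4),
              min(x$calibration_levels_1to4), max(x$calibration_levels_1to4)))
  cat(sprintf("  workflow spikes: %s ng/mL; %d runs x %d QC reps; %d lots\n",
              paste(x$spike_levels_workflow, collapse = ", "),
              x$n_runs, x$n_qc_replicates, x$n_lots))
  invisible(x)
}

#' Simulate a pharmacokinetic concentration-time profile
#'
#' One-compartment model with first-order absorption and elimination for
#' drug appearing in plasma after regional (intraperitoneal) instillation:
#'
#' \deqn{C(t) = \frac{D}{V_d} \frac{k_a}{k_a - k_e}
#'       (e^{-k_e t} - e^{-k_a t}), \quad t > 0}
#'
#' with `C(t) = 0` at and before dose time. Concentrations scale linearly
#' with dose. Inter-animal variability is lognormal on the whole profile.
#' Default rates place the peak near 25 min and, at 1 mg/kg with the
#' default apparent volume, a peak total concentration of a couple of
#' hundred ng/mL — a plausible regime for slow systemic uptake of a
#' locally instilled anesthetic.
#'
#' @param dose_mg_kg Dose, mg/kg.
#' @param design A [study_design()] supplying `sampling_times` (minutes).
#' @param n_animals Number of animals.
#' @param ka First-order absorption rate, 1/min.
#' @param ke First-order elimination rate, 1/min.
#' @param vd_l_kg Apparent volume of distribution, L/kg (absorbed dose
#'   scale; bioavailability is folded in).
#' @param cv_inter Lognormal inter-animal coefficient of variation (0
#'   disables variability).
#' @param seed Integer seed.
#' @return A data.frame with columns `animal`, `time_min` and
#'   `total_conc` (ng/mL).
#' @export
simulate_pk_profile <- function(dose_mg_kg, design = study_design(),
                                n_animals = 4L,
                                ka = 0.1, ke = 0.01, vd_l_kg = 3.3,
                                cv_inter = 0.4, seed = 1L) {
  stopifnot(inherits(design, "study_design"), dose_mg_kg >= 0,
            ka > 0, ke > 0, ka != ke, vd_l_kg > 0, cv_inter >= 0)
  times <- design$sampling_times
  # ng/mL: mg/kg -> ng per mL of distribution volume
  c0 <- dose_mg_kg * 1e6 / (vd_l_kg * 1000)
  shape <- ifelse(times <= 0, 0,
                  ka / (ka - ke) * (exp(-ke * times) - exp(-ka * times)))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv_inter^2))
  animal_fac <- if (cv_inter > 0)
    stats::rlnorm(n_animals, -sdlog^2 / 2, sdlog) else rep(1, n_animals)
  out <- expand.grid(time_min = times, animal = seq_len(n_animals),
                     KEEP.OUT.ATTRS = FALSE)
  out$total_conc <- c0 * shape[match(out$time_min, times)] *
    animal_fac[out$animal]
  out[, c("animal", "time_min", "total_conc")]
}
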