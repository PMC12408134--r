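#' Simulate a complete validation study
#'
#' Builds the injection manifest, the ground truth, and the simulated MRM
#' peak-area table for one validation campaign: per run (day), selectivity
#' blanks from each matrix lot (run 1 only), both calibration curves
#' acquired in technical replicates in ascending order with a blank
#' injected immediately after each ULOQ standard (the carry-over check),
#' the four QC levels per dilution, matrix-effect QCs across lots (run 1
#' only), and the whole-workflow plasma spikes processed through RED into
#' paired buffer (1:1) and plasma (1:4) fraction injections.
#'
#' Calibration and QC samples emulate the LC-MS validation arm: they are
#' spiked directly at the stated nominal (chamber-level) concentration and
#' only pass through the prep dilution. Workflow samples emulate the full
#' assay: the plasma spike equilibrates across the RED membrane according
#' to the binding model before prep.
#'
#' @param design A [study_design()].
#' @param binding A [binding_model()].
#' @param response A [response_model()].
#' @param geometry A [red_geometry()].
#' @param seed Integer seed; identical inputs and seed reproduce the
#'   tables exactly.
#' @param arms Character vector choosing which arms to simulate; any of
#'   `"calibration"`, `"qc"`, `"matrix"`, `"workflow"`, `"selectivity"`.
#' @return A list of class `red_study` with elements `manifest`, `peaks`,
#'   `truth` (workflow ground truth: true chamber and original-plasma
#'   free/bound/total per specimen), and the four model objects.
#' @export
simulate_study <- function(design = study_design(),
                           binding = binding_model(),
                           response = response_model(),
                           geometry = red_geometry(),
                           seed = 1L,
                           arms = c("calibration", "qc", "matrix",
                                    "workflow", "selectivity")) {
  stopifnot(inherits(design, "study_design"))
  arms <- match.arg(arms, several.ok = TRUE)

  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  mk <- function(sample_id, type, compartment, dilution_label, nominal,
                 level_name = NA_character_, run_day = 1L, lot = NA_integer_) {
    data.frame(sample_id = sample_id, type = type, compartment = compartment,
               dilution_label = dilution_label, nominal_ng_ml = nominal,
               level_name = level_name, run_day = as.integer(run_day),
               lot = as.integer(lot), stringsAsFactors = FALSE)
  }

  dil_of <- c(buffer = "1:1", plasma = "1:4")

  for (run in seq_len(design$n_runs)) {
    if (run == 1L && "selectivity" %in% arms) {
      for (dl in c("1:1", "1:4")) for (lt in seq_len(design$n_lots))
        add(mk(sprintf("SELBLK_%s_lot%d", gsub(":", "", dl), lt),
               "selectivity_blank", NA, dl, 0, run_day = run, lot = lt))
    }
    if ("calibration" %in% arms) {
      for (dl in c("1:1", "1:4")) {
        levels <- if (dl == "1:1") design$calibration_levels_1to1
                  else design$calibration_levels_1to4
        for (li in seq_along(levels)) for (rep in seq_len(design$n_cal_replicates))
          add(mk(sprintf("CAL_%s_L%02d_r%d_d%d", gsub(":", "", dl), li, rep, run),
                 "calibration", NA, dl, levels[li], run_day = run, lot = 1L))
        # blank immediately after the ULOQ standard: the carry-over check
        add(mk(sprintf("BLK_%s_postULOQ_d%d", gsub(":", "", dl), run),
               "blank", NA, dl, 0, run_day = run, lot = 1L))
      }
    }
    if ("qc" %in% arms) {
      for (dl in c("1:1", "1:4")) {
        qcs <- if (dl == "1:1") design$qc_levels_1to1 else design$qc_levels_1to4
        for (lv in names(qcs)) for (rep in seq_len(design$n_qc_replicates))
          add(mk(sprintf("QC_%s_%s_r%d_d%d", gsub(":", "", dl), lv, rep, run),
                 "qc", NA, dl, qcs[[lv]], level_name = lv,
                 run_day = run, lot = 1L))
      }
    }
    if (run == 1L && "matrix" %in% arms) {
      for (dl in c("1:1", "1:4")) {
        qcs <- if (dl == "1:1") design$qc_levels_1to1 else design$qc_levels_1to4
        for (lv in c("LQC", "HQC")) for (lt in seq_len(design$n_lots))
          for (rep in seq_len(3L))
            add(mk(sprintf("MX_%s_%s_lot%d_r%d", gsub(":", "", dl), lv, lt, rep),
                   "matrix_qc", NA, dl, qcs[[lv]], level_name = lv,
                   run_day = run, lot = lt))
      }
    }
    if ("workflow" %in% arms) {
      for (lv in names(design$spike_levels_workflow)) {
        spike <- design$spike_levels_workflow[[lv]]
        for (rep in seq_len(design$n_qc_replicates)) {
          spec <- sprintf("WF_%s_r%d_d%d", lv, rep, run)
          for (cp in c("buffer", "plasma"))
            add(mk(paste0(spec, "_", cp), "workflow", cp, dil_of[[cp]],
                   spike, level_name = lv, run_day = run, lot = 1L))
        }
      }
    }
  }

  manifest <- do.call(rbind, rows)
  manifest$injection_index <- seq_len(nrow(manifest))

  # ground truth for workflow specimens (one row per specimen, not per fraction)
  wf <- manifest[manifest$type == "workflow" & manifest$compartment == "buffer", ]
  truth <- NULL
  if (nrow(wf) > 0) {
    eq <- simulate_red_equilibrium(wf$nominal_ng_ml, binding, geometry)
    orig <- original_concentrations(eq$chamber_plasma_conc,
                                    eq$chamber_buffer_conc, geometry,
                                    sample_id = sub("_buffer$", "", wf$sample_id))
    truth <- data.frame(specimen_id = orig$sample_id,
                        spike_ng_ml = wf$nominal_ng_ml,
                        chamber_plasma_conc = eq$chamber_plasma_conc,
                        chamber_buffer_conc = eq$chamber_buffer_conc,
                        free_conc = orig$free_conc,
                        bound_conc = orig$bound_conc,
                        total_conc = orig$total_conc,
                        stringsAsFactors = FALSE)
  }

  # injected concentrations: chamber-level nominal (or RED chamber value)
  # through the prep dilution chain of the sample's compartment/dilution
  injected <- numeric(nrow(manifest))
  is_inj <- numeric(nrow(manifest))
  f_buf <- dilution_chain("buffer", geometry)
  f_pla <- dilution_chain("plasma", geometry)
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    fac <- if (row$dilution_label == "1:4") f_pla else f_buf
    cp_for_is <- if (row$dilution_label == "1:4") "plasma" else "buffer"
    # interference blanks are double blanks: no analyte and no IS spiked
    is_inj[k] <- if (row$type %in% c("blank", "selectivity_blank")) 0
                 else is_injected_conc(cp_for_is, geometry)
    chamber <- if (row$type == "workflow") {
      spec <- sub(sprintf("_%s$", row$compartment), "", row$sample_id)
      tr <- truth[truth$specimen_id == spec, ]
      if (row$compartment == "buffer") tr$chamber_buffer_conc
      else tr$chamber_plasma_conc
    } else row$nominal_ng_ml
    injected[k] <- chamber / fac
  }

  peaks <- simulate_peak_areas(manifest, injected, is_inj, response,
                               seed = seed)

  structure(list(manifest = manifest, peaks = peaks, truth = truth,
                 design = design, binding = binding, response = response,
                 geometry = geometry, seed = as.integer(seed)),
            class = "red_study")
}

#' @export
print.red_study <- function(x, ...) {
  cat(sprintf("red_study: %d injections, %d peak records, seed %d\n",
              nrow(x$manifest), nrow(x$peaks), x$seed))
  tab <- table(x$manifest$type)
  cat("  injections by type: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write the simulated study to CSV files
#'
#' Emits `manifest.csv`, `peaks.csv` and (when workflow specimens are
#' present) `truth.csv` in a locale-independent dialect (comma separator,
#' `.` decimal, UTF-8).
#'
#' @param study A `red_study` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "red_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(manifest = file.path(dir, "manifest.csv"),
             peaks = file.path(dir, "peaks.csv"))
  utils::write.csv(study$manifest, paths[["manifest"]], row.names = FALSE)
  utils::write.csv(study$peaks, paths[["peaks"]], row.names = FALSE)
  if (!is.null(study$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    utils::write.csv(study$truth, paths[["truth"]], row.names = FALSE)
  }
  invisible(paths)
}
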