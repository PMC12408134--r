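#' Read a peak-area CSV
#'
#' Schema-by-name: columns are matched by header, so column order is
#' irrelevant; unknown columns are preserved. Required columns:
#' `sample_id`, `analyte`, `role`, `area`. Malformed rows (non-numeric or
#' negative area) are reported with their line numbers.
#'
#' @param path CSV path.
#' @return A data.frame of peak records.
#' @export
read_peaks <- function(path) {
  df <- read_checked_csv(path, required = c("sample_id", "analyte", "role",
                                            "area"))
  bad <- which(!is.finite(df$area) | df$area < 0)
  if (length(bad) > 0)
    stop(sprintf("malformed area values in %s at data row(s): %s",
                 path, paste(utils::head(bad, 10), collapse = ", ")))
  df
}

#' Read a sample manifest CSV
#'
#' Required columns: `sample_id`, `type`, `dilution_label`,
#' `nominal_ng_ml`, `injection_index`. Optional columns (`compartment`,
#' `level_name`, `run_day`, `lot`, ...) are preserved.
#'
#' @param path CSV path.
#' @return A data.frame ordered by `injection_index`.
#' @export
read_manifest <- function(path) {
  df <- read_checked_csv(path, required = c("sample_id", "type",
                                            "dilution_label", "nominal_ng_ml",
                                            "injection_index"))
  df[order(df$injection_index), , drop = FALSE]
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing required column(s): %s (header is line 1)",
                 path, paste(missing, collapse = ", ")))
  df
}

#' Read a run configuration from YAML
#'
#' The configuration holds the four model blocks (`geometry`, `binding`,
#' `response`, `design`), a `seed`, and optional acceptance-band
#' overrides. Units are fixed package-wide: concentrations in ng/mL,
#' volumes in uL; if the config declares `units:`, they are validated.
#'
#' @param path YAML file path.
#' @return A list with elements `geometry`, `binding`, `response`,
#'   `design` (constructed objects) and `seed`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$units)) {
    if (!identical(cfg$units$concentration, "ng/mL"))
      stop("config declares unsupported concentration unit: ",
           cfg$units$concentration)
    if (!is.null(cfg$units$volume) && !identical(cfg$units$volume, "uL"))
      stop("config declares unsupported volume unit: ", cfg$units$volume)
  }
  build <- function(block, ctor) {
    if (is.null(cfg[[block]])) ctor()
    else do.call(ctor, cfg[[block]])
  }
  list(geometry = build("geometry", red_geometry),
       binding = build("binding", binding_model),
       response = build("response", response_model),
       design = build("design", study_design),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

# fit per run x dilution calibration curves from manifest + ratio table
fit_run_curves <- function(manifest, ratios) {
  cal <- manifest[manifest$type == "calibration", ]
  if (nrow(cal) == 0) stop("no calibration samples in manifest")
  curves <- list()
  for (run in sort(unique(cal$run_day))) for (dl in unique(cal$dilution_label)) {
    sub <- cal[cal$run_day == run & cal$dilution_label == dl, ]
    if (nrow(sub) == 0) next
    pts <- merge(sub[, c("sample_id", "nominal_ng_ml")],
                 ratios[, c("sample_id", "response_ratio")], by = "sample_id")
    names(pts)[names(pts) == "nominal_ng_ml"] <- "nominal_conc"
    cv <- fit_calibration(pts, dilution_label = dl)
    curves[[paste(run, dl, sep = "|")]] <-
      list(run_day = run, dilution_label = dl, curve = cv,
           assessment = assess_curve(cv))
  }
  curves
}

# back-calculate all non-calibration samples against their run/dilution curve
quantify_samples <- function(manifest, ratios, curves) {
  sam <- manifest[!(manifest$type %in% c("calibration")), ]
  sam <- merge(sam, ratios[, c("sample_id", "response_ratio")],
               by = "sample_id", all.x = TRUE)
  sam$analyzed_ng_ml <- NA_real_
  sam$flag_below_zero <- FALSE
  for (key in names(curves)) {
    cv <- curves[[key]]
    idx <- which(sam$run_day == cv$run_day &
                   sam$dilution_label == cv$dilution_label &
                   !is.na(sam$response_ratio))
    if (length(idx) == 0) next
    bc <- back_calculate(cv$curve, sam$response_ratio[idx])
    sam$analyzed_ng_ml[idx] <- bc$conc_ng_ml
    sam$flag_below_zero[idx] <- bc$flag_below_zero
  }
  sam[order(sam$injection_index), , drop = FALSE]
}

# pair workflow fractions and back-calculate original plasma concentrations
fractionate_workflow <- function(quantified, geometry) {
  wf <- quantified[quantified$type == "workflow", ]
  if (nrow(wf) == 0) return(NULL)
  if (!"compartment" %in% names(wf) || any(is.na(wf$compartment)))
    stop("workflow samples must carry a compartment label")
  wf$specimen_id <- sub("_(buffer|plasma)$", "", wf$sample_id)
  pl <- wf[wf$compartment == "plasma", ]
  bf <- wf[wf$compartment == "buffer", ]
  m <- merge(pl[, c("specimen_id", "level_name", "run_day", "nominal_ng_ml",
                    "analyzed_ng_ml")],
             bf[, c("specimen_id", "analyzed_ng_ml")],
             by = "specimen_id", suffixes = c("_plasma", "_buffer"))
  missing <- setdiff(wf$specimen_id, m$specimen_id)
  if (length(missing) > 0)
    stop("unpaired workflow fraction(s) for specimen(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  fr <- original_concentrations(m$analyzed_ng_ml_plasma,
                                m$analyzed_ng_ml_buffer,
                                geometry, sample_id = m$specimen_id)
  cbind(m[, c("specimen_id", "level_name", "run_day", "nominal_ng_ml")],
        fr[, c("free_conc", "bound_conc", "total_conc",
               "flag_negative_bound")])
}

#' Run the complete quantification and validation pipeline
#'
#' Orchestrates calibration, quantification, RED mass-balance
#' fractionation, and the validation statistics over one study (simulated
#' via [simulate_study()] or read from CSV files). Stages run in order
#' and any failure aborts with the stage name. The result is
#' deterministic for a fixed input.
#'
#' @param study A `red_study`, or `NULL` to read from files.
#' @param manifest_file,peaks_file CSV paths used when `study` is `NULL`.
#' @param geometry A [red_geometry()] (defaults to the study's).
#' @param out_dir Optional directory; when given, curve, fraction and
#'   validation CSVs plus a provenance log are written there.
#' @return A list of class `red_pipeline_result` with elements `curves`,
#'   `quantified`, `fractions`, `qc_stats`, `workflow_stats`,
#'   `carryover`, `selectivity`, `matrix_effect` and `provenance`.
#' @export
run_pipeline <- function(study = NULL, manifest_file = NULL,
                         peaks_file = NULL, geometry = NULL,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  inputs <- stage("input", {
    if (!is.null(study)) {
      stopifnot(inherits(study, "red_study"))
      if (is.null(geometry)) geometry <- study$geometry
      list(manifest = study$manifest, peaks = study$peaks,
           seed = study$seed)
    } else {
      if (is.null(manifest_file) || is.null(peaks_file))
        stop("either a red_study or manifest_file + peaks_file is required")
      if (is.null(geometry)) geometry <- red_geometry()
      list(manifest = read_manifest(manifest_file),
           peaks = read_peaks(peaks_file), seed = NA_integer_)
    }
  })
  manifest <- inputs$manifest
  peaks <- inputs$peaks

  # blanks carry no internal standard and are assessed on raw areas only
  ratios <- stage("response-ratios", {
    blank_ids <- manifest$sample_id[manifest$type %in%
                                      c("blank", "selectivity_blank")]
    response_ratios(peaks[!(peaks$sample_id %in% blank_ids), ])
  })
  curves <- stage("calibration", fit_run_curves(manifest, ratios))
  quantified <- stage("quantification",
                      quantify_samples(manifest, ratios, curves))
  fractions <- stage("fractionation",
                     fractionate_workflow(quantified, geometry))

  qc_stats <- stage("qc-validation", {
    qc <- quantified[quantified$type == "qc", ]
    if (nrow(qc) == 0) NULL else {
      out <- list()
      for (dl in unique(qc$dilution_label)) {
        sub <- qc[qc$dilution_label == dl, ]
        st <- intra_inter_run(data.frame(level_name = sub$level_name,
                                         nominal = sub$nominal_ng_ml,
                                         run_day = sub$run_day,
                                         measured = sub$analyzed_ng_ml))
        st$dilution_label <- dl
        out[[dl]] <- st
      }
      res <- do.call(rbind, out); rownames(res) <- NULL; res
    }
  })

  workflow_stats <- stage("workflow-validation", {
    if (is.null(fractions)) NULL else {
      out <- list()
      for (lv in unique(fractions$level_name)) {
        sub <- fractions[fractions$level_name == lv, ]
        nominal <- unique(sub$nominal_ng_ml)
        for (run in sort(unique(sub$run_day))) {
          v <- sub$total_conc[sub$run_day == run]
          out[[length(out) + 1L]] <-
            qc_stat_row(v, nominal, lv, sprintf("intra-run %d", run))
        }
        out[[length(out) + 1L]] <-
          qc_stat_row(sub$total_conc, nominal, lv, "inter-run")
      }
      res <- do.call(rbind, out); rownames(res) <- NULL; res
    }
  })

  carryover <- stage("carry-over", {
    blanks <- manifest[manifest$type == "blank", ]
    if (nrow(blanks) == 0) NULL else {
      qa <- peaks[peaks$analyte == "ropivacaine" & peaks$role == "quantifier", ]
      qi <- peaks[peaks$analyte == "d7-ropivacaine" & peaks$role == "quantifier", ]
      out <- list()
      for (dl in unique(blanks$dilution_label)) {
        bl_ids <- blanks$sample_id[blanks$dilution_label == dl]
        lloq <- manifest$sample_id[manifest$type == "calibration" &
                                     manifest$dilution_label == dl &
                                     manifest$nominal_ng_ml ==
                                     min(manifest$nominal_ng_ml[
                                       manifest$type == "calibration" &
                                         manifest$dilution_label == dl])]
        reg_ids <- manifest$sample_id[manifest$type == "calibration" &
                                        manifest$dilution_label == dl]
        out[[dl]] <- carryover_assess(
          qa$area[qa$sample_id %in% bl_ids],
          qi$area[qi$sample_id %in% bl_ids],
          qa$area[qa$sample_id %in% lloq],
          qi$area[qi$sample_id %in% reg_ids])
      }
      out
    }
  })

  selectivity <- stage("selectivity", {
    sel <- manifest[manifest$type == "selectivity_blank", ]
    if (nrow(sel) == 0) NULL else {
      qa <- peaks[peaks$analyte == "ropivacaine" & peaks$role == "quantifier", ]
      qi <- peaks[peaks$analyte == "d7-ropivacaine" & peaks$role == "quantifier", ]
      out <- list()
      for (dl in unique(sel$dilution_label)) {
        ids <- sel$sample_id[sel$dilution_label == dl]
        sub <- sel[sel$dilution_label == dl, ]
        lloq_ids <- manifest$sample_id[manifest$type == "calibration" &
                                         manifest$dilution_label == dl &
                                         manifest$nominal_ng_ml ==
                                         min(manifest$nominal_ng_ml[
                                           manifest$type == "calibration" &
                                             manifest$dilution_label == dl])]
        cal_ids <- manifest$sample_id[manifest$type == "calibration" &
                                        manifest$dilution_label == dl]
        blanks <- data.frame(
          lot = sub$lot,
          area_analyte = qa$area[match(sub$sample_id, qa$sample_id)],
          area_is = qi$area[match(sub$sample_id, qi$sample_id)])
        out[[dl]] <- selectivity_assess(
          blanks,
          lloq_analyte_area = mean(qa$area[qa$sample_id %in% lloq_ids]),
          is_reference_area = mean(qi$area[qi$sample_id %in% cal_ids]))
      }
      out
    }
  })

  matrix_stats <- stage("matrix-effect", {
    mx <- quantified[quantified$type == "matrix_qc", ]
    if (nrow(mx) == 0) NULL else {
      out <- list()
      for (dl in unique(mx$dilution_label)) {
        sub <- mx[mx$dilution_label == dl, ]
        st <- matrix_effect(data.frame(lot = sub$lot,
                                       level_name = sub$level_name,
                                       nominal = sub$nominal_ng_ml,
                                       measured = sub$analyzed_ng_ml))
        st$dilution_label <- dl
        out[[dl]] <- st
      }
      res <- do.call(rbind, out); rownames(res) <- NULL; res
    }
  })

  result <- structure(
    list(curves = curves, quantified = quantified, fractions = fractions,
         qc_stats = qc_stats, workflow_stats = workflow_stats,
         carryover = carryover, selectivity = selectivity,
         matrix_effect = matrix_stats,
         provenance = list(seed = inputs$seed,
                           package_version =
                             as.character(utils::packageVersion("redquant")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "red_pipeline_result")

  if (!is.null(out_dir)) stage("report", write_report(result, out_dir))
  result
}

#' @export
print.red_pipeline_result <- function(x, ...) {
  cat("RED quantification pipeline result\n")
  for (key in names(x$curves)) {
    cv <- x$curves[[key]]
    cat(sprintf("  curve run %d [%s]: slope %.6f, intercept %.6f, R2 %.4f, %s\n",
                cv$run_day, cv$dilution_label, cv$curve$slope,
                cv$curve$intercept, cv$curve$r_squared,
                if (cv$assessment$pass) "accepted" else "REJECTED"))
  }
  if (!is.null(x$workflow_stats)) {
    inter <- x$workflow_stats[x$workflow_stats$scope == "inter-run", ]
    for (k in seq_len(nrow(inter)))
      cat(sprintf("  workflow %s: inter-run accuracy %.2f%%, CV %.2f%% (n=%d) %s\n",
                  inter$level_name[k], inter$accuracy_pct[k], inter$cv_pct[k],
                  inter$n[k], if (inter$pass[k]) "PASS" else "FAIL"))
  }
  invisible(x)
}

#' Write the pipeline report bundle
#'
#' Emits one CSV per result table (curves, per-level curve accuracies,
#' fractions, QC statistics, workflow statistics, matrix effect,
#' selectivity) plus `provenance.txt` recording seed and package version.
#' Reported percentages are rounded half-up to 2 decimals in the
#' `*_rounded` columns; raw values are kept alongside.
#'
#' @param result A `red_pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "red_pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  curves <- do.call(rbind, lapply(result$curves, function(cv)
    data.frame(run_day = cv$run_day, dilution_label = cv$dilution_label,
               slope = cv$curve$slope, intercept = cv$curve$intercept,
               r_squared = cv$curve$r_squared, pass = cv$assessment$pass)))
  emit(curves, "curves")
  lvl <- do.call(rbind, lapply(result$curves, function(cv) {
    lv <- cv$assessment$levels
    lv$run_day <- cv$run_day; lv$dilution_label <- cv$dilution_label; lv
  }))
  emit(lvl, "curve_levels")
  if (!is.null(result$fractions)) emit(result$fractions, "fractions")
  round_cols <- function(df) {
    for (cl in intersect(c("accuracy_pct", "cv_pct"), names(df)))
      df[[paste0(cl, "_rounded")]] <- round_half_up(df[[cl]], 2)
    df
  }
  if (!is.null(result$qc_stats)) emit(round_cols(result$qc_stats), "qc_stats")
  if (!is.null(result$workflow_stats))
    emit(round_cols(result$workflow_stats), "workflow_stats")
  if (!is.null(result$matrix_effect))
    emit(round_cols(result$matrix_effect), "matrix_effect")
  if (!is.null(result$selectivity))
    for (dl in names(result$selectivity))
      emit(result$selectivity[[dl]],
           paste0("selectivity_", gsub(":", "to", dl)))
  prov <- file.path(dir, "provenance.txt")
  writeLines(c(sprintf("seed: %s", result$provenance$seed),
               sprintf("redquant version: %s",
                       result$provenance$package_version),
               sprintf("timestamp (UTC): %s", result$provenance$timestamp)),
             prov)
  invisible(c(paths, prov))
}

#' MRM transitions of the assay data model
#'
#' The quantifier and qualifier transitions for the analyte and its
#' deuterated internal standard, with collision energies and collision
#' cell exit potentials. Quantifier and qualifier of one analyte share the
#' precursor (Q1) mass.
#'
#' @return A data.frame with columns `analyte`, `role`, `q1_mass`,
#'   `q3_mass`, `collision_energy`, `cxp`.
#' @export
mrm_transitions <- function() {
  data.frame(
    analyte = c("ropivacaine", "ropivacaine",
                "d7-ropivacaine", "d7-ropivacaine"),
    role = c("quantifier", "qualifier", "quantifier", "qualifier"),
    q1_mass = c(275.1, 275.1, 282.1, 282.1),
    q3_mass = c(84.0, 98.2, 85.1, 105.1),
    collision_energy = c(59, 55, 57, 55),
    cxp = c(12, 12, 10, 12),
    stringsAsFactors = FALSE)
}
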