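test_that("study design validates levels and times", {
  d <- study_design()
  expect_equal(length(d$calibration_levels_1to1), 9)
  expect_equal(length(d$calibration_levels_1to4), 13)
  expect_error(study_design(calibration_levels_1to1 = c(10, 1)), "ascending")
  expect_error(study_design(qc_levels_1to1 = c(LLOQ = 0.01, HQC = 750)),
               "LLOQ")
  expect_error(study_design(sampling_times = c(5, 5, 10)), "increasing")
})

test_that("identical config and seed give identical CSV bytes", {
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  design <- study_design(n_runs = 1L, n_qc_replicates = 2L,
                         n_cal_replicates = 1L)
  s1 <- simulate_study(design = design, seed = 31L)
  s2 <- simulate_study(design = design, seed = 31L)
  p1 <- write_study_csv(s1, d1)
  p2 <- write_study_csv(s2, d2)
  for (nm in names(p1)) {
    expect_identical(readBin(p1[[nm]], "raw", file.size(p1[[nm]])),
                     readBin(p2[[nm]], "raw", file.size(p2[[nm]])))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("manifest structure covers all arms in injection order", {
  st <- simulate_study(seed = 1)
  m <- st$manifest
  expect_identical(m$injection_index, seq_len(nrow(m)))
  expect_setequal(unique(m$type),
                  c("selectivity_blank", "calibration", "blank", "qc",
                    "matrix_qc", "workflow"))
  # each post-ULOQ blank directly follows the top standard of its curve
  for (dl in c("1:1", "1:4")) {
    blanks <- m[m$type == "blank" & m$dilution_label == dl, ]
    for (k in seq_len(nrow(blanks))) {
      prev <- m[m$injection_index == blanks$injection_index[k] - 1L, ]
      expect_equal(prev$type, "calibration")
      expect_equal(prev$nominal_ng_ml,
                   max(m$nominal_ng_ml[m$type == "calibration" &
                                         m$dilution_label == dl]))
    }
  }
  # matrix arm: 6 lots x 3 reps x 2 levels x 2 dilutions
  mx <- m[m$type == "matrix_qc", ]
  expect_equal(nrow(mx), 6 * 3 * 2 * 2)
  expect_equal(sort(unique(mx$lot)), 1:6)
  # workflow fractions come in buffer/plasma pairs
  wf <- m[m$type == "workflow", ]
  expect_equal(sum(wf$compartment == "buffer"),
               sum(wf$compartment == "plasma"))
})

test_that("ground truth is mass-consistent with the configured spikes", {
  st <- simulate_study(seed = 3)
  tr <- st$truth
  geom <- st$geometry
  expect_equal(tr$chamber_plasma_conc * geom$v_plasma +
                 tr$chamber_buffer_conc * geom$v_buffer,
               tr$spike_ng_ml * geom$v_plasma, tolerance = 1e-9)
  expect_equal(tr$total_conc, tr$spike_ng_ml, tolerance = 1e-9)
  expect_equal(tr$free_conc + tr$bound_conc, tr$total_conc)
})

test_that("PK profiles are zero pre-dose and scale linearly with dose", {
  d <- study_design()
  pk <- simulate_pk_profile(1, d, n_animals = 4, cv_inter = 0, seed = 1)
  expect_true(all(pk$total_conc[pk$time_min <= 0] == 0))
  expect_true(all(pk$total_conc >= 0))
  # zero variability: identical profiles across animals
  wide <- split(pk$total_conc, pk$animal)
  for (k in 2:4) expect_equal(wide[[k]], wide[[1]])
  # 3:1 dose scaling triples concentrations
  pk3 <- simulate_pk_profile(3, d, n_animals = 4, cv_inter = 0, seed = 1)
  expect_equal(pk3$total_conc, 3 * pk$total_conc)
  # lognormal variability is reproducible and positive
  pa <- simulate_pk_profile(1, d, cv_inter = 0.4, seed = 9)
  pb <- simulate_pk_profile(1, d, cv_inter = 0.4, seed = 9)
  expect_identical(pa, pb)
})

test_that("simulated PK peak is in a plausible range for a 1 mg/kg dose", {
  pk <- simulate_pk_profile(1, study_design(), cv_inter = 0, seed = 1)
  peak <- max(pk$total_conc)
  expect_gt(peak, 50)
  expect_lt(peak, 1000)
  # peak occurs at an interior sampling time
  tmax <- pk$time_min[which.max(pk$total_conc)]
  expect_true(tmax > 0 && tmax < 240)
})
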