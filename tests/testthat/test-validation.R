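test_that("accuracy reproduces the validation-table arithmetic", {
  expect_equal(accuracy(305.82, 300), 101.94)
  expect_equal(accuracy(5, 5), 100)
  expect_equal(accuracy(821.76, 750), 109.568)
  expect_error(accuracy(1, 0), "> 0")
})

test_that("precision uses the n-1 sample standard deviation", {
  expect_equal(precision_cv(c(3, 3, 3)), 0)
  expect_equal(precision_cv(c(1, 2, 3)), 50)
  expect_equal(precision_cv(c(10, 10, 10, 12)), 100 * 1 / 10.5)
  expect_equal(round(precision_cv(c(10, 10, 10, 12)), 2), 9.52)
  expect_error(precision_cv(5), "2 values")
})

test_that("intra/inter-run statistics pool replicates and apply dual bands", {
  qc <- expand.grid(rep = 1:6, run_day = 1:3)
  qc <- data.frame(level_name = "MQC", nominal = 300, run_day = qc$run_day,
                   measured = 300)
  st <- intra_inter_run(qc)
  expect_equal(nrow(st), 4)  # 3 intra + 1 inter
  expect_true(all(st$accuracy_pct == 100 & st$cv_pct == 0 & st$pass))
  inter <- st[st$scope == "inter-run", ]
  expect_equal(inter$n, 18)

  # an accuracy of 118% passes at the LLOQ (80-120) but fails at LQC (85-115)
  mk <- function(level) data.frame(level_name = level, nominal = 100,
                                   run_day = 1, measured = rep(118, 6))
  expect_true(intra_inter_run(mk("LLOQ"))$pass[1])
  expect_false(intra_inter_run(mk("LQC"))$pass[1])

  # band edges are inclusive
  edge <- data.frame(level_name = "HQC", nominal = 100, run_day = 1,
                     measured = rep(115, 6))
  expect_true(all(intra_inter_run(edge)$pass))

  # absent expected levels are reported, not dropped
  st <- intra_inter_run(mk("LLOQ"), expected_levels = c("LLOQ", "HQC"))
  expect_true("HQC" %in% st$level_name)
  expect_equal(st$n[st$level_name == "HQC"], 0)
})

test_that("inter-run pooling matches direct computation on unbalanced runs", {
  set.seed(5)
  qc <- data.frame(level_name = "HQC", nominal = 750,
                   run_day = rep(1:3, each = 6),
                   measured = rnorm(18, 760, 20))
  st <- intra_inter_run(qc)
  inter <- st[st$scope == "inter-run", ]
  expect_equal(inter$mean, mean(qc$measured))
  expect_equal(inter$cv_pct, 100 * sd(qc$measured) / mean(qc$measured))
  expect_equal(inter$accuracy_pct, 100 * mean(qc$measured) / 750)
})

test_that("matrix effect flags a biased lot and accepts unbiased lots", {
  qc <- expand.grid(lot = 1:6, rep = 1:3)
  qc <- data.frame(lot = qc$lot, level_name = "LQC", nominal = 10,
                   measured = 10)
  st <- matrix_effect(qc)
  expect_true(all(st$pass))
  # one lot with a x1.25 matrix factor fails the +/-15% accuracy band
  qc$measured[qc$lot == 3] <- 12.5
  st <- matrix_effect(qc)
  expect_false(st$pass[st$lot == 3])
  expect_true(all(st$pass[st$lot != 3]))
  # fewer lots than designed: warning, statistics still computed
  expect_warning(st5 <- matrix_effect(qc[qc$lot <= 5, ]), "lots")
  expect_equal(length(unique(st5$lot)), 5)
})

test_that("carry-over thresholds are 20% (analyte) and 5% (IS), inclusive", {
  r <- carryover_assess(0, 0, lloq_analyte_areas = c(100, 100),
                        is_areas = c(1000, 1000))
  expect_true(r$pass)
  r <- carryover_assess(25, 10, lloq_analyte_areas = 100, is_areas = 1000)
  expect_false(r$analyte_pass)
  r <- carryover_assess(20, 50, lloq_analyte_areas = 100, is_areas = 1000)
  expect_true(r$analyte_pass)   # exactly 20%: inclusive
  expect_true(r$is_pass)        # exactly 5%: inclusive
  r <- carryover_assess(10, 51, lloq_analyte_areas = 100, is_areas = 1000)
  expect_false(r$is_pass)
  expect_error(carryover_assess(numeric(0), numeric(0), 100, 1000),
               "blank")
})

test_that("stability applies the +/-15% mean-accuracy rule per condition", {
  qc <- data.frame(condition = "freeze_thaw", level_name = "HQC",
                   nominal = 750, measured = c(800, 805, 802.68))
  st <- stability_assess(qc)
  expect_equal(st$accuracy_pct, 100 * mean(qc$measured) / 750)
  expect_true(st$pass)
  # 20% degradation fails
  deg <- data.frame(condition = "benchtop", level_name = "HQC",
                    nominal = 750, measured = rep(600, 3))
  expect_false(stability_assess(deg)$pass)
  expect_equal(stability_assess(deg)$accuracy_pct, 80)
  expect_error(stability_assess(data.frame(condition = "microwave",
                                           level_name = "HQC", nominal = 1,
                                           measured = 1)),
               "unknown storage condition")
})

test_that("reinjection comparison reports both reference bases", {
  first <- data.frame(level_name = rep(c("MQC", "HQC"), each = 3),
                      nominal = rep(c(300, 750), each = 3),
                      measured = c(310, 312, 308, 745, 750, 755))
  same <- reinjection_compare(first, first)
  expect_equal(same$accuracy_diff, c(0, 0))
  expect_equal(same$reinjection_vs_first_pct, c(100, 100))
  shifted <- first; shifted$measured <- shifted$measured * 1.02
  cmp <- reinjection_compare(first, shifted)
  expect_equal(cmp$reinjection_vs_first_pct, c(102, 102))
  expect_equal(cmp$accuracy_reinjection, cmp$accuracy_first * 1.02)
  expect_error(reinjection_compare(first, first[first$level_name == "MQC", ]),
               "mismatch")
})

test_that("recovery ratios follow the spike-before/after design", {
  same <- data.frame(area_analyte = rep(100, 5), area_is = rep(80, 5))
  r <- recovery(same, same, same)
  expect_equal(r$precipitation_analyte_pct, 100)
  expect_equal(r$overall_ratio_pct, 100)
  expect_true(r$pass)

  a <- data.frame(area_analyte = rep(120, 5), area_is = rep(100, 5))
  b <- data.frame(area_analyte = rep(100, 5), area_is = rep(100, 5))
  r <- recovery(a, b, b)
  expect_equal(r$precipitation_analyte_pct, 120)
  expect_equal(r$overall_analyte_pct, 120)
  expect_equal(r$precipitation_ratio_pct, 120)

  # analyte overall 99.7% vs IS 103.5%: |diff| <= 15 points -> pass
  a2 <- data.frame(area_analyte = rep(99.7, 5), area_is = rep(103.5, 5))
  c2 <- data.frame(area_analyte = rep(100, 5), area_is = rep(100, 5))
  r <- recovery(a2, c2, c2)
  expect_equal(r$overall_analyte_pct, 99.7)
  expect_equal(r$overall_is_pct, 103.5)
  expect_true(r$pass)
  # a 20-point gap fails
  a3 <- data.frame(area_analyte = rep(100, 5), area_is = rep(121, 5))
  expect_false(recovery(a3, c2, c2)$pass)
  expect_error(recovery(a2, c2, data.frame(area_analyte = rep(0, 5),
                                           area_is = rep(1, 5))),
               "approach C")
})

test_that("selectivity thresholds are inclusive per lot", {
  blanks <- data.frame(lot = 1:6,
                       area_analyte = c(0, 5, 20, 21, 10, 0),
                       area_is = c(0, 10, 50, 10, 51, 0))
  st <- selectivity_assess(blanks, lloq_analyte_area = 100,
                           is_reference_area = 1000)
  expect_equal(st$analyte_pass, c(T, T, T, F, T, T))
  expect_equal(st$is_pass, c(T, T, T, T, F, T))
  expect_equal(st$pass, st$analyte_pass & st$is_pass)
  expect_warning(selectivity_assess(blanks[1:3, ], 100, 1000), "lots")
})
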