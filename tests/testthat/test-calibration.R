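test_that("1/x-weighted fit matches the normal-equations oracle", {
  pts <- data.frame(nominal_conc = c(1, 10, 100),
                    response_ratio = c(1.0, 9.0, 105.0))
  cv <- fit_calibration(pts)
  o <- wls_normal_equations(pts$nominal_conc, pts$response_ratio,
                            1 / pts$nominal_conc)
  expect_equal(cv$slope, unname(o["slope"]), tolerance = 1e-12)
  expect_equal(cv$intercept, unname(o["intercept"]), tolerance = 1e-12)
})

test_that("weighted-fit oracle equivalence holds on random small instances", {
  set.seed(101)
  for (i in 1:200) {
    n_lv <- sample(2:6, 1)
    x <- rep(sort(10^runif(n_lv, -1.3, 3)), each = sample(1:3, 1))
    y <- pmax(0.5 * x + rnorm(length(x), 0, 0.05 * (x + 0.1)), 0)
    cv <- fit_calibration(data.frame(nominal_conc = x, response_ratio = y))
    o <- wls_normal_equations(x, y, 1 / x)
    expect_equal(cv$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(cv$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
})

test_that("noiseless data reproduce the generating line exactly", {
  # generating truth: the assay's reported 1:1 regression constants
  levels <- c(0.05, 1, 10, 100, 200, 400, 600, 800, 1000)
  y <- 0.727432 * levels - 0.007252
  cv <- fit_calibration(data.frame(nominal_conc = levels, response_ratio = y))
  expect_equal(cv$slope, 0.727432, tolerance = 1e-10)
  expect_equal(cv$intercept, -0.007252, tolerance = 1e-10)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)

  two <- fit_calibration(data.frame(nominal_conc = c(1, 2),
                                    response_ratio = c(1, 2)))
  expect_equal(two$slope, 1, tolerance = 1e-12)
  expect_equal(two$intercept, 0, tolerance = 1e-12)
})

test_that("degenerate and invalid calibration inputs are rejected", {
  expect_error(fit_calibration(data.frame(nominal_conc = c(1, 1),
                                          response_ratio = c(1, 1.1))),
               "2 distinct")
  expect_error(fit_calibration(data.frame(nominal_conc = c(0, 1),
                                          response_ratio = c(0, 1))),
               "> 0")
  expect_error(fit_calibration(data.frame(nominal_conc = c(-1, 1),
                                          response_ratio = c(0, 1))),
               "> 0")
})

test_that("back-calculation inverts prediction and clamps below zero", {
  levels <- c(0.05, 1, 10, 100, 1000)
  cv <- fit_calibration(data.frame(nominal_conc = levels,
                                   response_ratio = 0.727432 * levels - 0.007252))
  # ratio at the intercept maps to zero concentration
  expect_equal(back_calculate(cv, cv$intercept)$conc_ng_ml, 0)
  # round trip through prediction
  conc <- c(0.05, 0.3, 7, 350, 999)
  expect_equal(back_calculate(cv, predict(cv, conc))$conc_ng_ml, conc,
               tolerance = 1e-9)
  # reported worked value: ratio 0.720180 on the reported constants
  expect_equal(back_calculate(cv, 0.720180)$conc_ng_ml, 1.000,
               tolerance = 1e-3)
  # below-intercept ratios clamp to zero with a flag
  bc <- back_calculate(cv, cv$intercept - 0.01)
  expect_equal(bc$conc_ng_ml, 0)
  expect_true(bc$flag_below_zero)
})

test_that("R-squared is invariant under uniform rescaling of ratios", {
  set.seed(7)
  x <- c(0.05, 1, 10, 100, 1000)
  y <- 0.7 * x + rnorm(5, 0, 0.5)
  y <- pmax(y, 0.001)
  r2 <- fit_calibration(data.frame(nominal_conc = x, response_ratio = y))$r_squared
  for (k in c(0.1, 3, 100)) {
    r2k <- fit_calibration(data.frame(nominal_conc = x,
                                      response_ratio = k * y))$r_squared
    expect_equal(r2k, r2, tolerance = 1e-12)
  }
})

test_that("curve acceptance applies the dual bands and the 75% rule", {
  mk_curve <- function(acc) {
    # construct a curve object with prescribed per-level accuracies
    lv <- data.frame(nominal_conc = seq_along(acc),
                     mean_back_calc = seq_along(acc) * acc / 100)
    lv$accuracy_pct <- acc
    structure(list(slope = 1, intercept = 0, r_squared = 0.999,
                   weighting = "1/x", dilution_label = "1:1",
                   n = length(acc), levels = lv),
              class = "calibration_curve")
  }
  # all perfect
  a <- assess_curve(mk_curve(rep(100, 9)))
  expect_true(a$pass)
  # LLOQ at 119% passes its 20% band; the same accuracy at another level fails
  a <- assess_curve(mk_curve(c(119, rep(100, 8))))
  expect_true(a$levels$pass[1])
  a <- assess_curve(mk_curve(c(100, 119, rep(100, 7))))
  expect_false(a$levels$pass[2])
  # 3 of 9 levels failing -> 67% < 75% -> curve fails
  a <- assess_curve(mk_curve(c(100, 130, 130, 130, rep(100, 5))))
  expect_equal(a$frac_levels_pass, 6 / 9)
  expect_false(a$pass)
  # 2 of 9 failing -> 78% passes
  a <- assess_curve(mk_curve(c(100, 130, 130, rep(100, 6))))
  expect_true(a$pass)
  # band edges are inclusive
  a <- assess_curve(mk_curve(c(120, 115, rep(100, 7))))
  expect_true(all(a$levels$pass[1:2]))
  # low R2 fails regardless of accuracies
  bad <- mk_curve(rep(100, 9)); bad$r_squared <- 0.98
  expect_false(assess_curve(bad)$pass)
})

test_that("ion-ratio check compares against the reference with tolerance", {
  expect_true(ion_ratio_check(100, 40, 0.4)$pass)
  r <- ion_ratio_check(100, 0.4 * 1.5 * 100, 0.4, tolerance_frac = 0.3)
  expect_false(r$pass)
  r <- ion_ratio_check(100, 0, 0.4)
  expect_false(r$pass)
  expect_match(r$reason, "zero qualifier")
})
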