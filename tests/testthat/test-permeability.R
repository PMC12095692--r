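test_that("a flat PMF reproduces the analytic permeability", {
  prof <- pmf_profile(seq(-20, 20, 0.1), rep(0, 401))
  lp <- peff_from_pmf(prof, diffusivity = 1e-5, bounds = c(-20, 20))
  # P = D / L with L = 40 Angstrom = 4e-7 cm -> 25 cm/s
  expect_equal(attr(lp, "peff"), 25, tolerance = 1e-3)
  expect_equal(as.numeric(lp), log10(25), tolerance = 1e-4)
})

test_that("a square barrier matches its closed form to 0.1%", {
  z <- seq(-20, 20, 0.1)
  G <- 3 # kcal/mol
  # grid values jump between 5.9 and 6.0, i.e. the ideal step sits at the
  # cell midpoint 5.95, where the trapezoidal rule integrates the step
  # exactly; the effective barrier width is 11.9 Angstrom
  dG <- ifelse(abs(z) < 5.95, G, 0)
  prof <- pmf_profile(z, dG)
  kBT <- 0.0019872041 * 300
  D <- 1e-5
  span_cm <- 40e-8; w_cm <- 11.9e-8
  peff_closed <- D / ((span_cm - w_cm) + w_cm * exp(G / kBT))
  lp <- peff_from_pmf(prof, diffusivity = D, bounds = c(-20, 20))
  expect_equal(attr(lp, "peff"), peff_closed, tolerance = 1e-3)
})

test_that("permeability decreases with barrier height, increases with D", {
  p1 <- gen_pmf_profile(barrier_height = 3, well_depth = 0)
  p2 <- gen_pmf_profile(barrier_height = 6, well_depth = 0)
  lp1 <- peff_from_pmf(p1, bounds = c(-30, 30))
  lp2 <- peff_from_pmf(p2, bounds = c(-30, 30))
  expect_lt(as.numeric(lp2), as.numeric(lp1))
  lpD <- peff_from_pmf(p1, diffusivity = 2e-5, bounds = c(-30, 30))
  expect_gt(as.numeric(lpD), as.numeric(lp1))
  # pointwise increase of dG strictly decreases P_eff
  p3 <- p1
  p3$dG <- p1$dG + ifelse(abs(p1$z) < 5, 0.5, 0)
  expect_lt(as.numeric(peff_from_pmf(p3, bounds = c(-30, 30))),
            as.numeric(lp1))
})

test_that("profiles not referenced to water are rejected", {
  expect_error(pmf_profile(seq(-20, 20, 1), rep(1, 41)),
               "water phase")
  prof <- gen_pmf_profile()
  expect_error(peff_from_pmf(prof, bounds = c(-100, 100)), "narrower")
  expect_error(peff_from_pmf(prof, diffusivity = -1), "positive")
})

test_that("calibration recovers an exact line to machine precision", {
  x <- c(-4, -2, 0, 1)
  pairs <- tibble::tibble(log_peff_pmf = x,
                          log_peff_pampa = 0.3 * x - 5.0)
  cal <- fit_calibration(pairs)
  expect_equal(cal$slope, 0.3, tolerance = 1e-12)
  expect_equal(cal$intercept, -5.0, tolerance = 1e-12)
  expect_error(fit_calibration(pairs[1, ]), ">= 2")
  expect_error(fit_calibration(
    tibble::tibble(log_peff_pmf = c(1, 1), log_peff_pampa = c(0, 1))),
    "degenerate")
})

test_that("the five shipped reference pairs give the published line", {
  cal <- fit_calibration(reference_calibration_pairs())
  # hand OLS over the printed pairs
  expect_equal(cal$slope, 0.271, tolerance = 0.005)
  expect_equal(cal$intercept, -5.306, tolerance = 0.005)
  # the fit reproduces every training y within 0.02 log units
  pred <- apply_calibration(cal,
                            reference_calibration_pairs()$log_peff_pmf)
  expect_true(all(abs(pred$log_peff_pampa -
                        reference_calibration_pairs()$log_peff_pampa) <
                    0.02))
  # training RMS does not exceed the residual sd
  rms <- sqrt(mean((pred$log_peff_pampa -
                      reference_calibration_pairs()$log_peff_pampa)^2))
  expect_lte(rms, cal$residual_sd)
})

test_that("leave-one-out calibration predicts the held-out compounds", {
  pairs <- reference_calibration_pairs()
  loo_m23 <- fit_calibration(pairs[pairs$compound != "M23", ])
  pred_m23 <- apply_calibration(loo_m23, 0.56)$log_peff_pampa
  expect_equal(pred_m23, -5.16, tolerance = 0.02)
  loo_m27h <- fit_calibration(pairs[pairs$compound != "M27_H", ])
  pred_m27h <- apply_calibration(loo_m27h, -2.95)$log_peff_pampa
  expect_equal(pred_m27h, -6.10, tolerance = 0.02)
})

test_that("classification bands follow the published thresholds", {
  expect_equal(classify_permeability(7.00e-6), "high")
  expect_equal(classify_permeability(7.86e-7), "low_to_medium")
  expect_equal(classify_permeability(3.56e-7), "low")
  expect_equal(classify_permeability(3e-6), "medium_high_gap")
  # boundaries
  expect_equal(classify_permeability(4.7e-6), "medium_high_gap")
  expect_equal(classify_permeability(4.7000001e-6), "high")
  expect_equal(classify_permeability(7e-7), "low_to_medium")
  expect_equal(classify_permeability(2.1e-6), "low_to_medium")
  expect_error(classify_permeability(-1), "positive")
})

test_that("a slope-zero model maps every input to its intercept", {
  cal <- structure(list(slope = 0, intercept = -6, n_ref = 2,
                        residual_sd = 0, p0 = 1, fit = NULL,
                        pairs = NULL), class = "lf_calibration")
  out <- apply_calibration(cal, c(-10, 0, 10))
  expect_equal(out$log_peff_pampa, rep(-6, 3))
  expect_equal(out$peff, rep(1e-6, 3))
})

test_that("uncertainties propagate linearly through the calibration", {
  cal <- fit_calibration(reference_calibration_pairs())
  out <- apply_calibration(cal, 0.56, se = 0.23)
  expect_equal(out$se_log_peff_pampa, abs(cal$slope) * 0.23)
})
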