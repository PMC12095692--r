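test_that("vehicle normalization maps the control level to 1", {
  raw <- tibble::tibble(x = c(1, 10, 100),
                        y_rep1 = c(2000, 1000, 500),
                        y_rep2 = c(2000, 1000, 500))
  s <- normalize_to_vehicle(raw, vehicle = c(1900, 2100))
  m <- dplyr::filter(s, x == 1)
  expect_equal(unique(m$y), 1)
  expect_equal(dplyr::filter(s, x == 100)$y, c(0.25, 0.25))
  expect_error(normalize_to_vehicle(raw, vehicle = c(0, 0)), "positive")
})

test_that("a noiseless 4PL curve returns its planted IC50 exactly", {
  s <- gen_dose_response(ic50 = 62.14, hill = 1.2, top = 1, bottom = 0.05,
                         noise_sd = 0, seed = 1)
  f <- fit_ic50(s)
  expect_equal(f$ic50, 62.14, tolerance = 1e-3)
  expect_false(f$extrapolated)
  expect_false(f$inactive)
  # RSS at the optimum cannot exceed RSS at the planted truth
  truth_rss <- sum((s$y - (0.05 + 0.95 / (1 + (s$x / 62.14)^1.2)))^2)
  expect_lte(f$rss, truth_rss + 1e-9)
})

test_that("constant response is rejected as having no dose dependence", {
  s <- titration_series(10^seq(0, 3, length.out = 8), rep(1, 8))
  expect_error(fit_ic50(s), "no dose dependence")
})

test_that("noisy IC50 recovery stays within 15% across seeds", {
  hits <- vapply(1:25, function(seed) {
    s <- gen_dose_response(ic50 = 33, noise_sd = 0.03, seed = seed)
    abs(fit_ic50(s)$ic50 - 33) / 33 < 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the exact isotherm obeys its limiting regimes", {
  # L = K >> Tt: half-bound (hyperbolic limit)
  expect_equal(bound_fraction(100, 1e-3, 100), 0.5, tolerance = 1e-3)
  # saturating ligand
  expect_equal(bound_fraction(1e9, 0.1, 39), 1, tolerance = 1e-6)
  # approaches the hyperbola as Tt -> 0 (depletion vanishes)
  L <- 10^seq(-2, 3, length.out = 20)
  expect_lt(max(abs(bound_fraction(L, 39e-6, 39) - L / (L + 39))), 1e-6)
  # at Tt = K/1000 the residual depletion bias is itself of order T/(8K)
  expect_lt(max(abs(bound_fraction(L, 39e-3, 39) - L / (L + 39))),
            39e-3 / (8 * 39) * 1.3)
})

test_that("a noiseless MST titration returns its planted K_D exactly", {
  s <- gen_mst_titration(kd = 39, target_conc_nM = 100, noise_sd = 0,
                         seed = 1)
  f <- fit_mst_kd(s, target_conc_nM = 100)
  expect_equal(f$kd_app, 39, tolerance = 1e-3)
  expect_false(f$flagged)
})

test_that("noisy K_D recovery stays within 25% across seeds", {
  # triplicate dilution series, noise 5% of the response amplitude
  hits <- vapply(1:25, function(seed) {
    s <- gen_mst_titration(kd = 39, f_bound = 10, noise_sd = 0.5,
                           seed = seed)
    abs(fit_mst_kd(s)$kd_app - 39) / 39 < 0.25
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("noiseless melting curves return their planted midpoints", {
  for (tm in c(74.5, 84.1)) {
    mc <- gen_melting_curve(tm = tm, noise_frac = 0, seed = 1)
    f <- compute_tm(mc)
    expect_equal(f$tm, tm, tolerance = 0.1)
    expect_equal(f$tm_derivative, tm, tolerance = 0.1)
  }
})

test_that("a flat ratio yields no transition", {
  mc <- gen_melting_curve(ratio_lo = 0.9, ratio_hi = 0.9,
                          baseline_slope = 0, noise_frac = 0, seed = 1)
  expect_error(compute_tm(mc), "no transition detected")
})

test_that("Tm is invariant to rescaling both channels by one factor", {
  mc <- gen_melting_curve(tm = 74.5, noise_frac = 0.005, seed = 3)
  f1 <- compute_tm(mc)
  mc2 <- dplyr::mutate(mc, f330 = 7.3 * f330, f350 = 7.3 * f350)
  f2 <- compute_tm(mc2)
  expect_equal(f1$tm, f2$tm, tolerance = 1e-6)
})

test_that("delta_tm is the signed difference of fitted midpoints", {
  apo <- compute_tm(gen_melting_curve(tm = 74.5, noise_frac = 0, seed = 1))
  cplx <- compute_tm(gen_melting_curve(tm = 72.9, noise_frac = 0,
                                       seed = 2))
  expect_equal(delta_tm(apo, cplx), -1.6, tolerance = 0.05)
  expect_equal(delta_tm(apo, apo), 0)
  near <- compute_tm(gen_melting_curve(tm = 74.4, noise_frac = 0,
                                       seed = 3))
  expect_equal(delta_tm(apo, near), -0.1, tolerance = 0.05)
})

test_that("STD effects normalize to the chosen reference", {
  rec <- gen_std_intensities(effects = c(H1 = 0.41, H2 = 0.66, H3 = 0.91))
  out <- std_epitope_map(rec, reference = "max")
  expect_equal(out$relative_pct,
               100 * c(0.41, 0.66, 0.91) / 0.91, tolerance = 1e-9)
  expect_equal(max(out$relative_pct), 100)

  # single proton is its own reference
  one <- std_epitope_map(tibble::tibble(label = "a", i_sat = 3, i_0 = 10))
  expect_equal(one$relative_pct, 100)

  # a named reference smaller than the max pushes others above 100%
  named <- std_epitope_map(rec, reference = "H2")
  expect_gt(max(named$relative_pct), 100)
  expect_equal(named$relative_pct[named$label == "H2"], 100)

  # attenuation convention flips the ordering
  att <- std_epitope_map(rec, reference = "max",
                         direction = "attenuation")
  expect_equal(att$effect, 1 - c(0.41, 0.66, 0.91), tolerance = 1e-9)

  expect_error(
    std_epitope_map(tibble::tibble(label = "bad", i_sat = 1, i_0 = 0)),
    "i_0 must be positive")
})

test_that("a noiseless pH titration returns its planted pKa exactly", {
  s <- gen_ph_titration(pka = 6.69, noise_sd = 0, seed = 1)
  f <- fit_pka(s)
  expect_equal(f$pka, 6.69, tolerance = 0.01)
  expect_equal(f$delta_acid, 1.20, tolerance = 1e-3)
  expect_equal(f$delta_base, 0.95, tolerance = 1e-3)
})

test_that("flat chemical shifts are rejected", {
  s <- titration_series(seq(2, 13, 0.5), rep(1.0, 23))
  expect_error(fit_pka(s), "no titration transition")
})

test_that("pKa recovery holds for either shift-limit orientation", {
  # delta_acid above delta_base and vice versa seed the fit from opposite
  # limits; the estimate must not depend on that orientation
  up <- gen_ph_titration(pka = 7.8, delta_acid = 0.95, delta_base = 1.20,
                         noise_sd = 0, seed = 3)
  down <- gen_ph_titration(pka = 7.8, delta_acid = 1.20,
                           delta_base = 0.95, noise_sd = 0, seed = 3)
  expect_equal(fit_pka(up)$pka, fit_pka(down)$pka, tolerance = 1e-6)
  # single-proton noisy recovery stays well within 4 sigma of the
  # information bound (~0.026 at this design)
  errs <- vapply(1:25, function(seed) {
    abs(fit_pka(gen_ph_titration(pka = 7.8, noise_sd = 0.005,
                                 seed = seed))$pka - 7.8)
  }, numeric(1))
  expect_true(all(errs < 0.1))
})

test_that("protonated fraction follows the closed form", {
  expect_equal(protonated_fraction(7.0, 7.0), 0.5)
  expect_equal(protonated_fraction(6.65, 7.5), 1 / (1 + 10^0.85),
               tolerance = 1e-12)
  expect_equal(protonated_fraction(6.65, 7.5), 0.124, tolerance = 2e-3)
  expect_equal(protonated_fraction(7.0, -50), 1)
  # the ~1:1 ratio case: pKa 7.8 at pH 7.5
  expect_equal(protonated_fraction(7.8, 7.5), 1 / (1 + 10^-0.3),
               tolerance = 1e-12)
})
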