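#' PMF profile along the membrane normal
#'
#' Free energy of the permeant as a function of distance `z` from the
#' bilayer center, referenced to zero in the water phase (the profile must
#' decay to ~0 at both ends).
#'
#' @param z Distance from the bilayer center in Angstrom, strictly
#'   increasing, spanning the membrane symmetrically.
#' @param dG Free energy in kcal/mol at each `z`.
#' @param temperature Simulation temperature in K (default 300).
#' @return An `lf_pmf` tibble with columns `z`, `dG` and attribute
#'   `temperature`.
#' @export
pmf_profile <- function(z, dG, temperature = 300) {
  z <- as.numeric(z); dG <- as.numeric(dG)
  stopifnot(length(z) == length(dG), length(z) >= 5)
  if (any(diff(z) <= 0)) abort("`z` must be strictly increasing")
  if (any(!is.finite(dG))) abort("`dG` must be finite")
  if (abs(dG[1]) > 0.1 || abs(dG[length(dG)]) > 0.1)
    abort("profile must be referenced to zero in the water phase (|dG| <= 0.1 kcal/mol at both ends)")
  out <- tibble(z = z, dG = dG)
  attr(out, "temperature") <- temperature
  class(out) <- c("lf_pmf", class(out))
  out
}

#' Read a PMF profile CSV (columns z_angstrom, dG_kcal_mol)
#' @param path CSV path.
#' @param temperature Temperature in K.
#' @return An `lf_pmf`.
#' @export
read_pmf_csv <- function(path, temperature = 300) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("z_angstrom", "dG_kcal_mol") %in% names(df)))
  pmf_profile(df$z_angstrom, df$dG_kcal_mol, temperature)
}

.KB_KCAL <- 0.0019872041 # Boltzmann constant, kcal/mol/K

#' Effective permeability from a PMF (solubility-diffusion model)
#'
#' Inhomogeneous solubility-diffusion resistance integral:
#' `1/P_eff = integral exp(dG(z)/kBT) / D(z) dz` over the membrane span,
#' evaluated by the trapezoidal rule with `z` converted to cm. Returns
#' `log10(P_eff / P0)` with `P0 = 1 cm/s`. The default constant
#' diffusivity (1e-5 cm^2/s) introduces a systematic bias that the PAMPA
#' calibration regression absorbs; calibration is therefore mandatory for
#' reported permeabilities.
#'
#' @param profile An `lf_pmf`.
#' @param diffusivity Constant diffusivity in cm^2/s, or a vector over the
#'   profile grid (D(z) profile).
#' @param bounds Length-2 z-range (Angstrom) of the membrane; default: the
#'   span where `|dG| > 0.1` kcal/mol (whole profile if the profile is
#'   everywhere below that).
#' @return `log10(P_eff/P0)` with attributes `peff` (cm/s) and
#'   `resistance` (s/cm).
#' @export
peff_from_pmf <- function(profile, diffusivity = 1e-5, bounds = NULL) {
  stopifnot(inherits(profile, "lf_pmf"))
  if (any(diffusivity <= 0)) abort("diffusivity must be positive")
  temperature <- attr(profile, "temperature") %||% 300
  z <- profile$z; dG <- profile$dG
  D <- if (length(diffusivity) == 1) rep(diffusivity, length(z)) else {
    if (length(diffusivity) != length(z))
      abort("D(z) profile must match the PMF grid")
    diffusivity
  }
  if (is.null(bounds)) {
    inside <- which(abs(dG) > 0.1)
    bounds <- if (length(inside) >= 2) range(z[inside]) else range(z)
  }
  bounds <- sort(bounds)
  if (bounds[1] < min(z) || bounds[2] > max(z))
    abort("profile narrower than the requested bounds")
  sel <- z >= bounds[1] & z <= bounds[2]
  if (sum(sel) < 2) abort("fewer than 2 grid points inside bounds")
  kBT <- .KB_KCAL * temperature
  integrand <- exp(dG[sel] / kBT) / D[sel]
  resistance <- pracma::trapz(z[sel] * 1e-8, integrand) # Angstrom -> cm
  peff <- 1 / resistance
  out <- log10(peff)
  attr(out, "peff") <- peff
  attr(out, "resistance") <- resistance
  out
}

#' Fit the PAMPA calibration regression
#'
#' Ordinary least squares of experimental `log10(P_eff/PAMPA / P0)` on
#' computed `log10(P_eff/PMF / P0)` over reference compounds.
#'
#' @param pairs Data frame with columns `log_peff_pmf`, `log_peff_pampa`
#'   (one row per reference compound).
#' @return An `lf_calibration` list: `slope`, `intercept`, `n_ref`,
#'   `residual_sd`, `p0` (1 cm/s), `fit` (the lm object), `pairs`.
#' @export
fit_calibration <- function(pairs) {
  df <- as_tibble(pairs)
  stopifnot(all(c("log_peff_pmf", "log_peff_pampa") %in% names(df)))
  if (nrow(df) < 2) abort("need >= 2 calibration pairs")
  if (diff(range(df$log_peff_pmf)) < 1e-12)
    abort("calibration x values are degenerate (all equal)")
  fit <- stats::lm(log_peff_pampa ~ log_peff_pmf, data = df)
  # an exact line is legitimate here; silence lm's perfect-fit warning
  sigma <- suppressWarnings(summary(fit)$sigma)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_ref = nrow(df), residual_sd = sigma, p0 = 1,
    fit = fit, pairs = df),
    class = "lf_calibration")
}

#' @export
print.lf_calibration <- function(x, ...) {
  cat(sprintf(
    "<lf_calibration> log Peff/PAMPA = %.4f x log Peff/PMF + %.4f (n = %d, sd %.3g)\n",
    x$slope, x$intercept, x$n_ref, x$residual_sd))
  invisible(x)
}

#' Built-in PAMPA calibration pairs
#'
#' The five (log P_eff/PMF, log P_eff/PAMPA) pairs for the published lead
#' compounds M23, M23_H, M27, M27_H and M10 (the `_H` suffix marks the
#' protonated species). They reconstruct the calibration line relating
#' PMF-computed to PAMPA-measured log permeabilities; the original
#' nine-compound reference set lives in supplementary material that is not
#' redistributed here.
#'
#' @return Tibble with columns `compound`, `log_peff_pmf`,
#'   `log_peff_pampa`.
#' @export
reference_calibration_pairs <- function() {
  tibble(
    compound = c("M23", "M23_H", "M27", "M27_H", "M10"),
    log_peff_pmf = c(0.56, -4.22, 0.75, -2.95, 0.83),
    log_peff_pampa = c(-5.16, -6.45, -5.10, -6.10, -5.08))
}

#' Classify an effective permeability
#'
#' Bands: `high` above 4.7e-6 cm/s, `low_to_medium` within
#' [7e-7, 2.1e-6] cm/s, `low` below 7e-7 cm/s, and `medium_high_gap` for
#' the unnamed interval between the low-to-medium and high bands.
#'
#' @param peff Effective permeability in cm/s (positive).
#' @return Character class, vectorized over `peff`.
#' @export
classify_permeability <- function(peff) {
  if (any(peff <= 0)) abort("`peff` must be positive")
  dplyr::case_when(
    peff > 4.7e-6 ~ "high",
    peff > 2.1e-6 ~ "medium_high_gap",
    peff >= 7e-7 ~ "low_to_medium",
    TRUE ~ "low")
}

#' Apply a PAMPA calibration to computed log permeabilities
#'
#' Maps `log10(P_eff/PMF / P0)` through the calibration line, exponentiates
#' to cm/s, classifies, and (optionally) propagates input uncertainties
#' through the linear map.
#'
#' @param model An `lf_calibration`.
#' @param log_peff_pmf Computed log10 permeability value(s).
#' @param se Optional standard error(s) of `log_peff_pmf`, propagated as
#'   `slope * se`.
#' @param compound Optional compound label(s).
#' @return Tibble with columns `compound`, `log_peff_pmf`,
#'   `log_peff_pampa`, `se_log_peff_pampa`, `peff`, `class`.
#' @export
apply_calibration <- function(model, log_peff_pmf, se = NULL,
                              compound = NULL) {
  stopifnot(inherits(model, "lf_calibration"))
  lp <- model$intercept + model$slope * log_peff_pmf
  peff <- model$p0 * 10^lp
  tibble(
    compound = compound %||% sprintf("cmpd_%d", seq_along(log_peff_pmf)),
    log_peff_pmf = log_peff_pmf,
    log_peff_pampa = lp,
    se_log_peff_pampa = if (is.null(se)) NA_real_ else abs(model$slope) * se,
    peff = peff,
    class = classify_permeability(peff))
}
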