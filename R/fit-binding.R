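#' Fit a four-parameter logistic dose-response curve (IC50)
#'
#' Fits `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)` by nonlinear
#' least squares on log10(concentration), with top, bottom and hill free.
#' Initialization comes from the data quartiles. Standard errors are from
#' the Jacobian-based covariance at the optimum; the IC50 standard error is
#' delta-method transformed from the log10 scale.
#'
#' An IC50 outside the tested concentration range is flagged `extrapolated`;
#' fits with IC50 above `inactive_above` (default 1000 uM) or extrapolated
#' upward are classified inactive.
#'
#' @param series A `titration_series` (or data frame with `x` in uM and `y`
#'   as normalized viability fractions).
#' @param inactive_above Classification cutoff in uM.
#' @return An `lf_ic50_fit` list: `ic50`, `hill`, `top`, `bottom`,
#'   `se_ic50`, `extrapolated`, `inactive`, `rss`, `fit` (the nls object),
#'   `data`.
#' @export
fit_ic50 <- function(series, inactive_above = 1000) {
  s <- as_titration(series)
  if (length(unique(s$x)) < 5)
    abort("need >= 5 distinct concentrations")
  if (any(s$x <= 0)) abort("concentrations must be positive")
  m <- series_means(s)
  rng <- diff(range(m$y))
  if (rng < 1e-9 * max(abs(m$y), 1))
    abort("no dose dependence: response is constant")
  top0 <- max(m$y); bot0 <- min(m$y)
  # x where the mean response crosses halfway
  half <- (top0 + bot0) / 2
  ic0 <- m$x[which.min(abs(m$y - half))]
  df <- tibble(lx = log10(s$x), y = s$y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((lx - lic) * hill)),
      data = df,
      start = list(top = top0, bottom = bot0, lic = log10(ic0), hill = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      abort(paste0("IC50 fit did not converge: ", conditionMessage(e))))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  ic50 <- 10^cf[["lic"]]
  extrapolated <- ic50 < min(s$x) || ic50 > max(s$x)
  structure(list(
    ic50 = ic50, hill = cf[["hill"]], top = cf[["top"]],
    bottom = cf[["bottom"]],
    se_ic50 = log(10) * ic50 * unname(se["lic"]),
    extrapolated = extrapolated,
    inactive = ic50 > inactive_above || (extrapolated && ic50 > max(s$x)),
    rss = sum(stats::resid(fit)^2), fit = fit, data = s),
    class = "lf_ic50_fit")
}

#' @export
print.lf_ic50_fit <- function(x, ...) {
  cat(sprintf("<lf_ic50_fit> IC50 = %.4g uM (se %.2g), hill %.2f%s%s\n",
              x$ic50, x$se_ic50, x$hill,
              if (x$extrapolated) ", extrapolated" else "",
              if (x$inactive) ", inactive" else ""))
  invisible(x)
}

#' Exact 1:1 binding isotherm (bound fraction)
#'
#' The quadratic solution for the fraction of target bound at total ligand
#' `L`, total target `Tt` and dissociation constant `K` (all in the same
#' concentration unit):
#' `fb = ((L + Tt + K) - sqrt((L + Tt + K)^2 - 4 L Tt)) / (2 Tt)`.
#' Reduces to the hyperbola `L / (L + K)` when `Tt << K`.
#'
#' @param L Total ligand concentration(s).
#' @param Tt Total target concentration.
#' @param K Dissociation constant.
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
bound_fraction <- function(L, Tt, K) {
  s <- L + Tt + K
  disc <- pmax(s^2 - 4 * L * Tt, 0)
  (s - sqrt(disc)) / (2 * Tt)
}

#' Fit an MST titration to the exact 1:1 binding model
#'
#' Fits `Fnorm = f_free + (f_bound - f_free) * fb(L; Tt, K)` with the exact
#' quadratic isotherm [bound_fraction()], K on a log10 scale. The target
#' (labeled protein) concentration is fixed and known.
#'
#' @param series `titration_series` with `x` = total ligand concentration in
#'   uM and `y` = Fnorm (or any single response trace).
#' @param target_conc_nM Labeled target concentration in nM (e.g. 100).
#' @return An `lf_kd_fit` list: `kd_app` (uM), `f_free`, `f_bound`,
#'   `se_kd` (uM), `target_conc_nM`, `flagged` (TRUE when the optimizer hit
#'   its K bounds or did not converge cleanly), `rss`, `fit`, `data`.
#' @export
fit_mst_kd <- function(series, target_conc_nM = 100) {
  if (target_conc_nM <= 0) abort("`target_conc_nM` must be positive")
  s <- as_titration(series)
  if (any(s$x <= 0)) abort("ligand concentrations must be positive")
  span <- log10(max(s$x) / min(s$x))
  if (span < 3)
    warn("ligand series spans < 3 orders of magnitude; K_D may be poorly determined")
  Tt <- target_conc_nM / 1000 # uM
  m <- series_means(s)
  amp <- m$y[which.max(m$x)] - m$y[which.min(m$x)]
  half <- m$y[which.min(m$x)] + amp / 2
  k0 <- m$x[which.min(abs(m$y - half))]
  lo <- log10(min(s$x)) - 3; hi <- log10(max(s$x)) + 3
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ f_free + (f_bound - f_free) * bound_fraction(x, Tt, 10^lk),
      data = tibble(x = s$x, y = s$y),
      start = list(f_free = m$y[which.min(m$x)],
                   f_bound = m$y[which.max(m$x)], lk = log10(k0)),
      lower = c(-Inf, -Inf, lo), upper = c(Inf, Inf, hi),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      abort(paste0("1:1 isotherm fit did not converge: ",
                   conditionMessage(e))))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  kd <- 10^cf[["lk"]]
  flagged <- cf[["lk"]] <= lo + 1e-6 || cf[["lk"]] >= hi - 1e-6
  if (flagged) warn("kd_app hit its search bounds; fit flagged")
  structure(list(
    kd_app = kd, f_free = cf[["f_free"]], f_bound = cf[["f_bound"]],
    se_kd = log(10) * kd * unname(se["lk"]),
    target_conc_nM = target_conc_nM, flagged = flagged,
    rss = sum(stats::resid(fit)^2), fit = fit, data = s),
    class = "lf_kd_fit")
}

#' @export
print.lf_kd_fit <- function(x, ...) {
  cat(sprintf("<lf_kd_fit> K_D,app = %.4g uM (se %.2g), target %.0f nM%s\n",
              x$kd_app, x$se_kd, x$target_conc_nM,
              if (x$flagged) ", flagged" else ""))
  invisible(x)
}

#' Fit a Henderson-Hasselbalch pH titration (pKa)
#'
#' Fits the chemical shift of a reporter proton against pH:
#' `delta(pH) = delta_base + (delta_acid - delta_base) / (1 + 10^(pH - pKa))`.
#' The estimate is invariant to swapping the acid/base limit initialization.
#'
#' @param series `titration_series` with `x` = pH and `y` = chemical shift
#'   (ppm).
#' @return An `lf_pka_fit` list: `pka`, `delta_acid`, `delta_base`,
#'   `se_pka`, `rss`, `fit`, `data`.
#' @export
fit_pka <- function(series) {
  s <- as_titration(series)
  if (length(unique(s$x)) < 8) abort("need >= 8 pH points")
  m <- series_means(s)
  rng <- diff(range(m$y))
  if (rng < 1e-6)
    abort("no titration transition: shifts are flat across pH")
  da0 <- m$y[which.min(m$x)]
  db0 <- m$y[which.max(m$x)]
  half <- (da0 + db0) / 2
  pka0 <- m$x[which.min(abs(m$y - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ db + (da - db) / (1 + 10^(x - pka)),
      data = tibble(x = s$x, y = s$y),
      start = list(da = da0, db = db0, pka = pka0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      abort(paste0("pKa fit did not converge: ", conditionMessage(e))))
  cf <- stats::coef(fit)
  if (cf[["pka"]] < min(s$x) || cf[["pka"]] > max(s$x))
    warn("fitted pKa lies outside the measured pH range")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(
    pka = cf[["pka"]], delta_acid = cf[["da"]], delta_base = cf[["db"]],
    se_pka = unname(se["pka"]),
    rss = sum(stats::resid(fit)^2), fit = fit, data = s),
    class = "lf_pka_fit")
}

#' @export
print.lf_pka_fit <- function(x, ...) {
  cat(sprintf(
    "<lf_pka_fit> pKa = %.3f (se %.2g); delta acid/base %.3f/%.3f ppm\n",
    x$pka, x$se_pka, x$delta_acid, x$delta_base))
  invisible(x)
}

#' Protonated fraction at a given pH
#'
#' `1 / (1 + 10^(pH - pKa))` for a basic site: at pH = pKa the species is
#' half protonated; well below the pKa it is fully protonated.
#'
#' @param pka Site pKa.
#' @param ph pH value(s).
#' @return Protonated fraction(s) in `(0, 1)`.
#' @export
protonated_fraction <- function(pka, ph) {
  1 / (1 + 10^(ph - pka))
}
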