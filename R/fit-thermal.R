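#' Melting temperature from nanoDSF channel data
#'
#' Forms the F350/F330 fluorescence intensity ratio pointwise, smooths it
#' with a Savitzky-Golay filter (default window 11 points, polynomial order
#' 3), and locates the melting transition at the extremum of the first
#' derivative of the smoothed ratio. The transition may raise or lower the
#' ratio; the extremum sign is auto-detected. The result is invariant to
#' rescaling both channels by a common factor.
#'
#' With `refine = "model"` (the default, matching instrument-software
#' practice) the derivative extremum seeds a two-state fit - a logistic
#' transition with linear pre-baseline - and the reported Tm is the fitted
#' midpoint, which equals the derivative extremum of the fitted curve. When
#' both channels are supplied the fit is joint over log(F330) and log(F350)
#' (relative residuals, since fluorescence noise is multiplicative), which
#' uses the full two-channel information; with only a ratio column the fit
#' is on the ratio. `refine = "none"` reports the smoothed-derivative
#' extremum itself (quadratic peak interpolation).
#'
#' A transition is only reported if the smoothed ratio amplitude clearly
#' exceeds the residual noise and the derivative extremum lies strictly
#' inside the scanned range; otherwise the scan is rejected with
#' "no transition detected".
#'
#' @param melt Data frame with columns `temperature` (degC, monotone ramp),
#'   `f350` and `f330`; or columns `temperature` and `ratio`.
#' @param window,order Savitzky-Golay window length (odd) and polynomial
#'   order.
#' @param refine `"model"` (default) or `"none"`.
#' @return An `lf_tm_fit` list: `tm` (degC), `tm_derivative` (the raw
#'   derivative-extremum estimate), `ratio_curve` (tibble
#'   temperature/ratio/smoothed), `derivative_curve` (tibble
#'   temperature/dratio), `direction` (+1 ratio rises, -1 falls).
#' @export
compute_tm <- function(melt, window = 11, order = 3,
                       refine = c("model", "none")) {
  refine <- match.arg(refine)
  df <- as_tibble(melt)
  if (!"temperature" %in% names(df))
    abort("`melt` needs a `temperature` column")
  has_channels <- all(c("f350", "f330") %in% names(df))
  ratio <- if (has_channels) {
    if (any(df$f330 <= 0)) abort("F330 must be positive")
    df$f350 / df$f330
  } else {
    if (!"ratio" %in% names(df))
      abort("`melt` needs `f350` and `f330` (or `ratio`) columns")
    df$ratio
  }
  temp <- df$temperature
  if (length(temp) < 50) abort("need >= 50 temperature points")
  if (any(diff(temp) <= 0))
    abort("temperature ramp must be strictly increasing")
  sm <- signal::sgolayfilt(ratio, p = order, n = window)
  dr <- c(NA, (sm[-(1:2)] - sm[1:(length(sm) - 2)]) /
            (temp[-(1:2)] - temp[1:(length(temp) - 2)]), NA)
  h <- window %/% 2
  interior <- seq(h + 1, length(temp) - h) # filter edges are unreliable
  i_ext <- interior[which.max(abs(dr[interior]))]
  direction <- sign(dr[i_ext])

  noise_sd <- stats::sd(ratio - sm)
  amp <- diff(range(sm[interior]))
  if (amp <= max(10 * noise_sd, 1e-8 * max(abs(ratio), 1)) ||
      i_ext <= min(interior) || i_ext >= max(interior))
    abort("no transition detected")

  ii <- max(min(interior), i_ext - 3):min(max(interior), i_ext + 3)
  tm_deriv <- quad_peak(temp[ii], direction * dr[ii])
  if (!is.finite(tm_deriv) || abs(tm_deriv - temp[i_ext]) >
      2 * (temp[min(i_ext + 1, length(temp))] - temp[max(i_ext - 1, 1)]))
    tm_deriv <- temp[i_ext]

  tm <- tm_deriv
  if (refine == "model") {
    tm_fit <- fit_two_state(df, temp, ratio, sm, tm_deriv, direction,
                            has_channels)
    if (is.finite(tm_fit) && abs(tm_fit - tm_deriv) < 5) tm <- tm_fit
  }
  structure(list(
    tm = tm, tm_derivative = tm_deriv, direction = direction,
    ratio_curve = tibble(temperature = temp, ratio = ratio, smoothed = sm),
    derivative_curve = tibble(temperature = temp, dratio = dr)),
    class = "lf_tm_fit")
}

# two-state logistic + linear baseline; joint log-channel fit when both
# fluorescence channels are available
fit_two_state <- function(df, temp, ratio, sm, tm0, direction,
                          has_channels) {
  T0 <- min(temp)
  amp0 <- direction * diff(range(sm))
  fit <- if (has_channels) {
    y <- c(log(df$f330), log(df$f350))
    tt <- c(temp, temp)
    is350 <- rep(c(0, 1), each = length(temp))
    tryCatch(minpack.lm::nlsLM(
      y ~ lb0 + log(1 + b1 * (tt - T0)) +
        is350 * log(r0 + s * (tt - T0) +
                      amp / (1 + exp(-(tt - tm) / w))),
      data = tibble(y = y, tt = tt, is350 = is350),
      start = list(lb0 = log(df$f330[1]), b1 = 0, r0 = sm[1], s = 0,
                   amp = amp0, tm = tm0, w = 2),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  } else {
    tryCatch(minpack.lm::nlsLM(
      ratio ~ r0 + s * (temp - T0) + amp / (1 + exp(-(temp - tm) / w)),
      data = tibble(ratio = ratio, temp = temp),
      start = list(r0 = sm[1], s = 0, amp = amp0, tm = tm0, w = 2),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  }
  if (is.null(fit)) return(NA_real_)
  cf <- stats::coef(fit)
  if (cf[["w"]] <= 0) return(NA_real_)
  cf[["tm"]]
}

# vertex of the least-squares parabola through (x, y)
quad_peak <- function(x, y) {
  b <- stats::coef(stats::lm(y ~ x + I(x^2)))
  if (!is.finite(b[3]) || abs(b[3]) < 1e-15)
    return(x[(length(x) + 1) %/% 2])
  unname(-b[2] / (2 * b[3]))
}

#' @export
print.lf_tm_fit <- function(x, ...) {
  cat(sprintf("<lf_tm_fit> Tm = %.2f degC (ratio %s)\n", x$tm,
              if (x$direction > 0) "rising" else "falling"))
  invisible(x)
}

#' Thermal shift between apo and complex melting fits
#'
#' Signed shift `complex Tm - apo Tm` in degC; negative values indicate
#' destabilization of the protein by the bound compound.
#'
#' @param apo,complex `lf_tm_fit` objects from [compute_tm()].
#' @return Signed Delta-Tm in degC.
#' @export
delta_tm <- function(apo, complex) {
  stopifnot(inherits(apo, "lf_tm_fit"), inherits(complex, "lf_tm_fit"))
  complex$tm - apo$tm
}

#' Saturation-transfer-difference epitope mapping
#'
#' Computes the per-proton STD effect and expresses it relative to a
#' reference proton (100%). The effect is `i_sat / i_0` (on-resonance over
#' off-resonance intensity) when `direction = "ratio"`; the conventional
#' saturation-transfer magnitude `(i_0 - i_sat) / i_0` is available via
#' `direction = "attenuation"`. With `reference = "max"` the largest effect
#' is set to 100%; naming a proton instead can yield relative values above
#' 100%.
#'
#' @param records Data frame with columns `label`, `i_sat`, `i_0`.
#' @param reference `"max"` or a proton label present in `records`.
#' @param direction `"ratio"` (default) or `"attenuation"`.
#' @return Tibble with columns `label`, `i_sat`, `i_0`, `effect`,
#'   `relative_pct`.
#' @export
std_epitope_map <- function(records, reference = "max",
                            direction = c("ratio", "attenuation")) {
  direction <- match.arg(direction)
  df <- as_tibble(records)
  stopifnot(all(c("label", "i_sat", "i_0") %in% names(df)))
  bad <- which(df$i_0 <= 0)
  if (length(bad) > 0)
    abort(paste0("i_0 must be positive (records: ",
                 paste(df$label[bad], collapse = ", "), ")"))
  eff <- unname(if (direction == "ratio") df$i_sat / df$i_0
                else (df$i_0 - df$i_sat) / df$i_0)
  ref_eff <- if (identical(reference, "max")) max(eff) else {
    sel <- df$label == reference
    if (!any(sel)) abort(paste0("reference proton not found: ", reference))
    eff[sel][1]
  }
  if (ref_eff == 0) abort("reference effect is zero")
  dplyr::mutate(df, effect = eff, relative_pct = 100 * eff / ref_eff)
}
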