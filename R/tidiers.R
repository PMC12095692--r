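#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a dose-response fit
#' @param x An `lf_ic50_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.lf_ic50_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("ic50", "hill", "top", "bottom"),
         estimate = c(x$ic50, x$hill, x$top, x$bottom),
         std.error = c(x$se_ic50, s["hill", 2], s["top", 2],
                       s["bottom", 2]))
}

#' @rdname tidy.lf_ic50_fit
#' @export
glance.lf_ic50_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, rss = x$rss,
         extrapolated = x$extrapolated, inactive = x$inactive,
         nobs = nrow(x$data))
}

#' Tidy an MST 1:1 binding fit
#' @param x An `lf_kd_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.lf_kd_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("kd_app", "f_free", "f_bound"),
         estimate = c(x$kd_app, x$f_free, x$f_bound),
         std.error = c(x$se_kd, s["f_free", 2], s["f_bound", 2]))
}

#' @rdname tidy.lf_kd_fit
#' @export
glance.lf_kd_fit <- function(x, ...) {
  tibble(kd_app = x$kd_app, rss = x$rss, flagged = x$flagged,
         target_conc_nM = x$target_conc_nM, nobs = nrow(x$data))
}

#' Tidy a pKa fit
#' @param x An `lf_pka_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.lf_pka_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("pka", "delta_acid", "delta_base"),
         estimate = c(x$pka, x$delta_acid, x$delta_base),
         std.error = c(x$se_pka, s["da", 2], s["db", 2]))
}

#' @rdname tidy.lf_pka_fit
#' @export
glance.lf_pka_fit <- function(x, ...) {
  tibble(pka = x$pka, rss = x$rss, nobs = nrow(x$data))
}

#' Tidy a melting fit
#' @param x An `lf_tm_fit`.
#' @param ... Unused.
#' @return One-row tibble with `tm` and ratio direction.
#' @export
tidy.lf_tm_fit <- function(x, ...) {
  tibble(term = "tm", estimate = x$tm)
}

#' @rdname tidy.lf_tm_fit
#' @export
glance.lf_tm_fit <- function(x, ...) {
  tibble(tm = x$tm, direction = x$direction,
         n_points = nrow(x$ratio_curve))
}

#' Tidy a PAMPA calibration model
#' @param x An `lf_calibration`.
#' @param ... Unused.
#' @return `term`/`estimate`/`std.error` rows for slope and intercept.
#' @export
tidy.lf_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(s[, 2]))
}

#' @rdname tidy.lf_calibration
#' @export
glance.lf_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, n_ref = x$n_ref,
         residual_sd = x$residual_sd,
         r.squared = summary(x$fit)$r.squared)
}
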