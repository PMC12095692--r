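#' @import ggplot2
NULL

#' Plot a dose-response fit
#' @param object An `lf_ic50_fit`.
#' @param ... Unused.
#' @return A ggplot: replicate points and the fitted 4PL curve on log10
#'   concentration.
#' @export
autoplot.lf_ic50_fit <- function(object, ...) {
  d <- as_tibble(object$data)
  grid <- tibble(x = 10^seq(log10(min(d$x)), log10(max(d$x)),
                            length.out = 200))
  grid$y <- object$bottom + (object$top - object$bottom) /
    (1 + (grid$x / object$ic50)^object$hill)
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, colour = "firebrick") +
    geom_vline(xintercept = object$ic50, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "concentration (uM)", y = "normalized viability",
         title = sprintf("IC50 = %.3g uM", object$ic50))
}

#' Plot an MST binding fit
#' @param object An `lf_kd_fit`.
#' @param ... Unused.
#' @return A ggplot of Fnorm vs ligand concentration with the fitted 1:1
#'   isotherm.
#' @export
autoplot.lf_kd_fit <- function(object, ...) {
  d <- as_tibble(object$data)
  Tt <- object$target_conc_nM / 1000
  grid <- tibble(x = 10^seq(log10(min(d$x)), log10(max(d$x)),
                            length.out = 200))
  grid$y <- object$f_free + (object$f_bound - object$f_free) *
    bound_fraction(grid$x, Tt, object$kd_app)
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, colour = "steelblue") +
    geom_vline(xintercept = object$kd_app, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "ligand (uM)", y = "Fnorm",
         title = sprintf("K_D,app = %.3g uM", object$kd_app))
}

#' Plot a melting fit (ratio and first derivative)
#' @param object An `lf_tm_fit`.
#' @param ... Unused.
#' @return A ggplot of the F350/F330 ratio with the derivative overlaid
#'   (rescaled) and the Tm marked.
#' @export
autoplot.lf_tm_fit <- function(object, ...) {
  rc <- object$ratio_curve
  dc <- dplyr::filter(object$derivative_curve, is.finite(.data$dratio))
  scale <- diff(range(rc$ratio)) /
    max(diff(range(dc$dratio)), .Machine$double.eps)
  dc$scaled <- min(rc$ratio) + (dc$dratio - min(dc$dratio)) * scale * 0.5
  ggplot(rc, aes(x = .data$temperature)) +
    geom_point(aes(y = .data$ratio), alpha = 0.4, size = 0.7) +
    geom_line(aes(y = .data$smoothed), colour = "firebrick") +
    geom_line(data = dc, aes(y = .data$scaled), colour = "steelblue",
              linetype = "dotted") +
    geom_vline(xintercept = object$tm, linetype = "dashed") +
    labs(x = "temperature (degC)", y = "F350/F330",
         title = sprintf("Tm = %.2f degC", object$tm))
}

#' Plot a pH titration fit
#' @param object An `lf_pka_fit`.
#' @param ... Unused.
#' @return A ggplot of chemical shift vs pH with the fitted
#'   Henderson-Hasselbalch curve.
#' @export
autoplot.lf_pka_fit <- function(object, ...) {
  d <- as_tibble(object$data)
  grid <- tibble(x = seq(min(d$x), max(d$x), length.out = 200))
  grid$y <- object$delta_base +
    (object$delta_acid - object$delta_base) /
    (1 + 10^(grid$x - object$pka))
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, colour = "firebrick") +
    geom_vline(xintercept = object$pka, linetype = "dashed") +
    labs(x = "pH", y = "chemical shift (ppm)",
         title = sprintf("pKa = %.2f", object$pka))
}

#' Plot a screen report
#' @param object An `lf_screen`.
#' @param ... Unused.
#' @return A ggplot of ranked Tanimoto-Combo scores split into shape and
#'   color components.
#' @export
autoplot.lf_screen <- function(object, ...) {
  d <- as_tibble(object) |>
    tidyr::pivot_longer(c("shape_tanimoto", "color_tanimoto"),
                        names_to = "component", values_to = "score")
  ggplot(d, aes(x = .data$rank, y = .data$score,
                fill = .data$component)) +
    geom_col() +
    labs(x = "rank", y = "Tanimoto-Combo", fill = NULL)
}

#' Plot an epitope occupancy report
#' @param object An `lf_epitope_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-epitope occupancies.
#' @export
autoplot.lf_epitope_report <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(x = factor(.data$epitope), y = .data$occupancy_pct)) +
    geom_col(fill = "steelblue") +
    labs(x = "epitope (occupancy rank)", y = "occupancy (% of frames)")
}

#' Plot a PMF profile
#' @param object An `lf_pmf`.
#' @param ... Unused.
#' @return A ggplot of the free energy along the membrane normal.
#' @export
autoplot.lf_pmf <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$z, y = .data$dG)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = "z, distance from bilayer center (Angstrom)",
         y = "free energy (kcal/mol)")
}

#' Plot a PAMPA calibration
#' @param object An `lf_calibration`.
#' @param ... Unused.
#' @return A ggplot of the reference pairs and the fitted line.
#' @export
autoplot.lf_calibration <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$log_peff_pmf,
                           y = .data$log_peff_pampa)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "firebrick") +
    labs(x = "log10 Peff/PMF / P0", y = "log10 Peff/PAMPA / P0")
}
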