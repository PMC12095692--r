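#' Titration series container
#'
#' Common tabular container for all titration-style readouts: dose-response
#' (concentration vs normalized viability), MST (concentration vs Fnorm),
#' melting (temperature vs fluorescence ratio), and pH titrations (pH vs
#' chemical shift). Stored long: one row per (x, replicate) observation.
#'
#' @param x Abscissa values (concentration in uM, temperature in degC, or
#'   pH), one per design point.
#' @param y Response: a vector (one replicate) or matrix/data frame with one
#'   column per replicate, rows matching `x`.
#' @param assay Assay kind label (e.g. "dose_response", "mst", "melting",
#'   "ph_titration").
#' @param units Named list or character description of x/y units.
#' @return A `titration_series` tibble with columns `x`, `replicate`, `y`.
#' @export
titration_series <- function(x, y, assay = "generic", units = NULL) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) abort("`x` must be finite")
  y <- as.matrix(y)
  if (nrow(y) == 1 && length(x) > 1) y <- t(y)
  if (nrow(y) != length(x))
    abort("`y` must have one row per value of `x`")
  if (any(!is.finite(y))) abort("`y` must be finite")
  ord <- order(x)
  if (any(duplicated(x)))
    abort("`x` values must be distinct")
  out <- tidyr::expand_grid(i = ord, replicate = seq_len(ncol(y))) |>
    dplyr::mutate(x = x[.data$i],
                  y = y[cbind(.data$i, .data$replicate)]) |>
    dplyr::select("x", "replicate", "y") |>
    dplyr::arrange(.data$x, .data$replicate)
  attr(out, "assay") <- assay
  attr(out, "units") <- units
  class(out) <- c("titration_series", class(out))
  out
}

as_titration <- function(series) {
  if (inherits(series, "titration_series")) return(series)
  df <- as_tibble(series)
  if (all(c("x", "y") %in% names(df))) {
    if (!"replicate" %in% names(df)) df$replicate <- 1L
    class(df) <- c("titration_series", class(df))
    return(df)
  }
  # wide CSV convention: x, y_rep1..y_repN
  ycols <- grep("^y", names(df), value = TRUE)
  if (length(ycols) == 0 || !"x" %in% names(df))
    abort("expected columns `x` and `y`/`y_rep*`")
  titration_series(df$x, as.matrix(df[, ycols]))
}

#' Read a titration CSV (columns x, y_rep1..y_repN)
#'
#' @param path CSV path.
#' @param assay,units Passed to [titration_series()].
#' @return A `titration_series`.
#' @export
read_titration_csv <- function(path, assay = "generic", units = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ycols <- grep("^y", names(df), value = TRUE)
  titration_series(df$x, as.matrix(df[, ycols]), assay = assay,
                   units = units)
}

#' Write a titration series to CSV (columns x, y_rep1..y_repN)
#'
#' @param series A `titration_series` or long data frame with x/replicate/y.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  s <- as_titration(series)
  wide <- tidyr::pivot_wider(s, names_from = "replicate", values_from = "y",
                             names_prefix = "y_rep")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Normalize raw responses to vehicle controls
#'
#' Divides every raw response by the mean of the vehicle (DMSO) control
#' responses, so the vehicle level maps to 1.0. This is the normalization
#' applied to viability readouts before dose-response fitting.
#'
#' @param raw Data frame/tibble with column `x` and response columns
#'   (`y`, or `y_rep1..y_repN`), or a `titration_series`.
#' @param vehicle Numeric vector of vehicle control responses; its mean must
#'   be positive.
#' @return A `titration_series` of normalized responses.
#' @export
normalize_to_vehicle <- function(raw, vehicle) {
  vm <- mean(vehicle)
  if (!is.finite(vm) || vm <= 0)
    abort("vehicle mean must be positive")
  s <- as_titration(raw)
  s$y <- s$y / vm
  attr(s, "assay") <- "dose_response"
  s
}

# shared helper: per-x mean response
series_means <- function(s) {
  dplyr::summarise(dplyr::group_by(as_tibble(s), .data$x),
                   y = mean(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$x)
}
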