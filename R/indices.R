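#' NDVI from a reflectance scene
#'
#' Per-pixel Normalized Difference Vegetation Index,
#' \deqn{NDVI = (NIR - RED) / (NIR + RED),}
#' clamped to \eqn{[-1, 1]}. Because the valid digital-number range admits
#' slightly negative reflectances (down to -100), the raw quotient can fall
#' marginally outside \eqn{[-1, 1]}; such values are clamped. Pixels that are
#' invalid in the scene, or where `NIR + RED == 0`, are masked.
#'
#' @param scene A [reflectance_scene()], normally passed through
#'   [validate_reflectance()] first.
#' @param cadence Cadence of the period attached to the result; daily NDVI is
#'   the default.
#' @return An [index_grid()] of kind `"NDVI"` whose period is the scene
#'   date's slot.
#' @examples
#' s <- reflectance_scene(matrix(2000L, 1, 1), matrix(6000L, 1, 1), "2021-06-07")
#' ndvi(s)$values  # 0.5
#' @export
ndvi <- function(scene, cadence = "daily") {
  stopifnot(inherits(scene, "reflectance_scene"))
  red <- scene$red
  nir <- scene$nir
  denom <- as.numeric(nir) + as.numeric(red)
  ok <- scene$valid & denom != 0
  vals <- matrix(NA_real_, nrow(red), ncol(red))
  vals[ok] <- clamp((as.numeric(nir[ok]) - as.numeric(red[ok])) /
                      denom[ok], -1, 1)
  index_grid(vals, "NDVI", period_of(scene$date, cadence), scene$geometry)
}

check_ndvi_inputs <- function(current, ..., what = "index inputs") {
  refs <- list(...)
  stopifnot(inherits(current, "index_grid"), current$kind == "NDVI")
  for (r in refs) {
    stopifnot(inherits(r, "index_grid"), r$kind == "NDVI")
    stop_if_geometry_mismatch(current$geometry, r$geometry, what)
  }
  invisible(TRUE)
}

#' Vegetation Condition Index
#'
#' Positions the current NDVI inside the historical per-pixel min-max
#' envelope for the same period of year:
#' \deqn{VCI = (NDVI - NDVI_{min}) / (NDVI_{max} - NDVI_{min}),}
#' clamped to \eqn{[0, 1]} (in near-real-time use the current composite can
#' exceed the archived extremes). Pixels are masked where any input is
#' masked or where the envelope is degenerate (`max == min`), since no
#' anomaly is defined there.
#'
#' @param current Current-period NDVI composite ([index_grid()]).
#' @param hist_min,hist_max Per-pixel historical minimum and maximum NDVI
#'   for the same period of year.
#' @return An [index_grid()] of kind `"VCI"` with the current grid's period.
#' @export
vci <- function(current, hist_min, hist_max) {
  check_ndvi_inputs(current, hist_min, hist_max, what = "VCI inputs")
  rng <- hist_max$values - hist_min$values
  ok <- !is.na(current$values) & !is.na(rng) & rng != 0
  vals <- matrix(NA_real_, nrow(current$values), ncol(current$values))
  vals[ok] <- clamp((current$values[ok] - hist_min$values[ok]) / rng[ok],
                    0, 1)
  index_grid(vals, "VCI", current$period, current$geometry)
}

# shared body of the three ratio indices: (cur - ref) / ref, clamped +/-1.25
ratio_index <- function(current, reference, kind) {
  ok <- !is.na(current$values) & !is.na(reference$values) &
    reference$values != 0
  vals <- matrix(NA_real_, nrow(current$values), ncol(current$values))
  vals[ok] <- clamp((current$values[ok] - reference$values[ok]) /
                      reference$values[ok], -1.25, 1.25)
  index_grid(vals, kind, current$period, current$geometry)
}

#' Mean-referenced Vegetation Condition Index
#'
#' Relative deviation of the current NDVI from the multi-year mean NDVI for
#' the same period of year:
#' \deqn{MVCI = (NDVI - NDVI_{mean}) / NDVI_{mean},}
#' saturated at an absolute value of 1.25 (125\%), mirroring the product
#' encoding. Masked where either input is masked or the reference is zero.
#'
#' @param current Current-period NDVI composite.
#' @param hist_mean Multi-year mean NDVI reference field.
#' @return An [index_grid()] of kind `"MVCI"`.
#' @export
mvci <- function(current, hist_mean) {
  check_ndvi_inputs(current, hist_mean, what = "MVCI inputs")
  ratio_index(current, hist_mean, "MVCI")
}

#' Ratio-to-Median Vegetation Condition Index
#'
#' As [mvci()] but referenced to the multi-year median NDVI.
#'
#' @param current Current-period NDVI composite.
#' @param hist_median Multi-year median NDVI reference field.
#' @return An [index_grid()] of kind `"RMVCI"`.
#' @export
rmvci <- function(current, hist_median) {
  check_ndvi_inputs(current, hist_median, what = "RMVCI inputs")
  ratio_index(current, hist_median, "RMVCI")
}

#' Ratio-to-Previous-Year Vegetation Condition Index
#'
#' Relative deviation of the current NDVI from the previous year's NDVI for
#' the same period of year:
#' \deqn{RVCI = (NDVI_i - NDVI_{i-1}) / NDVI_{i-1},}
#' saturated at \eqn{\pm 1.25}. When both grids carry periods, they must be
#' for the same slot number in consecutive years (a week-52 reference is
#' accepted for week 53 of the current year, the alignment used when the
#' previous year has only 52 weeks).
#'
#' @param current Current-year NDVI composite.
#' @param previous_year Previous year's NDVI composite for the same slot.
#' @return An [index_grid()] of kind `"RVCI"`.
#' @export
rvci <- function(current, previous_year) {
  check_ndvi_inputs(current, previous_year, what = "RVCI inputs")
  pc <- current$period
  pp <- previous_year$period
  if (!is.null(pc) && !is.null(pp)) {
    if (pp$year != pc$year - 1L) {
      stop("previous_year grid must be from the preceding year",
           call. = FALSE)
    }
    week_ok <- pp$week == pc$week || (pc$week == 53L && pp$week == 52L)
    if (!week_ok) {
      stop("previous_year grid must cover the same period of year",
           call. = FALSE)
    }
  }
  ratio_index(current, previous_year, "RVCI")
}
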