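#' Synthetic true-NDVI series
#'
#' Generates per-date "ground truth" NDVI fields that emulate what the
#' production chain sees over vegetated land: a seasonal sinusoid around a
#' base level (vegetated NDVI typically lies between 0.2 and 0.8), a fixed
#' west-east spatial gradient, a deterministic per-year offset emulating
#' interannual variability (wet vs. dry years — without it every year would
#' repeat and min/max/anomaly references would be degenerate), and white
#' pixel noise:
#' \deqn{NDVI(p, d) = base + year\_offset_y + amp \sin(2\pi (doy - phase)/365)
#'   + gradient(p) + \epsilon(p, d).}
#' Values are clamped to \eqn{[-1, 1]}. Output is deterministic given
#' `seed`; the generator does not disturb the caller's RNG state.
#'
#' @param n_rows,n_cols Grid shape (default 128, small enough that a
#'   multi-year weekly archive builds in seconds).
#' @param dates Vector of acquisition dates.
#' @param seed Integer seed controlling noise and any drawn year offsets.
#' @param base Baseline NDVI (default 0.45).
#' @param amplitude Seasonal amplitude (default 0.25, keeping the seasonal
#'   swing inside the 0.2..0.8 vegetated range).
#' @param phase_day Day of year at which the sinusoid crosses its base going
#'   up (default 80); the seasonal peak falls ~91 days later.
#' @param noise_sd Per-pixel, per-date Gaussian noise standard deviation
#'   (default 0.02).
#' @param gradient Half-range of a linear west-east NDVI gradient (default
#'   0.05): column 1 sits at `-gradient`, the last column at `+gradient`.
#' @param year_offsets Named numeric of per-year NDVI offsets. Default: the
#'   years in `dates` get offsets evenly spaced over \eqn{[-0.1, 0.1]} in
#'   year order (a single year gets 0).
#' @return A list of class `truth_series` with elements `dates`, `grids`
#'   (one matrix per date), `params` and `geometry`.
#' @export
make_truth_series <- function(n_rows = 128, n_cols = 128, dates, seed = 1L,
                              base = 0.45, amplitude = 0.25, phase_day = 80,
                              noise_sd = 0.02, gradient = 0.05,
                              year_offsets = NULL) {
  dates <- as.Date(dates)
  # offsets follow the product (ISO) year, so a week-1 date falling in late
  # December of the preceding calendar year stays with its product year
  years <- sort(unique(as.integer(format(dates, "%G"))))
  if (is.null(year_offsets)) {
    off <- if (length(years) == 1L) 0 else
      seq(-0.1, 0.1, length.out = length(years))
    year_offsets <- stats::setNames(off, years)
  }
  reach <- abs(base) + abs(amplitude) + abs(gradient) +
    max(abs(year_offsets))
  if (reach > 1) {
    stop("base + amplitude + gradient + year offsets exceed the NDVI range",
         call. = FALSE)
  }
  grad <- matrix(rep(seq(-gradient, gradient, length.out = n_cols),
                     each = n_rows), n_rows, n_cols)
  grids <- with_seed(seed, lapply(seq_along(dates), function(i) {
    d <- dates[i]
    doy <- as.integer(format(d, "%j"))
    yo <- year_offsets[[format(d, "%G")]]
    season <- amplitude * sin(2 * pi * (doy - phase_day) / 365)
    eps <- if (noise_sd > 0) {
      matrix(stats::rnorm(n_rows * n_cols, sd = noise_sd), n_rows, n_cols)
    } else 0
    clamp(base + yo + season + grad + eps, -1, 1)
  }))
  structure(list(dates = dates, grids = grids,
                 params = list(base = base, amplitude = amplitude,
                               phase_day = phase_day, noise_sd = noise_sd,
                               gradient = gradient,
                               year_offsets = year_offsets, seed = seed),
                 geometry = grid_geometry(n_rows, n_cols)),
            class = "truth_series")
}

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Reflectance scene realising a true NDVI field
#'
#' Inverts the NDVI quotient at a chosen total digital number: with
#' `nir + red = total_dn`,
#' `nir = round(total_dn (1 + v) / 2)` and `red = round(total_dn (1 - v) / 2)`,
#' so that `ndvi()` recovers `v` to within `1 / total_dn`.
#'
#' @param truth Numeric matrix of true NDVI values in \eqn{[-1, 1]}.
#' @param date Acquisition date for the scene.
#' @param total_dn Band sum in digital numbers, in (0, 32000\]; default 8000
#'   (mid-range reflectances).
#' @param geometry Optional [grid_geometry()].
#' @return A fully valid [reflectance_scene()].
#' @export
to_reflectance <- function(truth, date, total_dn = 8000, geometry = NULL) {
  if (inherits(truth, "index_grid")) truth <- truth$values
  stopifnot(is.matrix(truth), total_dn > 0, total_dn <= 32000)
  nir <- matrix(as.integer(round(total_dn * (1 + truth) / 2)),
                nrow(truth), ncol(truth))
  red <- matrix(as.integer(round(total_dn * (1 - truth) / 2)),
                nrow(truth), ncol(truth))
  reflectance_scene(red, nir, date, geometry = geometry)
}

#' Mask random cloud blobs into a scene
#'
#' Emulates cloud/fog/no-data contamination by invalidating contiguous
#' blobs. A smooth random field (a sum of Gaussian bumps) is thresholded at
#' the requested coverage quantile, so the masked fraction matches
#' `cover_fraction` almost exactly and the masked cells form connected
#' patches. Deterministic given `seed`.
#'
#' @param scene A [reflectance_scene()].
#' @param cover_fraction Fraction of pixels to mask, in \[0, 1\].
#' @param seed Integer seed.
#' @return The scene with its validity mask shrunk by the cloud mask.
#' @export
add_clouds <- function(scene, cover_fraction, seed = 1L) {
  stopifnot(inherits(scene, "reflectance_scene"),
            cover_fraction >= 0, cover_fraction <= 1)
  if (cover_fraction == 0) return(scene)
  if (cover_fraction >= 1) {
    scene$valid[] <- FALSE
    return(scene)
  }
  nr <- nrow(scene$red)
  nc <- ncol(scene$red)
  field <- with_seed(seed, {
    n_bumps <- max(4L, as.integer(round(nr * nc / 1024)))
    cy <- stats::runif(n_bumps, 1, nr)
    cx <- stats::runif(n_bumps, 1, nc)
    sg <- stats::runif(n_bumps, 0.05, 0.25) * max(nr, nc)
    f <- matrix(0, nr, nc)
    rows <- matrix(rep(seq_len(nr), nc), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (b in seq_len(n_bumps)) {
      f <- f + exp(-((rows - cy[b])^2 + (cols - cx[b])^2) / (2 * sg[b]^2))
    }
    f
  })
  thr <- stats::quantile(field, 1 - cover_fraction, names = FALSE)
  scene$valid <- scene$valid & (field <= thr)
  scene
}
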