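# Shared fixture builders. Everything is generated in code, seeded, and
# small enough to run in seconds.

# uniform scene with optional per-cell overrides
flat_scene <- function(red, nir, nr = 2, nc = 2, date = "2021-06-07",
                       valid = NULL, geometry = NULL) {
  reflectance_scene(matrix(as.integer(red), nr, nc),
                    matrix(as.integer(nir), nr, nc),
                    date, valid = valid, geometry = geometry)
}

# NDVI index grid from a value matrix, attached to a weekly period
ndvi_grid <- function(values, year = 2021, week = 23, cadence = "weekly",
                      geometry = NULL) {
  if (!is.matrix(values)) values <- matrix(values, 1, length(values))
  per <- if (cadence == "weekly") week_partition(year)[[week]]
  else biweekly_partition(year)[[week]]
  index_grid(values, "NDVI", per, geometry)
}

# daily NDVI grids for all days of a week, built from synthetic truth
synth_daily_week <- function(year, week, nr = 16, nc = 16, seed = 1,
                             noise_sd = 0.02, clouds = 0, total_dn = 8000,
                             year_offsets = NULL) {
  per <- week_partition(year)[[week]]
  dates <- seq(per$start_date, per$end_date, by = "day")
  ts <- make_truth_series(nr, nc, dates, seed = seed, noise_sd = noise_sd,
                         year_offsets = year_offsets)
  grids <- lapply(seq_along(dates), function(i) {
    sc <- to_reflectance(ts$grids[[i]], dates[i], total_dn = total_dn)
    if (clouds > 0) sc <- add_clouds(sc, clouds, seed = seed * 1000 + i)
    ndvi(validate_reflectance(sc))
  })
  list(grids = grids, truth = ts, period = per)
}

# multi-year weekly archive of NDVI composites (index grids with periods)
synth_weekly_archive <- function(years, weeks, nr = 16, nc = 16, seed = 1,
                                 noise_sd = 0.02, clouds = 0) {
  offs <- stats::setNames(
    if (length(years) == 1) 0 else seq(-0.1, 0.1, length.out = length(years)),
    years)
  composites <- list()
  for (y in years) {
    for (w in weeks) {
      dw <- synth_daily_week(y, w, nr, nc, seed = seed + y * 53 + w,
                             noise_sd = noise_sd, clouds = clouds,
                             year_offsets = offs)
      composites[[length(composites) + 1L]] <- mvc(dw$grids, dw$period)
    }
  }
  composites
}
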