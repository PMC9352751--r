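# vegindex

Near-real-time vegetation-condition monitoring from daily satellite
surface reflectance, for agricultural and drought analysts who need this
week's crop condition placed in its multi-year context rather than a bare
greenness map.

From co-registered RED/NIR digital-number rasters (16-bit signed, valid
range −100..16000, the MOD09GQ convention), the package produces the full
operational product chain:

* **daily NDVI** — per pixel, NDVI = (NIR − RED)/(NIR + RED);
* **weekly / biweekly maximum-value composites (MVC)** on the ISO-8601 week
  calendar — the per-pixel maximum of daily NDVI in the window, which
  suppresses cloud-, fog- and no-data-depressed values;
* **per-pixel multi-year climatologies** — min/max/mean/median NDVI per
  week-of-year slot, maintained incrementally and exactly;
* **anomaly indices** for the same period of year:
  * VCI = (NDVI − NDVI_min)/(NDVI_max − NDVI_min) — position inside the
    historical envelope, 0 = driest on record, 1 = greenest;
  * MVCI = (NDVI − NDVI_mean)/NDVI_mean and
    RMVCI = (NDVI − NDVI_median)/NDVI_median — relative deviation from the
    multi-year mean/median;
  * RVCI = (NDVI_i − NDVI_i−1)/NDVI_i−1 — relative deviation from last
    year's composite;
* **8-bit product encoding** — NDVI scales [−1, 1] → [0, 250] via
  v × 125 + 125; VCI scales [0, 1] via v × 250; the ratio indices saturate
  at |v| = 1.25 (125 %) and scale via v × 100 + 125; byte 255 is no-data
  and bytes 251–254 never occur — plus the operational layer-naming
  convention (e.g. `VCI-WEEKLY_2021_23_2021.06.07_2021.06.13`, with the
  legacy aliases `RNDVI`/`RMNDVI` for RVCI/RMVCI).

Products are written as single-band 8-bit GeoTIFFs (no-data tag 255)
through a built-in minimal GeoTIFF reader/writer, so outputs open directly
in GDAL-based GIS tools. A seed-reproducible synthetic scene generator
(seasonal NDVI curve, spatial gradient, interannual offsets, pixel noise,
contiguous cloud blobs) makes the whole chain testable end to end without
satellite downloads.

## Worked example

Build a five-year synthetic archive for ISO week 23 (June 7–13 in 2021),
run the pipeline, and read this week's drought picture:

```r
library(vegindex)
years <- 2017:2021
scenes <- list()
for (y in years) {
  per <- week_partition(y)[[23]]
  dates <- seq(per$start_date, per$end_date, by = "day")
  ts <- make_truth_series(64, 64, dates, seed = y)
  for (i in seq_along(dates)) {
    sc <- to_reflectance(ts$grids[[i]], dates[i])
    scenes[[length(scenes) + 1]] <- add_clouds(sc, 0.3, seed = y * 10 + i)
  }
}
res <- run_pipeline(list(scenes = scenes, out_dir = "products",
                         products = c("NDVI", "VCI", "MVCI", "RVCI")))
#> pipeline complete: 17 written, 0 skipped, 3 error(s)
```

17 products are written: the weekly NDVI composite for each of the five
years plus VCI/MVCI/RVCI for 2018–2021 where references exist; the three
"errors" are the anomaly products of 2017, the archive's first year, which
by construction has no historical reference — the pipeline reports them
per-product and carries on. Reading the 2021 VCI back:

```r
v <- decode_grid(read_product(
  file.path("products", "VCI-WEEKLY_2021_23_2021.06.07_2021.06.13.tif")))
v
#> <index_grid> VCI weekly 2021-23 (2021-06-07..2021-06-13), 64 x 64 px, 0 no-data
mean(v$values, na.rm = TRUE)
#> [1] 0.5714115
mean(v$values < 0.35, na.rm = TRUE)   # share of pixels under drought stress
#> [1] 0.3229980
```

A mean VCI of 0.57 says the week sits slightly above the middle of its
2017–2020 envelope overall, while 32 % of pixels fall below the common
drought-stress threshold of 0.35.

The same chain is scriptable from a shell via `exec/vegindex`
(subcommands `ndvi`, `composite`, `climatology`, `derive`, `name`,
`synth`, `run`).

## Documentation

The methods vignette (`vignettes/vegindex-methods.Rmd`) describes the
product chain, the calendar, every numerical choice (rounding, clamping,
degenerate denominators, reference policies), what the synthetic generator
does and does not emulate, and known limitations.
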