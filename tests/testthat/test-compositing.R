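make_tile <- function(nr, nc, origin_x, origin_y, fill_red, fill_nir,
                      date = "2021-06-07", valid = NULL) {
  g <- grid_geometry(nr, nc, origin_x, origin_y, pixel_size = 1)
  reflectance_scene(matrix(as.integer(fill_red), nr, nc),
                    matrix(as.integer(fill_nir), nr, nc),
                    date, valid = valid, geometry = g)
}

test_that("mosaic of one tile over its own bounds is the identity", {
  t1 <- make_tile(4, 5, 0, 4, 2000, 6000)
  out <- mosaic_clip(list(t1), aoi = c(0, 0, 5, 4))
  expect_identical(out$red, t1$red)
  expect_identical(out$nir, t1$nir)
  expect_identical(out$valid, t1$valid)
  expect_true(same_geometry(out$geometry, t1$geometry))
})

test_that("disjoint tiles union their extents and conserve valid counts", {
  t1 <- make_tile(4, 4, 0, 4, 2000, 6000)
  t2 <- make_tile(4, 4, 4, 4, 1000, 3000)
  out <- mosaic_clip(list(t1, t2))
  expect_equal(out$geometry$n_cols, 8L)
  expect_equal(out$geometry$n_rows, 4L)
  expect_equal(sum(out$valid), sum(t1$valid) + sum(t2$valid))
  expect_true(all(out$red[, 1:4] == 2000L))
  expect_true(all(out$red[, 5:8] == 1000L))
})

test_that("overlapping tiles resolve to the first valid value in input order", {
  t1 <- make_tile(4, 4, 0, 4, 2000, 6000)
  t2 <- make_tile(4, 4, 2, 4, 1000, 3000)   # overlaps columns 3..4 of t1
  out <- mosaic_clip(list(t1, t2))
  expect_true(all(out$red[, 3:4] == 2000L))  # A valid, B valid -> A wins
  # where A is invalid, B fills in
  t1b <- t1
  t1b$valid[, 3] <- FALSE
  out2 <- mosaic_clip(list(t1b, t2))
  expect_true(all(out2$red[, 3] == 1000L))
  expect_true(all(out2$red[, 4] == 2000L))
})

test_that("mosaic rejects mixed dates, CRSs and unaligned lattices", {
  t1 <- make_tile(4, 4, 0, 4, 2000, 6000)
  t2 <- make_tile(4, 4, 4, 4, 1000, 3000, date = "2021-06-08")
  expect_error(mosaic_clip(list(t1, t2)), "mixed dates")
  t3 <- make_tile(4, 4, 4, 4, 1000, 3000)
  t3$geometry$crs_id <- "EPSG:32614"
  expect_error(mosaic_clip(list(t1, t3)), "mixed CRSs")
  t4 <- make_tile(4, 4, 4.5, 4, 1000, 3000)
  expect_error(mosaic_clip(list(t1, t4)), "lattice")
  expect_error(mosaic_clip(list(t1), aoi = c(100, 100, 110, 110)),
               "does not intersect")
})

test_that("polygon AOIs mask cell centers outside the ring", {
  t1 <- make_tile(4, 4, 0, 4, 2000, 6000)
  # triangle covering the lower-left half
  tri <- rbind(c(0, 0), c(4, 0), c(0, 4), c(0, 0))
  out <- mosaic_clip(list(t1), aoi = tri)
  expect_true(out$valid[4, 1])    # bottom-left center (0.5, 0.5)
  expect_false(out$valid[1, 4])   # top-right center (3.5, 3.5)
  expect_equal(sum(out$valid), 6) # strict lower triangle of centers
})

test_that("mvc picks the per-pixel maximum over valid days", {
  d1 <- ndvi_grid(matrix(c(0.2, NA, NA, 0.1), 2, 2))
  d2 <- ndvi_grid(matrix(c(0.5, 0.3, NA, -0.2), 2, 2))
  out <- mvc(list(d1, d2))
  expect_equal(out$values, matrix(c(0.5, 0.3, NA, 0.1), 2, 2))
  expect_equal(attr(out, "n_days"), 2L)
  # single grid is the identity; empty list errors
  expect_equal(mvc(list(d1))$values, d1$values)
  expect_error(mvc(list()), "at least one")
})

test_that("mvc dominance, permutation invariance and mask shrinkage hold", {
  set.seed(14)
  week <- synth_daily_week(2021, 23, nr = 32, nc = 32, seed = 4,
                           clouds = 0.4)
  grids <- week$grids
  out <- mvc(grids, week$period)
  stackv <- simplify2array(lapply(grids, `[[`, "values"))
  # brute-force oracle: per-pixel max over the day axis
  oracle <- apply(stackv, c(1, 2), function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  expect_equal(out$values, oracle)
  # dominance: >= every valid daily value, and equal to one of them
  for (g in grids) {
    ok <- !is.na(g$values)
    expect_true(all(out$values[ok] >= g$values[ok]))
  }
  # permutation invariance
  out2 <- mvc(rev(grids), week$period)
  expect_identical(out2$values, out$values)
  # output masked set is a subset of every day's masked set
  expect_true(all(which(is.na(out$values)) %in% which(is.na(grids[[1]]$values))))
})

test_that("two weekly composites compose to the biweekly composite", {
  w1 <- synth_daily_week(2021, 1, nr = 32, nc = 32, seed = 21, clouds = 0.3)
  w2 <- synth_daily_week(2021, 2, nr = 32, nc = 32, seed = 22, clouds = 0.3)
  biweek <- biweekly_partition(2021)[[1]]
  direct <- mvc(c(w1$grids, w2$grids), biweek)
  via_weekly <- mvc(list(mvc(w1$grids, w1$period), mvc(w2$grids, w2$period)),
                    biweek)
  expect_identical(via_weekly$values, direct$values)
})

test_that("mvc rejects days outside the stated period and mixed geometry", {
  d_in <- ndvi_grid(matrix(0.3, 2, 2), year = 2021, week = 23)
  expect_error(mvc(list(d_in), period = week_partition(2021)[[24]]),
               "outside the composite period")
  g2 <- index_grid(matrix(0.3, 3, 3), "NDVI", week_partition(2021)[[23]])
  expect_error(mvc(list(d_in, g2)), "co-registered")
})
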