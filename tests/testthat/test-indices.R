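test_that("reflectance validation masks the sensor range without touching values", {
  s <- reflectance_scene(matrix(c(0L, 16001L, 50L, -200L), 2, 2),
                         matrix(c(16000L, 0L, -100L, 100L), 2, 2),
                         "2021-06-07",
                         valid = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2))
  v <- validate_reflectance(s)
  # boundary values valid; +1 over the top excluded; already-invalid stays
  expect_identical(v$valid, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_identical(v$red, s$red)
  expect_identical(v$nir, s$nir)
  # mask monotonicity on random scenes
  set.seed(3)
  for (i in 1:20) {
    r <- matrix(sample(c(-500:17000), 64, TRUE), 8, 8)
    n <- matrix(sample(c(-500:17000), 64, TRUE), 8, 8)
    mask <- matrix(sample(c(TRUE, FALSE), 64, TRUE), 8, 8)
    out <- validate_reflectance(reflectance_scene(r, n, "2021-01-05", mask))
    expect_true(all(out$valid <= mask))
  }
  expect_error(reflectance_scene(matrix(0L, 2, 2), matrix(0L, 3, 2),
                                 "2021-01-05"), "shape")
})

test_that("ndvi computes the normalized difference and masks degenerates", {
  s <- reflectance_scene(matrix(c(4000L, 2000L, 0L, 6000L), 2, 2),
                         matrix(c(4000L, 6000L, 0L, 2000L), 2, 2),
                         "2021-06-07")
  g <- ndvi(s)
  expect_equal(g$values[1, 1], 0)
  expect_equal(g$values[2, 1], 0.5)     # 4000 / 8000
  expect_true(is.na(g$values[1, 2]))    # 0/0 pixel
  expect_equal(g$values[2, 2], -0.5)
  expect_identical(g$kind, "NDVI")
  expect_identical(g$period$cadence, "daily")
  # negative-but-valid reflectances stay computable and clamped
  s2 <- reflectance_scene(matrix(-100L, 1, 1), matrix(50L, 1, 1),
                          "2021-06-07")
  expect_true(ndvi(validate_reflectance(s2))$values[1, 1] <= 1)
})

test_that("vci positions current NDVI inside the historical envelope", {
  cur <- ndvi_grid(c(0.5, 0.2, 0.8, 0.5))
  mn <- ndvi_grid(c(0.2, 0.2, 0.2, 0.4))
  mx <- ndvi_grid(c(0.8, 0.8, 0.8, 0.4))
  v <- vci(cur, mn, mx)
  expect_equal(v$values[1, 1], 0.5)   # 0.3 / 0.6
  expect_equal(v$values[1, 2], 0)     # cur = min
  expect_equal(v$values[1, 3], 1)     # cur = max
  expect_true(is.na(v$values[1, 4]))  # degenerate max = min
  expect_identical(v$kind, "VCI")

  # affine invariance: shifting all three inputs leaves VCI unchanged
  sh <- 0.1
  v2 <- vci(ndvi_grid(c(0.5, 0.2, 0.8, 0.5) + sh),
            ndvi_grid(c(0.2, 0.2, 0.2, 0.4) + sh),
            ndvi_grid(c(0.8, 0.8, 0.8, 0.4) + sh))
  expect_equal(v2$values[, 1:3], v$values[, 1:3])

  # monotone in current NDVI
  set.seed(5)
  lo <- runif(50, -0.5, 0.2); hi <- lo + runif(50, 0.05, 0.5)
  c1 <- runif(50, lo, hi); c2 <- pmin(c1 + runif(50, 0, 0.3), hi)
  va <- vci(ndvi_grid(c1), ndvi_grid(lo), ndvi_grid(hi))$values
  vb <- vci(ndvi_grid(c2), ndvi_grid(lo), ndvi_grid(hi))$values
  expect_true(all(vb >= va))
  # above-archive current clamps to 1 rather than exceeding it
  over <- vci(ndvi_grid(0.9), ndvi_grid(0.2), ndvi_grid(0.8))
  expect_equal(over$values[1, 1], 1)
})

test_that("ratio indices deviate from their reference and saturate at 125%", {
  cur <- ndvi_grid(c(0.6, 0.4, 1.0, 0.3))
  ref <- ndvi_grid(c(0.4, 0.4, 0.1, 0))
  for (f in list(mvci, rmvci)) {
    r <- f(cur, ref)
    expect_equal(r$values[1, 1], 0.5)    # 0.2 / 0.4
    expect_equal(r$values[1, 2], 0)      # cur = ref
    expect_equal(r$values[1, 3], 1.25)   # clamped from 9.0
    expect_true(is.na(r$values[1, 4]))   # zero reference
  }
  expect_identical(mvci(cur, ref)$kind, "MVCI")
  expect_identical(rmvci(cur, ref)$kind, "RMVCI")
})

test_that("rvci compares consecutive years of the same week", {
  cur <- ndvi_grid(c(0.3, 0.6), year = 2021, week = 23)
  prev <- ndvi_grid(c(0.6, 0.6), year = 2020, week = 23)
  r <- rvci(cur, prev)
  expect_equal(r$values[1, 1], -0.5)   # -0.3 / 0.6
  expect_equal(r$values[1, 2], 0)
  expect_identical(r$kind, "RVCI")
  expect_error(rvci(cur, ndvi_grid(c(0.5, 0.5), year = 2019, week = 23)),
               "preceding year")
  expect_error(rvci(cur, ndvi_grid(c(0.5, 0.5), year = 2020, week = 24)),
               "same period")
  # the week-52 alignment for week 53 of a short previous year is accepted
  expect_silent(rvci(ndvi_grid(c(0.3, 0.6), year = 2020, week = 53),
                     ndvi_grid(c(0.5, 0.5), year = 2019, week = 52)))
})

test_that("index outputs respect declared ranges and mask algebra", {
  set.seed(9)
  for (i in 1:10) {
    cv <- matrix(runif(36, -1, 1), 6, 6)
    rv <- matrix(runif(36, -0.2, 0.9), 6, 6)
    cv[sample(36, 6)] <- NA
    rv[sample(36, 6)] <- NA
    cur <- ndvi_grid(cv)
    ref <- ndvi_grid(rv)
    out <- mvci(cur, ref)$values
    ok <- !is.na(out)
    expect_true(all(out[ok] >= -1.25 & out[ok] <= 1.25))
    # output mask contains every input mask plus degenerate denominators
    expect_true(all(is.na(out)[is.na(cv) | is.na(rv) |
                                 (!is.na(rv) & rv == 0)]))
    expect_identical(is.na(out), is.na(cv) | is.na(rv) |
                       (!is.na(rv) & rv == 0))
  }
  expect_error(vci(ndvi_grid(0.5),
                   index_grid(matrix(0.1, 2, 2), "NDVI",
                              week_partition(2021)[[23]]),
                   index_grid(matrix(0.9, 2, 2), "NDVI",
                              week_partition(2021)[[23]])),
               "co-registered")
})
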