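test_that("derived fields match hand statistics and the n=1 degenerate case", {
  y1 <- ndvi_grid(matrix(c(0.2, NA), 1, 2), year = 2018, week = 5)
  y2 <- ndvi_grid(matrix(c(0.4, NA), 1, 2), year = 2019, week = 5)
  y3 <- ndvi_grid(matrix(c(0.9, NA), 1, 2), year = 2020, week = 5)
  st <- climatology_build(list(y1, y2, y3))
  d <- st$derived[[5]]
  expect_equal(d$min[1, 1], 0.2)
  expect_equal(d$max[1, 1], 0.9)
  expect_equal(d$mean[1, 1], 0.5)
  expect_equal(d$median[1, 1], 0.4)
  # pixel masked in every year stays masked in all derived fields
  for (f in d) expect_true(is.na(f[1, 2]))
  # single-year stack: every statistic is that year's grid
  s1 <- climatology_build(list(y1))
  for (f in s1$derived[[5]]) expect_identical(f[1, 1], 0.2)
  # 53 week slots exist regardless of the years stored
  expect_length(st$weeks, 53)
  expect_length(climatology_build(list(ndvi_grid(matrix(0.3, 1, 1),
                                                 year = 2020, week = 1,
                                                 cadence = "biweekly")))$weeks,
                27)
})

test_that("median of an even year-count averages the two central values", {
  set.seed(31)
  grids <- lapply(seq_len(4), function(i)
    ndvi_grid(matrix(runif(16, 0, 0.9), 4, 4), year = 2016 + i, week = 10))
  st <- climatology_build(grids)
  vals <- simplify2array(lapply(grids, `[[`, "values"))
  # sorting oracle
  oracle <- apply(vals, c(1, 2), function(x) {
    s <- sort(x)
    (s[2] + s[3]) / 2
  })
  expect_equal(st$derived[[10]]$median, oracle)
})

test_that("incremental update equals a rebuild bitwise", {
  composites <- synth_weekly_archive(2017:2021, weeks = c(3, 7), nr = 16,
                                     nc = 16, seed = 2, clouds = 0.2)
  is_last_year <- vapply(composites, function(g) g$period$year == 2021L, TRUE)
  full <- climatology_build(composites)
  partial <- climatology_build(composites[!is_last_year])
  for (g in composites[is_last_year]) {
    partial <- climatology_update(partial, g)
  }
  for (w in c(3, 7)) {
    expect_identical(partial$weeks[[w]], full$weeks[[w]])
    expect_identical(partial$derived[[w]], full$derived[[w]])
  }
})

test_that("replacing a year and inserting an all-masked grid behave like rebuilds", {
  composites <- synth_weekly_archive(2018:2020, weeks = 4, nr = 8, nc = 8,
                                     seed = 6)
  st <- climatology_build(composites)
  # replace 2019 with a different grid
  repl <- ndvi_grid(matrix(0.33, 8, 8), year = 2019, week = 4)
  expect_message(st2 <- climatology_update(st, repl), "replacing")
  rebuilt <- climatology_build(c(composites[c(1, 3)], list(repl)))
  expect_identical(st2$derived[[4]], rebuilt$derived[[4]])
  # an all-masked year leaves min/max/range statements intact per pixel
  blank <- ndvi_grid(matrix(NA_real_, 8, 8), year = 2021, week = 4)
  st3 <- climatology_update(st2, blank)
  expect_identical(st3$derived[[4]], st2$derived[[4]])
})

test_that("min <= mean/median <= max and year insertion only widens the envelope", {
  composites <- synth_weekly_archive(2016:2020, weeks = 9, nr = 12, nc = 12,
                                     seed = 8, clouds = 0.3)
  st <- climatology_build(composites[-5])
  d0 <- st$derived[[9]]
  st <- climatology_update(st, composites[[5]])
  d <- st$derived[[9]]
  ok <- !is.na(d$min)
  expect_true(all(d$min[ok] <= d$median[ok] & d$median[ok] <= d$max[ok]))
  expect_true(all(d$min[ok] <= d$mean[ok] & d$mean[ok] <= d$max[ok]))
  both <- ok & !is.na(d0$min)
  expect_true(all(d$min[both] <= d0$min[both]))
  expect_true(all(d$max[both] >= d0$max[both]))
})

test_that("reference_for applies the year policy and errors on empty sets", {
  composites <- synth_weekly_archive(2018:2021, weeks = 2, nr = 8, nc = 8,
                                     seed = 12)
  st <- climatology_build(composites)
  all_years <- reference_for(st, 2, "mean")
  excl <- reference_for(st, 2, "mean", year = 2021)
  incl <- reference_for(st, 2, "mean", year = 2021, include_current = TRUE)
  expect_identical(attr(all_years, "years"), 2018:2021)
  expect_identical(attr(excl, "years"), 2018:2020)  # one year fewer
  expect_identical(attr(incl, "years"), 2018:2021)
  expect_identical(incl$values, all_years$values)
  # excluding the current year really changes the statistic
  expect_false(identical(excl$values, all_years$values))
  # matches a from-scratch derivation over the admitted years
  sub <- Filter(function(g) g$period$year < 2021, composites)
  expect_identical(excl$values, climatology_build(sub)$derived[[2]]$mean)
  expect_error(reference_for(st, 2, "min", year = 2018), "no reference years")
  expect_error(reference_for(st, 40, "min"), "no reference years")
})

test_that("previous_year looks up the archive with the week-53 fallback", {
  g20 <- ndvi_grid(matrix(0.4, 4, 4), year = 2020, week = 23)
  g21 <- ndvi_grid(matrix(0.6, 4, 4), year = 2021, week = 23)
  st <- climatology_build(list(g20, g21))
  prev <- previous_year(st, 2021, 23)
  expect_identical(prev$values, g20$values)
  expect_identical(prev$period$year, 2020L)
  # 2020 had 53 weeks; 2019 did not -> week 52 stands in
  g19 <- ndvi_grid(matrix(0.5, 4, 4), year = 2019, week = 52)
  st2 <- climatology_build(list(g19, ndvi_grid(matrix(0.7, 4, 4),
                                               year = 2020, week = 53)))
  expect_message(p53 <- previous_year(st2, 2020, 53), "week 52")
  expect_identical(p53$values, g19$values)
  expect_identical(p53$period$week, 52L)
  expect_error(previous_year(st, 2020, 23), "no composite archived")
})
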