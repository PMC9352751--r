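# every example string of the operational naming convention, regenerated
# byte-for-byte
test_that("layer names reproduce the published convention exactly", {
  w1 <- week_partition(2021)[[1]]
  b1 <- biweekly_partition(2021)[[1]]
  d1 <- daily_partition(2021)[[1]]
  expect_identical(layer_name("NDVI", d1), "NDVI-DAILY_2021.01.01")
  expect_identical(layer_name("NDVI", w1),
                   "NDVI-WEEKLY_2021_01_2021.01.04_2021.01.10")
  expect_identical(layer_name("NDVI", b1),
                   "NDVI-BIWEEKLY_2021_01_2021.01.04_2021.01.17")
  expect_identical(layer_name("NDVI", w1, method = "MEAN"),
                   "NDVI-MULTIYEAR-WEEKLY_01_MEAN")
  expect_identical(layer_name("VCI", w1),
                   "VCI-WEEKLY_2021_01_2021.01.04_2021.01.10")
  expect_identical(layer_name("VCI", b1),
                   "VCI-BIWEEKLY_2021_01_2021.01.04_2021.01.17")
  expect_identical(layer_name("MVCI", w1),
                   "MVCI-WEEKLY_2021_01_2021.01.04_2021.01.10")
  expect_identical(layer_name("MVCI", b1),
                   "MVCI-BIWEEKLY_2021_01_2021.01.04_2021.01.17")
  # RVCI and RMVCI keep their legacy service aliases
  expect_identical(layer_name("RVCI", w1),
                   "RNDVI-WEEKLY_2021_01_2021.01.04_2021.01.10")
  expect_identical(layer_name("RVCI", b1),
                   "RNDVI-BIWEEKLY_2021_01_2021.01.04_2021.01.17")
  expect_identical(layer_name("RMVCI", w1),
                   "RMNDVI-WEEKLY_2021_01_2021.01.04_2021.01.10")
  expect_identical(layer_name("RMVCI", b1),
                   "RMNDVI-BIWEEKLY_2021_01_2021.01.04_2021.01.17")
})

test_that("map-file names reproduce the published convention exactly", {
  expect_identical(map_name("NDVI", "daily", 2021), "NDVI-DAILY_2021")
  expect_identical(map_name("NDVI", "weekly", 2021), "NDVI-WEEKLY_2021")
  expect_identical(map_name("NDVI", "biweekly", 2021), "NDVI-BIWEEKLY_2021")
  expect_identical(map_name("NDVI", "weekly", multiyear = TRUE),
                   "NDVI-MULTIYEAR-WEEKLY")
  expect_identical(map_name("NDVI", "biweekly", multiyear = TRUE),
                   "NDVI-MULTIYEAR-BIWEEKLY")
  expect_identical(map_name("VCI", "weekly", 2021), "VCI-WEEKLY_2021")
  expect_identical(map_name("RVCI", "weekly", 2021), "RNDVI-WEEKLY_2021")
  expect_identical(map_name("RMVCI", "biweekly", 2021),
                   "RMNDVI-BIWEEKLY_2021")
})

test_that("parse_layer_name is the exact inverse on randomized layers", {
  set.seed(23)
  kinds <- c("NDVI", "VCI", "MVCI", "RMVCI", "RVCI")
  for (i in 1:40) {
    year <- sample(2000:2030, 1)
    cadence <- sample(c("weekly", "biweekly"), 1)
    parts <- if (cadence == "weekly") week_partition(year)
             else biweekly_partition(year)
    per <- parts[[sample(seq_along(parts), 1)]]
    kind <- sample(kinds, 1)
    nm <- layer_name(kind, per)
    back <- parse_layer_name(nm)
    expect_identical(back$kind, kind)
    expect_identical(back$cadence, cadence)
    expect_identical(back$period$year, per$year)
    expect_identical(back$period$week, per$week)
    expect_identical(back$period$start_date, per$start_date)
    expect_identical(back$period$end_date, per$end_date)
    expect_identical(layer_name(back$kind, back$period), nm)
  }
  # daily and multi-year forms
  d <- parse_layer_name("NDVI-DAILY_2021.02.28")
  expect_identical(d$period$start_date, as.Date("2021-02-28"))
  m <- parse_layer_name("NDVI-MULTIYEAR-BIWEEKLY_07_MEDIAN")
  expect_identical(m$method, "MEDIAN")
  expect_identical(m$week, 7L)
})

test_that("parse rejects non-conforming names", {
  expect_error(parse_layer_name("EVI-WEEKLY_2021_01_2021.01.04_2021.01.10"),
               "not a recognised")
  expect_error(parse_layer_name("NDVI-WEEKLY_2021_1_2021.01.04_2021.01.10"),
               "not a recognised")
  expect_error(parse_layer_name("NDVI-MULTIYEAR-WEEKLY_01_MODE"),
               "not a recognised")
  expect_error(layer_name("VCI", week_partition(2021)[[1]], method = "MEAN"),
               "only for NDVI")
})
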