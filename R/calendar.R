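#' Composite period
#'
#' A temporal slot of the product calendar: one day, one ISO-8601 week, or a
#' pair of consecutive ISO weeks ("biweekly"). Weekly slots run Monday to
#' Sunday; biweekly slots pair ISO weeks (1,2), (3,4), ... and an unpaired
#' ISO week 53 forms a short final 7-day slot. For daily cadence `week` holds
#' the day of year.
#'
#' @param year Product year (ISO year for weekly/biweekly cadence, calendar
#'   year for daily).
#' @param week Slot number: ISO week 1..53 (weekly), biweekly slot 1..27, or
#'   day of year 1..366 (daily).
#' @param start_date,end_date First and last calendar date of the slot.
#' @param cadence `"daily"`, `"weekly"` or `"biweekly"`.
#' @return An object of class `composite_period`.
#' @export
composite_period <- function(year, week, start_date, end_date,
                             cadence = c("weekly", "biweekly", "daily")) {
  cadence <- match.arg(cadence)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  span <- as.integer(end_date - start_date) + 1L
  ok <- switch(cadence,
    daily    = span == 1L,
    weekly   = span == 7L,
    biweekly = span %in% c(7L, 14L))  # 7 when an orphan week 53 closes the year
  if (!ok) stop(sprintf("span of %d day(s) is invalid for %s cadence",
                        span, cadence), call. = FALSE)
  structure(
    list(year = as.integer(year), week = as.integer(week),
         start_date = start_date, end_date = end_date, cadence = cadence),
    class = "composite_period")
}

#' @export
print.composite_period <- function(x, ...) {
  cat(sprintf("<composite_period> %s %d-%02d: %s .. %s\n", x$cadence,
              x$year, x$week, format(x$start_date), format(x$end_date)))
  invisible(x)
}

#' @export
format.composite_period <- function(x, ...) {
  sprintf("%s %d-%02d (%s..%s)", x$cadence, x$year, x$week,
          format(x$start_date), format(x$end_date))
}

same_period <- function(a, b) {
  identical(a$cadence, b$cadence) && a$year == b$year && a$week == b$week
}

# Monday starting ISO week 1 of `year` (the week containing January 4th).
iso_week1_start <- function(year) {
  jan4 <- as.Date(sprintf("%d-01-04", year))
  jan4 - (as.POSIXlt(jan4)$wday + 6L) %% 7L
}

# number of ISO weeks in a year: 52 or 53
n_iso_weeks <- function(year) {
  as.integer(iso_week1_start(year + 1L) - iso_week1_start(year)) %/% 7L
}

#' ISO year and week of a date
#'
#' @param date A `Date` (or coercible). Vectorised.
#' @return A data.frame with columns `year` and `week` (ISO-8601). Dates near
#'   calendar-year boundaries belong to their ISO year, e.g. 2021-01-01 falls
#'   in week 53 of ISO year 2020.
#' @examples
#' week_of("2021-06-07")  # week 23 of 2021
#' @export
week_of <- function(date) {
  date <- as.Date(date)
  data.frame(year = as.integer(format(date, "%G")),
             week = as.integer(format(date, "%V")))
}

#' Weekly partition of a year
#'
#' The ISO-8601 weeks of `year`, each a Monday-to-Sunday
#' [composite_period()]. A year has 52 or 53 ISO weeks.
#'
#' @param year Year (>= 2000).
#' @return List of `composite_period`, in order.
#' @export
week_partition <- function(year) {
  stopifnot(year >= 2000)
  w1 <- iso_week1_start(year)
  lapply(seq_len(n_iso_weeks(year)), function(k) {
    start <- w1 + 7L * (k - 1L)
    composite_period(year, k, start, start + 6L, "weekly")
  })
}

#' Biweekly partition of a year
#'
#' Consecutive ISO-week pairs (1,2), (3,4), ...; slot `k` spans ISO weeks
#' `2k-1` and `2k`. In a 53-week year the unpaired week 53 becomes a short
#' final 7-day slot.
#'
#' @param year Year (>= 2000).
#' @return List of `composite_period` with cadence `"biweekly"`.
#' @export
biweekly_partition <- function(year) {
  stopifnot(year >= 2000)
  w1 <- iso_week1_start(year)
  nw <- n_iso_weeks(year)
  n_slots <- ceiling(nw / 2)
  lapply(seq_len(n_slots), function(k) {
    start <- w1 + 14L * (k - 1L)
    ndays <- if (2L * k <= nw) 14L else 7L
    composite_period(year, k, start, start + ndays - 1L, "biweekly")
  })
}

#' Daily partition of a year
#'
#' One [composite_period()] per calendar day; `week` holds the day of year.
#'
#' @param year Year (>= 2000).
#' @return List of 365 or 366 `composite_period` with cadence `"daily"`.
#' @export
daily_partition <- function(year) {
  stopifnot(year >= 2000)
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  lapply(seq_along(days), function(k) {
    composite_period(year, k, days[k], days[k], "daily")
  })
}

# the weekly or biweekly period containing `date`
period_of <- function(date, cadence = c("weekly", "biweekly", "daily")) {
  cadence <- match.arg(cadence)
  date <- as.Date(date)
  if (cadence == "daily") {
    yr <- as.integer(format(date, "%Y"))
    return(composite_period(yr, as.integer(format(date, "%j")),
                            date, date, "daily"))
  }
  iso <- week_of(date)
  if (cadence == "weekly") {
    week_partition(iso$year)[[iso$week]]
  } else {
    biweekly_partition(iso$year)[[(iso$week + 1L) %/% 2L]]
  }
}

KIND_LEVELS <- c("NDVI", "VCI", "MVCI", "RMVCI", "RVCI")
# operational layer-name aliases kept from the service's legacy convention
KIND_PREFIX <- c(NDVI = "NDVI", VCI = "VCI", MVCI = "MVCI",
                 RMVCI = "RMNDVI", RVCI = "RNDVI")
MULTIYEAR_METHODS <- c("MIN", "MAX", "MEAN", "MEDIAN")

check_kind <- function(kind) {
  kind <- toupper(as.character(kind))
  if (!kind %in% KIND_LEVELS) {
    stop(sprintf("unknown index kind '%s'", kind), call. = FALSE)
  }
  kind
}

fmt_dot_date <- function(d) format(as.Date(d), "%Y.%m.%d")

#' Product layer name
#'
#' Builds the operational layer-name string for a product. Daily NDVI layers
#' are named `NDVI-DAILY_YYYY.MM.DD`; weekly/biweekly layers are
#' `<PREFIX>-<CADENCE>_<YEAR>_<WW>_<START>_<END>` with dates as `YYYY.MM.DD`
#' and the slot number zero-padded to two digits; multi-year reference layers
#' are `NDVI-MULTIYEAR-<CADENCE>_<WW>_<METHOD>`. RVCI and RMVCI keep their
#' legacy layer prefixes `RNDVI` and `RMNDVI`.
#'
#' @param kind Index kind: `"NDVI"`, `"VCI"`, `"MVCI"`, `"RMVCI"`, `"RVCI"`.
#' @param period A [composite_period()]. For multi-year layers only its
#'   cadence and week are used.
#' @param method For multi-year NDVI reference layers, one of
#'   `"MIN"`, `"MAX"`, `"MEAN"`, `"MEDIAN"`; otherwise `NULL`.
#' @return A single string.
#' @examples
#' p <- week_partition(2021)[[1]]
#' layer_name("VCI", p)                    # "VCI-WEEKLY_2021_01_2021.01.04_2021.01.10"
#' layer_name("NDVI", p, method = "MEAN")  # "NDVI-MULTIYEAR-WEEKLY_01_MEAN"
#' @export
layer_name <- function(kind, period, method = NULL) {
  kind <- check_kind(kind)
  stopifnot(inherits(period, "composite_period"))
  if (!is.null(method)) {
    method <- toupper(method)
    if (kind != "NDVI") {
      stop("multi-year reference layers exist only for NDVI", call. = FALSE)
    }
    if (!method %in% MULTIYEAR_METHODS) {
      stop(sprintf("method must be one of %s",
                   paste(MULTIYEAR_METHODS, collapse = "/")), call. = FALSE)
    }
    if (period$cadence == "daily") {
      stop("multi-year layers are weekly or biweekly", call. = FALSE)
    }
    return(sprintf("NDVI-MULTIYEAR-%s_%02d_%s",
                   toupper(period$cadence), period$week, method))
  }
  if (period$cadence == "daily") {
    if (kind != "NDVI") stop("only NDVI has a daily product", call. = FALSE)
    return(sprintf("NDVI-DAILY_%s", fmt_dot_date(period$start_date)))
  }
  sprintf("%s-%s_%d_%02d_%s_%s",
          KIND_PREFIX[[kind]], toupper(period$cadence), period$year,
          period$week, fmt_dot_date(period$start_date),
          fmt_dot_date(period$end_date))
}

#' Map-file name grouping a year of layers
#'
#' The coarser naming level of the service convention: `NDVI-DAILY_2021`,
#' `VCI-WEEKLY_2021`, `NDVI-MULTIYEAR-WEEKLY`, ...
#'
#' @inheritParams layer_name
#' @param cadence `"daily"`, `"weekly"` or `"biweekly"`.
#' @param year Product year; ignored for multi-year maps.
#' @param multiyear Logical; name the multi-year NDVI reference map.
#' @return A single string.
#' @export
map_name <- function(kind, cadence, year = NULL, multiyear = FALSE) {
  kind <- check_kind(kind)
  cadence <- match.arg(cadence, c("daily", "weekly", "biweekly"))
  if (multiyear) {
    stopifnot(kind == "NDVI", cadence != "daily")
    return(sprintf("NDVI-MULTIYEAR-%s", toupper(cadence)))
  }
  sprintf("%s-%s_%d", KIND_PREFIX[[kind]], toupper(cadence),
          as.integer(year))
}

#' Parse a product layer name
#'
#' Exact inverse of [layer_name()].
#'
#' @param name A layer-name string.
#' @return A list with elements `kind`, `cadence`, `method` (or `NULL`) and,
#'   where applicable, `period` (a [composite_period()]) or `week`.
#' @export
parse_layer_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  rx_date <- "\\d{4}\\.\\d{2}\\.\\d{2}"
  prefix_to_kind <- stats::setNames(names(KIND_PREFIX), KIND_PREFIX)

  m <- regmatches(name, regexec(
    sprintf("^NDVI-DAILY_(%s)$", rx_date), name))[[1]]
  if (length(m)) {
    d <- as.Date(m[2], format = "%Y.%m.%d")
    return(list(kind = "NDVI", cadence = "daily", method = NULL,
                period = period_of(d, "daily")))
  }

  m <- regmatches(name, regexec(
    "^NDVI-MULTIYEAR-(WEEKLY|BIWEEKLY)_(\\d{2})_(MIN|MAX|MEAN|MEDIAN)$",
    name))[[1]]
  if (length(m)) {
    return(list(kind = "NDVI", cadence = tolower(m[2]), method = m[4],
                week = as.integer(m[3])))
  }

  m <- regmatches(name, regexec(sprintf(
    "^(NDVI|VCI|MVCI|RMNDVI|RNDVI)-(WEEKLY|BIWEEKLY)_(\\d{4})_(\\d{2})_(%s)_(%s)$",
    rx_date, rx_date), name))[[1]]
  if (length(m)) {
    cad <- tolower(m[3])
    per <- composite_period(as.integer(m[4]), as.integer(m[5]),
                            as.Date(m[6], format = "%Y.%m.%d"),
                            as.Date(m[7], format = "%Y.%m.%d"), cad)
    return(list(kind = prefix_to_kind[[m[2]]], cadence = cad, method = NULL,
                period = per))
  }
  stop(sprintf("'%s' is not a recognised product layer name", name),
       call. = FALSE)
}
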