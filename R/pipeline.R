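#' Run the full production pipeline
#'
#' Drives the whole chain in dependency order: validate reflectance scenes,
#' mosaic/clip each acquisition date, compute daily NDVI, build weekly or
#' biweekly maximum-value composites, update the multi-year climatology, and
#' derive, encode and write the requested anomaly products. Re-runs are
#' idempotent at the product level: an output file that already exists is
#' skipped, and a rerun with nothing to produce performs no recomputation.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Recognised keys:
#'   \describe{
#'     \item{`scenes`}{List of acquisitions; each entry either a
#'       [reflectance_scene()] or a list with `red`, `nir` (GeoTIFF paths)
#'       and `date`. Multiple entries may share a date (tiles to mosaic).}
#'     \item{`out_dir`}{Output directory for product GeoTIFFs (required).}
#'     \item{`aoi`}{Optional bounding box `c(xmin, ymin, xmax, ymax)` or
#'       GeoJSON polygon path.}
#'     \item{`archive_dir`}{Optional directory of encoded composite products
#'       forming the historical archive; new composites are appended to it.}
#'     \item{`cadence`}{`"weekly"` (default) or `"biweekly"`.}
#'     \item{`products`}{Character subset of
#'       `c("NDVI", "VCI", "MVCI", "RMVCI", "RVCI")` to derive per period
#'       (default all five).}
#'     \item{`daily_ndvi`}{Write the per-date daily NDVI products
#'       (default `FALSE`).}
#'     \item{`include_current_year`}{Reference policy: admit the current
#'       product year into the multi-year references (default `FALSE`).}
#'     \item{`overwrite`}{Recompute products whose files exist
#'       (default `FALSE`).}
#'   }
#' @return Invisibly, a list with `products` (a data.frame of layer name,
#'   path and status: `"written"`, `"skipped"` or `"error: ..."`), `log`
#'   (per-stage valid/masked pixel counts) and `stack` (the final
#'   climatology stack).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  cadence <- if (is.null(config$cadence)) "weekly" else
    match.arg(config$cadence, c("weekly", "biweekly"))
  products <- if (is.null(config$products)) KIND_LEVELS else
    vapply(config$products, check_kind, "")
  overwrite <- isTRUE(config$overwrite)
  daily_ndvi <- isTRUE(config$daily_ndvi)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  scenes <- lapply(config$scenes, function(s) {
    if (inherits(s, "reflectance_scene")) s
    else read_scene(s$red, s$nir, s$date, validate = FALSE)
  })
  if (!length(scenes)) stop("config$scenes is empty", call. = FALSE)
  dates <- sort(unique(as.Date(vapply(scenes, function(s) format(s$date),
                                      ""))))

  # group dates by composite period
  period_key <- function(p) sprintf("%d_%02d", p$year, p$week)
  periods <- list()
  for (d in dates) {
    p <- period_of(as.Date(d, origin = "1970-01-01"), cadence)
    periods[[period_key(p)]] <- p
  }

  # plan every output file; a fully up-to-date plan short-circuits the run
  plan <- data.frame(name = character(), path = character(),
                     stage = character(), key = character(),
                     stringsAsFactors = FALSE)
  add_plan <- function(name, stage, key) {
    plan[nrow(plan) + 1L, ] <<- list(name, file.path(out_dir,
                                                     paste0(name, ".tif")),
                                     stage, key)
  }
  if (daily_ndvi) {
    for (d in dates) {
      dd <- as.Date(d, origin = "1970-01-01")
      add_plan(layer_name("NDVI", period_of(dd, "daily")), "daily",
               format(dd))
    }
  }
  for (key in names(periods)) {
    p <- periods[[key]]
    add_plan(layer_name("NDVI", p), "composite", key)
    for (k in setdiff(products, "NDVI")) {
      add_plan(layer_name(k, p), "derive", key)
    }
  }
  plan$exists <- file.exists(plan$path)
  log <- list(stages = data.frame(stage = character(), item = character(),
                                  valid = integer(), masked = integer(),
                                  stringsAsFactors = FALSE),
              errors = character())
  note <- function(stage, item, grid_vals) {
    log$stages[nrow(log$stages) + 1L, ] <<- list(
      stage, item, sum(!is.na(grid_vals)), sum(is.na(grid_vals)))
  }

  status <- stats::setNames(rep(NA_character_, nrow(plan)), plan$name)
  stack <- if (!is.null(config$archive_dir)) {
    climatology_from_dir(config$archive_dir, cadence)
  } else NULL

  if (all(plan$exists) && !overwrite) {
    status[] <- "skipped"
    res <- list(products = data.frame(name = plan$name, path = plan$path,
                                      status = unname(status),
                                      stringsAsFactors = FALSE),
                log = c(log, list(written = 0L, skipped = nrow(plan))),
                stack = stack)
    message(sprintf("all %d products up to date; nothing recomputed",
                    nrow(plan)))
    return(invisible(res))
  }

  # daily chain: validate -> mosaic/clip -> NDVI
  daily_ndvi_grids <- list()
  for (d in dates) {
    dd <- as.Date(d, origin = "1970-01-01")
    tiles <- Filter(function(s) s$date == dd, scenes)
    tiles <- lapply(tiles, validate_reflectance)
    scene <- mosaic_clip(tiles, config$aoi)
    note("mosaic_clip", format(dd), ifelse(scene$valid, 1, NA))
    g <- ndvi(scene)
    note("ndvi", format(dd), g$values)
    daily_ndvi_grids[[format(dd)]] <- g
    if (daily_ndvi) {
      nm <- layer_name("NDVI", g$period)
      i <- match(nm, plan$name)
      if (plan$exists[i] && !overwrite) {
        status[nm] <- "skipped"
      } else {
        write_product(encode_grid(g), plan$path[i])
        status[nm] <- "written"
      }
    }
  }

  # weekly/biweekly MVC composites + climatology update
  composites <- list()
  for (key in names(periods)) {
    p <- periods[[key]]
    in_period <- Filter(function(g) {
      g$period$start_date >= p$start_date & g$period$end_date <= p$end_date
    }, daily_ndvi_grids)
    comp <- mvc(unname(in_period), p)
    note("mvc", key, comp$values)
    composites[[key]] <- comp
    nm <- layer_name("NDVI", p)
    i <- match(nm, plan$name)
    if (plan$exists[i] && !overwrite) {
      status[nm] <- "skipped"
    } else {
      write_product(encode_grid(comp), plan$path[i])
      status[nm] <- "written"
    }
    if (!is.null(config$archive_dir)) {
      apath <- file.path(config$archive_dir, paste0(nm, ".tif"))
      if (!file.exists(apath)) {
        dir.create(config$archive_dir, showWarnings = FALSE, recursive = TRUE)
        write_product(encode_grid(comp), apath)
      }
    }
    # in-memory references keep full precision; only the archived files are
    # quantized to the 8-bit product form
    stack <- if (is.null(stack)) climatology_build(list(comp))
    else climatology_update(stack, comp)
  }

  # derived anomaly products
  include_cur <- isTRUE(config$include_current_year)
  for (key in names(periods)) {
    p <- periods[[key]]
    cur <- composites[[key]]
    for (k in setdiff(products, "NDVI")) {
      nm <- layer_name(k, p)
      i <- match(nm, plan$name)
      if (plan$exists[i] && !overwrite) {
        status[nm] <- "skipped"
        next
      }
      out <- tryCatch({
        g <- switch(k,
          VCI = vci(cur,
                    reference_for(stack, p$week, "min", p$year,
                                  include_cur),
                    reference_for(stack, p$week, "max", p$year,
                                  include_cur)),
          MVCI = mvci(cur, reference_for(stack, p$week, "mean", p$year,
                                         include_cur)),
          RMVCI = rmvci(cur, reference_for(stack, p$week, "median", p$year,
                                           include_cur)),
          RVCI = rvci(cur, previous_year(stack, p$year, p$week)))
        note("derive", nm, g$values)
        write_product(encode_grid(g), plan$path[i])
        "written"
      }, error = function(e) {
        msg <- sprintf("%s: %s", nm, conditionMessage(e))
        log$errors <<- c(log$errors, msg)
        paste0("error: ", conditionMessage(e))
      })
      status[nm] <- out
    }
  }

  written <- sum(status == "written", na.rm = TRUE)
  res <- list(products = data.frame(name = plan$name, path = plan$path,
                                    status = unname(status[plan$name]),
                                    stringsAsFactors = FALSE),
              log = c(log, list(written = written,
                                skipped = sum(status == "skipped",
                                              na.rm = TRUE))),
              stack = stack)
  message(sprintf("pipeline complete: %d written, %d skipped, %d error(s)",
                  written, res$log$skipped, length(log$errors)))
  invisible(res)
}
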