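#' Mosaic co-dated tiles and clip to an area of interest
#'
#' Merges reflectance tiles of the same date onto one grid and clips the
#' result to an area of interest. Tiles must share the date, CRS and pixel
#' size, and be co-aligned to a common lattice (origins differing by whole
#' pixels). Where tiles overlap, the first tile in input order that holds a
#' valid observation wins. Cells outside every tile, or outside the AOI, are
#' masked.
#'
#' @param tiles List of [reflectance_scene()] objects.
#' @param aoi Area of interest: a numeric bounding box
#'   `c(xmin, ymin, xmax, ymax)`, a polygon given as a two-column matrix of
#'   vertices (x, y), the path to a GeoJSON file with a Polygon feature, or
#'   `NULL` to keep the union of the tile extents.
#' @return A single [reflectance_scene()] covering the intersection of the
#'   AOI with the union of tile extents.
#' @export
mosaic_clip <- function(tiles, aoi = NULL) {
  if (!length(tiles)) stop("no tiles to mosaic", call. = FALSE)
  lapply(tiles, function(t) stopifnot(inherits(t, "reflectance_scene")))
  g1 <- tiles[[1]]$geometry
  dates <- unique(vapply(tiles, function(t) format(t$date), ""))
  if (length(dates) != 1L) {
    stop("tiles carry mixed dates; mosaic one acquisition at a time",
         call. = FALSE)
  }
  for (t in tiles) {
    g <- t$geometry
    if (!identical(g$crs_id, g1$crs_id)) {
      stop("tiles carry mixed CRSs", call. = FALSE)
    }
    if (abs(g$pixel_size - g1$pixel_size) > 1e-9 * g1$pixel_size) {
      stop("tiles carry mixed pixel sizes", call. = FALSE)
    }
    off_x <- (g$origin_x - g1$origin_x) / g1$pixel_size
    off_y <- (g$origin_y - g1$origin_y) / g1$pixel_size
    if (abs(off_x - round(off_x)) > 1e-6 || abs(off_y - round(off_y)) > 1e-6) {
      stop("tiles are not aligned to a common lattice", call. = FALSE)
    }
  }

  poly <- NULL
  if (is.null(aoi)) {
    boxes <- lapply(tiles, function(t) geometry_bbox(t$geometry))
    bbox <- c(min(vapply(boxes, `[[`, 0, "xmin")),
              min(vapply(boxes, `[[`, 0, "ymin")),
              max(vapply(boxes, `[[`, 0, "xmax")),
              max(vapply(boxes, `[[`, 0, "ymax")))
  } else if (is.numeric(aoi) && is.null(dim(aoi)) && length(aoi) == 4L) {
    bbox <- as.numeric(aoi)
  } else {
    poly <- as_polygon(aoi)
    bbox <- c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
  }
  if (bbox[1] >= bbox[3] || bbox[2] >= bbox[4]) {
    stop("AOI bounding box is empty", call. = FALSE)
  }

  # snap the clipped extent to the tile lattice
  px <- g1$pixel_size
  col0 <- floor((bbox[1] - g1$origin_x) / px)
  col1 <- ceiling((bbox[3] - g1$origin_x) / px)
  row0 <- floor((g1$origin_y - bbox[4]) / px)
  row1 <- ceiling((g1$origin_y - bbox[2]) / px)
  out_geom <- grid_geometry(
    n_rows = row1 - row0, n_cols = col1 - col0,
    origin_x = g1$origin_x + col0 * px,
    origin_y = g1$origin_y - row0 * px,
    pixel_size = px, crs_id = g1$crs_id)

  red <- matrix(0L, out_geom$n_rows, out_geom$n_cols)
  nir <- matrix(0L, out_geom$n_rows, out_geom$n_cols)
  valid <- matrix(FALSE, out_geom$n_rows, out_geom$n_cols)

  any_overlap <- FALSE
  for (t in tiles) {
    g <- t$geometry
    dc <- as.integer(round((g$origin_x - out_geom$origin_x) / px))
    dr <- as.integer(round((out_geom$origin_y - g$origin_y) / px))
    rows <- intersect(seq_len(out_geom$n_rows), seq_len(g$n_rows) + dr)
    cols <- intersect(seq_len(out_geom$n_cols), seq_len(g$n_cols) + dc)
    if (!length(rows) || !length(cols)) next
    any_overlap <- TRUE
    src_rows <- rows - dr
    src_cols <- cols - dc
    # first valid value in input order wins: only fill still-invalid cells
    fill <- t$valid[src_rows, src_cols, drop = FALSE] &
      !valid[rows, cols, drop = FALSE]
    sub_red <- red[rows, cols, drop = FALSE]
    sub_nir <- nir[rows, cols, drop = FALSE]
    sub_red[fill] <- t$red[src_rows, src_cols, drop = FALSE][fill]
    sub_nir[fill] <- t$nir[src_rows, src_cols, drop = FALSE][fill]
    red[rows, cols] <- sub_red
    nir[rows, cols] <- sub_nir
    valid[rows, cols] <- valid[rows, cols, drop = FALSE] | fill
  }
  if (!any_overlap) {
    stop("AOI does not intersect any input tile", call. = FALSE)
  }

  if (!is.null(poly)) {
    xs <- geometry_col_centers(out_geom)
    ys <- geometry_row_centers(out_geom)
    inside <- outer(ys, xs, function(y, x) point_in_polygon(x, y, poly))
    valid <- valid & inside
  }

  reflectance_scene(red, nir, tiles[[1]]$date, valid, out_geom)
}

# accepts a 2-column vertex matrix or a GeoJSON file with a Polygon
as_polygon <- function(aoi) {
  if (is.matrix(aoi) && ncol(aoi) == 2L) return(aoi)
  if (is.character(aoi) && length(aoi) == 1L && file.exists(aoi)) {
    gj <- yaml::read_yaml(aoi)  # JSON is a YAML subset
    coords <- find_polygon_coords(gj)
    if (is.null(coords)) {
      stop("no Polygon geometry found in GeoJSON AOI", call. = FALSE)
    }
    ring <- coords[[1]]  # exterior ring
    return(do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2]))))
  }
  stop("AOI must be a bbox, a vertex matrix, or a GeoJSON polygon file",
       call. = FALSE)
}

find_polygon_coords <- function(x) {
  if (is.list(x)) {
    if (identical(x$type, "Polygon")) return(x$coordinates)
    for (el in x) {
      found <- if (is.list(el)) find_polygon_coords(el) else NULL
      if (!is.null(found)) return(found)
    }
  }
  NULL
}

# even-odd ray casting; vectorised over points
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  # drop a closing vertex equal to the first
  if (all(poly[n, ] == poly[1, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Maximum-value composite of daily NDVI grids
#'
#' Per-pixel maximum over the days on which the pixel holds a valid NDVI —
#' the classic MVC rule that suppresses cloud-, fog- and no-data-depressed
#' values within a 7- or 14-day window. A pixel is masked only when it is
#' masked on every day.
#'
#' @param dailies Non-empty list of co-registered [index_grid()] objects of
#'   kind `"NDVI"`.
#' @param period The enclosing [composite_period()] for the output. When
#'   `NULL`, the weekly (or, if the dates span two ISO weeks of one biweekly
#'   slot, biweekly) period containing all input dates is inferred.
#' @return An [index_grid()] of kind `"NDVI"` for the composite period. The
#'   number of contributing daily grids is recorded in attribute `"n_days"`
#'   so callers can enforce a completeness policy (operationally, weekly
#'   products are released once all days of the week are present).
#' @export
mvc <- function(dailies, period = NULL) {
  if (!length(dailies)) stop("mvc needs at least one daily grid",
                             call. = FALSE)
  g1 <- dailies[[1]]
  stopifnot(inherits(g1, "index_grid"))
  for (d in dailies) {
    stopifnot(inherits(d, "index_grid"), d$kind == "NDVI")
    stop_if_geometry_mismatch(g1$geometry, d$geometry, "daily NDVI grids")
  }
  if (is.null(period)) period <- infer_enclosing_period(dailies)
  if (!is.null(period)) {
    for (d in dailies) {
      if (!is.null(d$period) &&
          (d$period$start_date < period$start_date ||
           d$period$end_date > period$end_date)) {
        stop("daily grid dates fall outside the composite period",
             call. = FALSE)
      }
    }
  }
  acc <- dailies[[1]]$values
  for (d in dailies[-1]) {
    acc <- pmax(acc, d$values, na.rm = TRUE)
  }
  out <- index_grid(acc, "NDVI", period, g1$geometry)
  attr(out, "n_days") <- length(dailies)
  out
}

infer_enclosing_period <- function(dailies) {
  dates <- do.call(c, lapply(dailies, function(d) {
    if (is.null(d$period)) NULL else d$period$start_date
  }))
  if (is.null(dates) || !length(dates)) return(NULL)
  weekly <- period_of(min(dates), "weekly")
  if (max(dates) <= weekly$end_date) return(weekly)
  biweekly <- period_of(min(dates), "biweekly")
  if (max(dates) <= biweekly$end_date) return(biweekly)
  stop("daily grids span more than one composite period; pass `period`",
       call. = FALSE)
}
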