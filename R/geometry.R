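#' Raster grid geometry
#'
#' Describes the georeferencing of a north-up raster grid: its shape, the map
#' coordinates of the top-left corner of the top-left pixel, the (square)
#' pixel size in map units, and a CRS identifier. The operational products
#' this package models are 250 m grids, but any positive resolution is
#' accepted.
#'
#' @param n_rows,n_cols Grid shape (positive integers).
#' @param origin_x,origin_y Map coordinates of the top-left corner of the
#'   top-left pixel. `origin_y` is the *top* edge: row indices increase
#'   southward.
#' @param pixel_size Side length of a pixel in map units (positive).
#' @param crs_id Text identifier of the coordinate reference system,
#'   e.g. `"EPSG:4326"`. Carried through unchanged; no reprojection is done.
#'
#' @return An object of class `grid_geometry`.
#' @examples
#' grid_geometry(128, 128, origin_x = -100, origin_y = 40)
#' @export
grid_geometry <- function(n_rows, n_cols, origin_x = 0, origin_y = 0,
                          pixel_size = 1, crs_id = "EPSG:4326") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows <= 0L || n_cols <= 0L) {
    stop("n_rows and n_cols must be single positive integers", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single positive number", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size = as.numeric(pixel_size), crs_id = as.character(crs_id)),
    class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d px, pixel %g, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_id))
  invisible(x)
}

# bounding box (xmin, ymin, xmax, ymax) of the full grid extent
geometry_bbox <- function(geom) {
  c(xmin = geom$origin_x,
    ymin = geom$origin_y - geom$n_rows * geom$pixel_size,
    xmax = geom$origin_x + geom$n_cols * geom$pixel_size,
    ymax = geom$origin_y)
}

# x coordinate of column centers / y of row centers
geometry_col_centers <- function(geom) {
  geom$origin_x + (seq_len(geom$n_cols) - 0.5) * geom$pixel_size
}
geometry_row_centers <- function(geom) {
  geom$origin_y - (seq_len(geom$n_rows) - 0.5) * geom$pixel_size
}

#' Test whether two grids are co-registered
#'
#' Two geometries are co-registered when they have identical shape, origin,
#' pixel size and CRS; index math can then be applied cell-by-cell.
#'
#' @param a,b `grid_geometry` objects.
#' @param tol Numeric tolerance on origin/pixel-size comparison, as a fraction
#'   of the pixel size.
#' @return `TRUE` or `FALSE`.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  eps <- tol * a$pixel_size
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) < eps &&
    abs(a$origin_y - b$origin_y) < eps &&
    abs(a$pixel_size - b$pixel_size) < eps &&
    identical(a$crs_id, b$crs_id)
}

stop_if_geometry_mismatch <- function(a, b, what = "grids") {
  if (!same_geometry(a, b)) {
    stop(sprintf("%s are not co-registered (geometry mismatch)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}
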