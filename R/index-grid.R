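#' Floating-point index grid
#'
#' A per-pixel vegetation-index field. Masked (no-data) cells are stored as
#' `NA`; everything else carries a finite value in the kind's nominal range:
#' NDVI in \eqn{[-1, 1]}, VCI in \eqn{[0, 1]}, and the ratio indices
#' MVCI/RMVCI/RVCI in \eqn{[-1.25, 1.25]} after clamping.
#'
#' @param values Numeric matrix; `NA` marks no-data cells.
#' @param kind One of `"NDVI"`, `"VCI"`, `"MVCI"`, `"RMVCI"`, `"RVCI"`.
#' @param period A [composite_period()] or `NULL` (e.g. multi-year reference
#'   fields, which belong to a week-of-year rather than a dated period).
#' @param geometry A [grid_geometry()]; defaults to a unit grid.
#' @return An object of class `index_grid`.
#' @export
index_grid <- function(values, kind, period = NULL, geometry = NULL) {
  kind <- check_kind(kind)
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) {
    stop("index values must be finite or NA", call. = FALSE)
  }
  rng <- kind_range(kind)
  bad <- !is.na(values) & (values < rng[1] - 1e-9 | values > rng[2] + 1e-9)
  if (any(bad)) {
    stop(sprintf("%s values outside [%g, %g]; clamp before constructing",
                 kind, rng[1], rng[2]), call. = FALSE)
  }
  if (!is.null(period)) stopifnot(inherits(period, "composite_period"))
  if (is.null(geometry)) geometry <- grid_geometry(nrow(values), ncol(values))
  stopifnot(inherits(geometry, "grid_geometry"),
            geometry$n_rows == nrow(values), geometry$n_cols == ncol(values))
  structure(list(values = values, kind = kind, period = period,
                 geometry = geometry),
            class = "index_grid")
}

#' @export
print.index_grid <- function(x, ...) {
  per <- if (is.null(x$period)) "(no period)" else format(x$period)
  cat(sprintf("<index_grid> %s %s, %d x %d px, %d no-data\n", x$kind, per,
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

kind_range <- function(kind) {
  switch(kind,
         NDVI = c(-1, 1),
         VCI = c(0, 1),
         c(-1.25, 1.25))
}

#' Encoded 8-bit product grid
#'
#' The operational product representation: 8-bit unsigned values where
#' 0..250 encode the index and 255 is the no-data sentinel. Bytes 251..254
#' carry no meaning and are rejected.
#'
#' @param bytes Integer matrix with values in 0..250 or 255.
#' @inheritParams index_grid
#' @return An object of class `encoded_grid`.
#' @export
encoded_grid <- function(bytes, kind, period = NULL, geometry = NULL) {
  kind <- check_kind(kind)
  if (!is.matrix(bytes)) stop("bytes must be a matrix", call. = FALSE)
  storage.mode(bytes) <- "integer"
  if (any(is.na(bytes))) {
    stop("encoded grids have no NA; no-data is the byte 255", call. = FALSE)
  }
  bad <- bytes < 0L | (bytes > 250L & bytes != 255L)
  if (any(bad)) {
    stop("encoded bytes must lie in 0..250 or equal 255", call. = FALSE)
  }
  if (!is.null(period)) stopifnot(inherits(period, "composite_period"))
  if (is.null(geometry)) geometry <- grid_geometry(nrow(bytes), ncol(bytes))
  stopifnot(inherits(geometry, "grid_geometry"),
            geometry$n_rows == nrow(bytes), geometry$n_cols == ncol(bytes))
  structure(list(bytes = bytes, kind = kind, period = period,
                 geometry = geometry),
            class = "encoded_grid")
}

#' @export
print.encoded_grid <- function(x, ...) {
  per <- if (is.null(x$period)) "(no period)" else format(x$period)
  cat(sprintf("<encoded_grid> %s %s, %d x %d px, %d no-data (255)\n", x$kind,
              per, nrow(x$bytes), ncol(x$bytes), sum(x$bytes == 255L)))
  invisible(x)
}
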