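#' Read a RED/NIR reflectance scene from GeoTIFFs
#'
#' Loads two co-registered single-band 16-bit signed GeoTIFFs (the MOD09GQ
#' band convention) into a [reflectance_scene()]. Any other sample type is
#' rejected. Cells tagged no-data in either band start out invalid; range
#' screening is applied via [validate_reflectance()].
#'
#' @param red_path,nir_path Paths to the RED and NIR band rasters.
#' @param date Acquisition date.
#' @param validate Apply [validate_reflectance()] (default `TRUE`).
#' @return A [reflectance_scene()].
#' @export
read_scene <- function(red_path, nir_path, date, validate = TRUE) {
  red <- read_geotiff(red_path)
  nir <- read_geotiff(nir_path)
  for (b in list(red, nir)) {
    if (b$dtype != "int16") {
      stop("reflectance bands must be 16-bit signed integer rasters",
           call. = FALSE)
    }
  }
  if (!same_geometry(red$geometry, nir$geometry)) {
    stop("RED and NIR bands are not co-registered", call. = FALSE)
  }
  valid <- !is.na(red$values) & !is.na(nir$values)
  rv <- red$values; rv[is.na(rv)] <- 0L
  nv <- nir$values; nv[is.na(nv)] <- 0L
  scene <- reflectance_scene(rv, nv, date, valid, red$geometry)
  if (validate) scene <- validate_reflectance(scene)
  scene
}

#' Write a reflectance scene as two 16-bit GeoTIFFs
#'
#' Counterpart of [read_scene()], used mainly to materialise synthetic
#' scenes. Invalid cells are written as the no-data value -28672 (the
#' MOD09GQ band fill).
#'
#' @param scene A [reflectance_scene()].
#' @param red_path,nir_path Output paths.
#' @return A character vector of the two paths, invisibly.
#' @export
write_scene <- function(scene, red_path, nir_path) {
  stopifnot(inherits(scene, "reflectance_scene"))
  fill <- -28672L
  red <- scene$red; red[!scene$valid] <- NA_integer_
  nir <- scene$nir; nir[!scene$valid] <- NA_integer_
  write_geotiff(red, red_path, scene$geometry, "int16", nodata = fill)
  write_geotiff(nir, nir_path, scene$geometry, "int16", nodata = fill)
  invisible(c(red_path, nir_path))
}

#' Write an encoded product grid as an 8-bit GeoTIFF
#'
#' Products are single-band 8-bit unsigned GeoTIFFs with the no-data tag
#' 255 and the grid's georeferencing. When `path` is a directory the
#' filename is derived from the product's layer name
#' (`<layer_name>.tif`).
#'
#' @param e An [encoded_grid()].
#' @param path Output file path, or an existing directory.
#' @param method Multi-year method name when writing a reference field (see
#'   [layer_name()]).
#' @return The file path written, invisibly.
#' @export
write_product <- function(e, path, method = NULL) {
  stopifnot(inherits(e, "encoded_grid"))
  if (dir.exists(path)) {
    if (is.null(e$period)) {
      stop("grid carries no period; give a full file path", call. = FALSE)
    }
    path <- file.path(path, paste0(layer_name(e$kind, e$period, method),
                                   ".tif"))
  }
  write_geotiff(e$bytes, path, e$geometry, "uint8", nodata = 255L)
  invisible(path)
}

#' Read an encoded product GeoTIFF
#'
#' Reads an 8-bit product raster back into an [encoded_grid()]. Kind and
#' period are recovered from the filename when it follows the layer-naming
#' convention; otherwise pass `kind` explicitly. Bytes 251..254 are rejected
#' as corrupt.
#'
#' @param path Product file path.
#' @param kind Index kind override; default parses the filename.
#' @return An [encoded_grid()]; for multi-year reference files the method is
#'   attached as attribute `"method"`.
#' @export
read_product <- function(path, kind = NULL) {
  r <- read_geotiff(path)
  if (r$dtype != "uint8") {
    stop("product rasters are 8-bit unsigned", call. = FALSE)
  }
  bytes <- r$values
  bytes[is.na(bytes)] <- 255L  # no-data tag maps back to the sentinel
  meta <- NULL
  if (is.null(kind)) {
    base <- sub("\\.tif$", "", basename(path))
    meta <- tryCatch(parse_layer_name(base), error = function(e) NULL)
    if (is.null(meta)) {
      stop("cannot infer product kind from filename; pass `kind`",
           call. = FALSE)
    }
    kind <- meta$kind
  }
  period <- if (!is.null(meta) && !is.null(meta$period)) meta$period else NULL
  out <- encoded_grid(bytes, kind, period, r$geometry)
  if (!is.null(meta) && !is.null(meta$method)) {
    attr(out, "method") <- meta$method
    attr(out, "week") <- meta$week
  }
  out
}

#' Load a climatology stack from an archive of weekly NDVI products
#'
#' Reads every `NDVI-WEEKLY_*`/`NDVI-BIWEEKLY_*` product GeoTIFF in a
#' directory, decodes it, and builds the multi-year stack. Because the
#' archive is stored in the 8-bit product form, the per-year grids carry
#' quantized NDVI; derived fields are computed from those, exactly as the
#' operational archive does.
#'
#' @param dir Directory holding encoded composite products.
#' @param cadence `"weekly"` or `"biweekly"`.
#' @return A `climatology_stack`, or `NULL` when no matching files exist.
#' @export
climatology_from_dir <- function(dir, cadence = c("weekly", "biweekly")) {
  cadence <- match.arg(cadence)
  pattern <- sprintf("^NDVI-%s_\\d{4}_.*\\.tif$", toupper(cadence))
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) return(NULL)
  composites <- lapply(files, function(f) decode_grid(read_product(f)))
  climatology_build(composites)
}

#' Save a climatology stack as an archive of product GeoTIFFs
#'
#' Writes each per-year composite as an encoded `NDVI-WEEKLY`/`-BIWEEKLY`
#' product and each derived field as an `NDVI-MULTIYEAR-*` reference
#' product.
#'
#' @param stack A `climatology_stack`.
#' @param dir Output directory (created if needed).
#' @param derived Also write the min/max/mean/median reference fields.
#' @return The directory, invisibly.
#' @export
climatology_to_dir <- function(stack, dir, derived = TRUE) {
  stopifnot(inherits(stack, "climatology_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(stack$weeks)) {
    slot <- stack$weeks[[k]]
    for (yr in names(slot)) {
      per <- make_slot_period(as.integer(yr), k, stack$cadence)
      g <- index_grid(slot[[yr]], "NDVI", per, stack$geometry)
      write_product(encode_grid(g), dir)
    }
    if (derived && !is.null(stack$derived[[k]])) {
      # carrier period for the cadence/week only (2020 has all 53 ISO weeks)
      per <- make_slot_period(2020L, k, stack$cadence)
      for (m in names(stack$derived[[k]])) {
        g <- index_grid(stack$derived[[k]][[m]], "NDVI", per,
                        stack$geometry)
        write_product(encode_grid(g), dir, method = toupper(m))
      }
    }
  }
  invisible(dir)
}
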