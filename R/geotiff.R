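# Minimal single-band GeoTIFF I/O.
#
# Only what the product chain needs: baseline TIFF, little-endian,
# uncompressed, one sample per pixel, 8-bit unsigned or 16-bit signed, one
# strip, with the GeoTIFF ModelPixelScale/ModelTiepoint tags, a minimal
# GeoKey directory, the GDAL_NODATA convention for the no-data value, and
# the CRS identifier mirrored in ImageDescription. Files are readable by
# GDAL-based tools and by libtiff.

TAG_IMAGE_WIDTH <- 256L
TAG_IMAGE_LENGTH <- 257L
TAG_BITS_PER_SAMPLE <- 258L
TAG_COMPRESSION <- 259L
TAG_PHOTOMETRIC <- 262L
TAG_IMAGE_DESCRIPTION <- 270L
TAG_STRIP_OFFSETS <- 273L
TAG_SAMPLES_PER_PIXEL <- 277L
TAG_ROWS_PER_STRIP <- 278L
TAG_STRIP_BYTE_COUNTS <- 279L
TAG_SAMPLE_FORMAT <- 339L
TAG_MODEL_PIXEL_SCALE <- 33550L
TAG_MODEL_TIEPOINT <- 33922L
TAG_GEO_KEY_DIRECTORY <- 34735L
TAG_GDAL_NODATA <- 42113L

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
# 1 BYTE, 2 ASCII, 3 SHORT, 4 LONG, 12 DOUBLE

#' Write a single-band GeoTIFF
#'
#' Writes `values` as an uncompressed single-band GeoTIFF, either 8-bit
#' unsigned (`dtype = "uint8"`) or 16-bit signed (`dtype = "int16"`).
#' Georeferencing is stored via the ModelPixelScale and ModelTiepoint tags
#' plus a minimal GeoKey directory (an `"EPSG:<code>"` `crs_id` is encoded
#' as the corresponding geographic or projected CRS key; any identifier is
#' also mirrored verbatim in ImageDescription). `nodata`, if given, is
#' recorded with the GDAL no-data convention and `NA` cells are written as
#' that value.
#'
#' @param values Integer matrix (row 1 = northernmost row).
#' @param path Output file path.
#' @param geometry A [grid_geometry()] matching `values`.
#' @param dtype `"uint8"` or `"int16"`.
#' @param nodata Optional no-data value to tag and substitute for `NA`.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(values, path, geometry = NULL,
                          dtype = c("uint8", "int16"), nodata = NULL) {
  dtype <- match.arg(dtype)
  stopifnot(is.matrix(values))
  if (is.null(geometry)) geometry <- grid_geometry(nrow(values), ncol(values))
  stopifnot(geometry$n_rows == nrow(values),
            geometry$n_cols == ncol(values))
  v <- as.vector(t(values))  # TIFF stores rows contiguously
  if (!is.null(nodata)) v[is.na(v)] <- nodata
  if (anyNA(v)) stop("NA cells present but no `nodata` value given",
                     call. = FALSE)
  v <- as.integer(v)
  lim <- if (dtype == "uint8") c(0L, 255L) else c(-32768L, 32767L)
  if (any(v < lim[1] | v > lim[2])) {
    stop(sprintf("values outside the %s range", dtype), call. = FALSE)
  }

  bits <- if (dtype == "uint8") 8L else 16L
  sample_format <- if (dtype == "uint8") 1L else 2L
  n_data_bytes <- length(v) * (bits %/% 8L)

  entries <- list()
  extra <- list()  # deferred out-of-line values: list(bytes = raw)
  add <- function(tag, type, values_num = NULL, raw_bytes = NULL) {
    entries[[length(entries) + 1L]] <<- list(tag = tag, type = type,
                                             values = values_num,
                                             raw = raw_bytes)
  }
  ascii <- function(s) c(charToRaw(s), as.raw(0L))

  add(TAG_IMAGE_WIDTH, 4L, geometry$n_cols)
  add(TAG_IMAGE_LENGTH, 4L, geometry$n_rows)
  add(TAG_BITS_PER_SAMPLE, 3L, bits)
  add(TAG_COMPRESSION, 3L, 1L)
  add(TAG_PHOTOMETRIC, 3L, 1L)
  add(TAG_IMAGE_DESCRIPTION, 2L, raw_bytes = ascii(geometry$crs_id))
  add(TAG_STRIP_OFFSETS, 4L, 8L)  # data starts right after the header
  add(TAG_SAMPLES_PER_PIXEL, 3L, 1L)
  add(TAG_ROWS_PER_STRIP, 4L, geometry$n_rows)
  add(TAG_STRIP_BYTE_COUNTS, 4L, n_data_bytes)
  add(TAG_SAMPLE_FORMAT, 3L, sample_format)
  add(TAG_MODEL_PIXEL_SCALE, 12L,
      c(geometry$pixel_size, geometry$pixel_size, 0))
  add(TAG_MODEL_TIEPOINT, 12L,
      c(0, 0, 0, geometry$origin_x, geometry$origin_y, 0))
  add(TAG_GEO_KEY_DIRECTORY, 3L, geo_key_directory(geometry$crs_id))
  if (!is.null(nodata)) {
    add(TAG_GDAL_NODATA, 2L, raw_bytes = ascii(as.character(nodata)))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  w8 <- function(x) writeBin(as.raw(x), con)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")

  # header: II, 42, IFD offset (after header + pixel data)
  ifd_offset <- 8L + n_data_bytes
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifd_offset)

  if (dtype == "uint8") w8(v) else w16(v)

  # lay out the IFD and its out-of-line value area
  n_entries <- length(entries)
  value_area <- ifd_offset + 2L + 12L * n_entries + 4L
  payloads <- list()
  cursor <- value_area
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    bytes <- if (!is.null(e$raw)) e$raw else encode_tiff_values(e)
    count <- if (!is.null(e$raw)) length(e$raw) else length(e$values)
    entries[[i]]$count <- count
    if (length(bytes) <= 4L) {
      entries[[i]]$inline <- c(bytes, rep(as.raw(0L), 4L - length(bytes)))
      entries[[i]]$offset <- NA_integer_
    } else {
      entries[[i]]$offset <- cursor
      payloads[[length(payloads) + 1L]] <- bytes
      cursor <- cursor + length(bytes)
      if (length(bytes) %% 2L == 1L) {  # keep offsets word-aligned
        payloads[[length(payloads)]] <- c(bytes, as.raw(0L))
        cursor <- cursor + 1L
      }
    }
  }

  w16(n_entries)
  for (e in entries) {
    w16(e$tag)
    w16(e$type)
    w32(e$count)
    if (is.na(e$offset)) writeBin(e$inline, con) else w32(e$offset)
  }
  w32(0L)  # no next IFD
  for (p in payloads) writeBin(p, con)
  invisible(path)
}

# little-endian byte encoding of an IFD entry's value list
encode_tiff_values <- function(e) {
  sz <- TIFF_TYPE_SIZES[[as.character(e$type)]]
  vals <- e$values
  if (e$type == 12L) {
    out <- writeBin(as.double(vals), raw(), size = 8L, endian = "little")
  } else {
    out <- writeBin(as.integer(vals), raw(), size = 4L, endian = "little")
    if (sz < 4L) {
      keep <- as.vector(outer(seq_len(sz), (seq_along(vals) - 1L) * 4L, `+`))
      out <- out[keep]
    }
  }
  out
}

# minimal GeoKey directory: model type, pixel-is-area, CRS code when the
# identifier is "EPSG:<code>"
geo_key_directory <- function(crs_id) {
  keys <- list(c(1025L, 0L, 1L, 1L))  # GTRasterTypeGeoKey = PixelIsArea
  code <- suppressWarnings(
    as.integer(sub("^EPSG:", "", crs_id, ignore.case = TRUE)))
  if (!is.na(code) && grepl("^EPSG:", crs_id, ignore.case = TRUE)) {
    if (code == 4326L || (code >= 4000L && code < 5000L)) {
      keys <- c(list(c(1024L, 0L, 1L, 2L)), keys,
                list(c(2048L, 0L, 1L, code)))  # geographic
    } else {
      keys <- c(list(c(1024L, 0L, 1L, 1L)), keys,
                list(c(3072L, 0L, 1L, code)))  # projected
    }
  } else {
    keys <- c(list(c(1024L, 0L, 1L, 0L)), keys)
  }
  keys <- keys[order(vapply(keys, `[`, 0L, 1L))]
  c(1L, 1L, 0L, length(keys), unlist(keys))
}

#' Read a single-band GeoTIFF written by this package (or compatible)
#'
#' Supports uncompressed little- or big-endian baseline TIFFs with one
#' 8-bit-unsigned or 16-bit-signed band. Returns the pixel matrix along with
#' the geometry reconstructed from the GeoTIFF tags and the GDAL no-data
#' value if tagged (no-data cells are returned as `NA`).
#'
#' @param path File path.
#' @return A list with elements `values` (integer matrix, `NA` at no-data
#'   cells), `geometry` ([grid_geometry()]), `dtype` and `nodata`.
#' @export
read_geotiff <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8L) stop("not a TIFF file", call. = FALSE)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file", call. = FALSE))
  rint <- function(at, size, n = 1L, signed = TRUE) {
    readBin(raw_all[at:(at + size * n - 1L)], "integer", n = n, size = size,
            signed = signed || size == 4L, endian = endian)
  }
  rdouble <- function(at, n) {
    readBin(raw_all[at:(at + 8L * n - 1L)], "double", n = n, size = 8L,
            endian = endian)
  }
  if (rint(3L, 2L, signed = FALSE) != 42L) {
    stop("not a TIFF file", call. = FALSE)
  }
  ifd <- rint(5L, 4L)
  n_entries <- rint(ifd + 1L, 2L, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    at <- ifd + 3L + (i - 1L) * 12L
    tag <- rint(at, 2L, signed = FALSE)
    type <- rint(at + 2L, 2L, signed = FALSE)
    count <- rint(at + 4L, 4L)
    sz <- TIFF_TYPE_SIZES[as.character(type)]
    if (is.na(sz)) next
    total <- sz * count
    val_at <- if (total <= 4L) at + 8L else rint(at + 8L, 4L) + 1L
    vals <- if (type == 12L) {
      rdouble(val_at, count)
    } else if (type == 2L) {
      rawToChar(raw_all[val_at:(val_at + count - 2L)])
    } else {
      rint(val_at, sz, n = count, signed = FALSE)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop(sprintf("TIFF tag %d missing", tag), call. = FALSE)
    v
  }
  width <- need(TAG_IMAGE_WIDTH)
  height <- need(TAG_IMAGE_LENGTH)
  bits <- need(TAG_BITS_PER_SAMPLE)
  comp <- tags[[as.character(TAG_COMPRESSION)]]
  if (!is.null(comp) && comp != 1L) {
    stop("only uncompressed TIFFs are supported", call. = FALSE)
  }
  spp <- tags[[as.character(TAG_SAMPLES_PER_PIXEL)]]
  if (!is.null(spp) && spp != 1L) {
    stop("only single-band TIFFs are supported", call. = FALSE)
  }
  fmt <- tags[[as.character(TAG_SAMPLE_FORMAT)]]
  if (is.null(fmt)) fmt <- 1L
  dtype <- if (bits == 8L && fmt == 1L) "uint8"
  else if (bits == 16L && fmt == 2L) "int16"
  else stop(sprintf("unsupported sample layout: %d-bit format %d", bits, fmt),
            call. = FALSE)

  offsets <- need(TAG_STRIP_OFFSETS)
  counts <- need(TAG_STRIP_BYTE_COUNTS)
  data_raw <- do.call(c, lapply(seq_along(offsets), function(i) {
    raw_all[(offsets[i] + 1L):(offsets[i] + counts[i])]
  }))
  v <- if (dtype == "uint8") {
    as.integer(data_raw)
  } else {
    readBin(data_raw, "integer", n = length(data_raw) %/% 2L, size = 2L,
            signed = TRUE, endian = endian)
  }
  values <- matrix(v, height, width, byrow = TRUE)

  scale <- tags[[as.character(TAG_MODEL_PIXEL_SCALE)]]
  tie <- tags[[as.character(TAG_MODEL_TIEPOINT)]]
  px <- if (!is.null(scale)) scale[1] else 1
  ox <- if (!is.null(tie)) tie[4] else 0
  oy <- if (!is.null(tie)) tie[5] else height * px
  crs_id <- tags[[as.character(TAG_IMAGE_DESCRIPTION)]]
  if (is.null(crs_id)) {
    gk <- tags[[as.character(TAG_GEO_KEY_DIRECTORY)]]
    crs_id <- geo_keys_to_crs(gk)
  }
  geometry <- grid_geometry(height, width, ox, oy, px, crs_id)

  nodata <- tags[[as.character(TAG_GDAL_NODATA)]]
  if (!is.null(nodata)) {
    nodata <- as.numeric(trimws(nodata))
    values[values == nodata] <- NA_integer_
  }
  list(values = values, geometry = geometry, dtype = dtype, nodata = nodata)
}

geo_keys_to_crs <- function(gk) {
  if (is.null(gk) || length(gk) < 4L) return("unknown")
  n <- gk[4]
  for (k in seq_len(n)) {
    key <- gk[4L * k + 1L]
    if (key %in% c(2048L, 3072L)) {
      return(sprintf("EPSG:%d", gk[4L * k + 4L]))
    }
  }
  "unknown"
}
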