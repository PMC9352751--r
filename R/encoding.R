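#' 8-bit product encodings
#'
#' The operational products store every index as an 8-bit unsigned integer in
#' \[0, 250\] with 255 as the no-data sentinel. Three affine transforms are
#' used:
#' \describe{
#'   \item{NDVI}{`byte = round(v * 125 + 125)`, mapping \[-1, 1\] to \[0, 250\].}
#'   \item{VCI}{`byte = round(v * 250)`, mapping \[0, 1\] to \[0, 250\].}
#'   \item{MVCI / RMVCI / RVCI}{piecewise: 0 when `v <= -1.25`, 250 when
#'     `v >= 1.25`, else `round(v * 100 + 125)` — the ratio is saturated at
#'     an absolute value of 125\%.}
#' }
#' Rounding is to the nearest integer with ties away from zero, so the
#' decoded centre of each bin is unbiased. Inputs are clamped to the kind's
#' nominal range before scaling, which keeps the byte range exactly
#' \[0, 250\]; bytes 251..254 are never produced.
#'
#' @param v Numeric vector of index values. `NA` is not accepted here — mask
#'   handling lives in [encode_grid()].
#' @return Integer vector of bytes in 0..250.
#' @examples
#' encode_ndvi(c(-1, 0, 1))   # 0 125 250
#' encode_vci(c(0, 0.5, 1))   # 0 125 250
#' encode_ratio(c(-2, 0, 1.25))  # 0 125 250
#' @name product-encoding
NULL

# nearest integer, ties away from zero (round() rounds half to even)
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

check_finite <- function(v, what) {
  if (!is.numeric(v) || any(!is.finite(v))) {
    stop(sprintf("%s requires finite numeric input", what), call. = FALSE)
  }
  invisible(v)
}

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

#' @rdname product-encoding
#' @export
encode_ndvi <- function(v) {
  check_finite(v, "encode_ndvi")
  as.integer(round_half_away(clamp(v, -1, 1) * 125 + 125))
}

#' @rdname product-encoding
#' @export
encode_vci <- function(v) {
  check_finite(v, "encode_vci")
  as.integer(round_half_away(clamp(v, 0, 1) * 250))
}

#' @rdname product-encoding
#' @export
encode_ratio <- function(v) {
  check_finite(v, "encode_ratio")
  out <- round_half_away(clamp(v, -1.25, 1.25) * 100 + 125)
  out[v <= -1.25] <- 0
  out[v >= 1.25] <- 250
  as.integer(out)
}

encoder_for <- function(kind) {
  switch(kind, NDVI = encode_ndvi, VCI = encode_vci, encode_ratio)
}

#' Decode product bytes back to index values
#'
#' Inverse of the affine encodings: byte 255 decodes to `NA` (no data) and
#' bytes 251..254 raise a corrupt-product error. For the ratio kinds the
#' saturated bytes 0 and 250 decode to -1.25 and +1.25 — values beyond the
#' saturation limit are not recoverable.
#'
#' @param byte Integer vector with values in 0..250 or 255.
#' @param kind Index kind (see [index_grid()]).
#' @return Numeric vector of index values, `NA` where `byte == 255`.
#' @export
decode_value <- function(byte, kind) {
  kind <- check_kind(kind)
  byte <- as.integer(byte)
  if (any(is.na(byte))) stop("bytes must not be NA", call. = FALSE)
  if (any(byte < 0L | byte > 255L)) {
    stop("bytes must lie in 0..255", call. = FALSE)
  }
  if (any(byte >= 251L & byte <= 254L)) {
    stop("corrupt product: bytes 251..254 are not valid encodings",
         call. = FALSE)
  }
  out <- switch(kind,
                NDVI = (byte - 125) / 125,
                VCI  = byte / 250,
                (byte - 125) / 100)
  out[byte == 255L] <- NA_real_
  out
}

#' Encode an index grid to the 8-bit product form
#'
#' Element-wise application of the kind's transform; masked (`NA`) cells
#' become the no-data byte 255.
#'
#' @param g An [index_grid()].
#' @return An [encoded_grid()] with the same kind, period and geometry.
#' @export
encode_grid <- function(g) {
  stopifnot(inherits(g, "index_grid"))
  enc <- encoder_for(g$kind)
  bytes <- matrix(255L, nrow(g$values), ncol(g$values))
  ok <- !is.na(g$values)
  bytes[ok] <- enc(g$values[ok])
  encoded_grid(bytes, g$kind, g$period, g$geometry)
}

#' Decode an 8-bit product grid to index values
#'
#' @param e An [encoded_grid()].
#' @return An [index_grid()]; byte 255 becomes `NA`.
#' @export
decode_grid <- function(e) {
  stopifnot(inherits(e, "encoded_grid"))
  vals <- matrix(decode_value(as.vector(e$bytes), e$kind),
                 nrow(e$bytes), ncol(e$bytes))
  index_grid(vals, e$kind, e$period, e$geometry)
}
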