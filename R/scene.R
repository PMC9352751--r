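#' Dated RED/NIR surface-reflectance scene
#'
#' Bundles the two MOD09GQ-convention reflectance bands of one acquisition:
#' integer digital numbers where the physically valid range is
#' \eqn{[-100, 16000]} (reflectance scaled by 10000, with slightly negative
#' values admitted by atmospheric correction), a logical validity mask, the
#' acquisition date and the grid geometry.
#'
#' @param red,nir Integer matrices of identical shape (digital numbers).
#' @param date Acquisition date (`Date` or coercible).
#' @param valid Logical matrix, `TRUE` where the pixel holds a usable
#'   observation. Defaults to all `TRUE`.
#' @param geometry A [grid_geometry()]; defaults to a unit grid of the band
#'   shape.
#'
#' @return An object of class `reflectance_scene`.
#' @seealso [validate_reflectance()], [ndvi()]
#' @examples
#' s <- reflectance_scene(red = matrix(2000L, 2, 2), nir = matrix(6000L, 2, 2),
#'                        date = "2021-06-07")
#' @export
reflectance_scene <- function(red, nir, date, valid = NULL, geometry = NULL) {
  if (!is.matrix(red) || !is.matrix(nir)) {
    stop("red and nir must be matrices", call. = FALSE)
  }
  if (!identical(dim(red), dim(nir))) {
    stop("red and nir bands differ in shape", call. = FALSE)
  }
  storage.mode(red) <- "integer"
  storage.mode(nir) <- "integer"
  if (is.null(valid)) valid <- matrix(TRUE, nrow(red), ncol(red))
  if (!is.logical(valid) || !identical(dim(valid), dim(red))) {
    stop("valid mask must be a logical matrix matching the band shape",
         call. = FALSE)
  }
  valid[is.na(valid)] <- FALSE
  # NA digital numbers never count as observations
  valid <- valid & !is.na(red) & !is.na(nir)
  if (is.null(geometry)) geometry <- grid_geometry(nrow(red), ncol(red))
  stopifnot(inherits(geometry, "grid_geometry"),
            geometry$n_rows == nrow(red), geometry$n_cols == ncol(red))
  structure(
    list(red = red, nir = nir, valid = valid,
         date = as.Date(date), geometry = geometry),
    class = "reflectance_scene")
}

#' @export
print.reflectance_scene <- function(x, ...) {
  cat(sprintf("<reflectance_scene> %s, %d x %d px, %d valid (%.1f%%)\n",
              format(x$date), nrow(x$red), ncol(x$red), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Mask reflectance values outside the valid sensor range
#'
#' Restricts the scene's validity mask to pixels where both bands fall inside
#' the valid digital-number range \eqn{[-100, 16000]}. The mask only ever
#' shrinks (a pixel already flagged invalid stays invalid) and the band
#' values themselves are untouched.
#'
#' @param scene A [reflectance_scene()].
#' @return The scene with its `valid` mask intersected with the range check.
#' @export
validate_reflectance <- function(scene) {
  stopifnot(inherits(scene, "reflectance_scene"))
  in_range <- !is.na(scene$red) & !is.na(scene$nir) &
    scene$red >= REFLECTANCE_MIN & scene$red <= REFLECTANCE_MAX &
    scene$nir >= REFLECTANCE_MIN & scene$nir <= REFLECTANCE_MAX
  scene$valid <- scene$valid & in_range
  scene
}

REFLECTANCE_MIN <- -100L
REFLECTANCE_MAX <- 16000L
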