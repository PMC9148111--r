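#' Fisheye camera intrinsics for the equidistant projection model
#'
#' Bundles the composite per-axis distortion coefficients of an
#' equidistant-projection fisheye lens with its principal point and virtual
#' imaging distance. Under this model a world point at incident angle `w`
#' (radians off the optical axis) images at a radial pixel offset proportional
#' to `w`; `kx` and `ky` are the proportionality constants (pixels per radian)
#' along the image column and row axes. They absorb the focal length,
#' per-axis distortion factors and sensor magnification into a single
#' calibratable number per axis.
#'
#' @param kx,ky Composite distortion coefficients, pixels per radian; must be
#'   positive. Typically obtained from [calibrate()].
#' @param u0,v0 Principal point (pixel column / row where the optical axis
#'   meets the sensor). Continuous, sub-pixel values allowed.
#' @param l Virtual imaging distance of the lens, in the same length unit as
#'   the world coordinates; added to the measured camera-to-target distance
#'   `h` to form the model distance `L = h + l`. Defaults to 0 (unknown).
#' @param units Free-text label for the length unit (e.g. `"mm"`, `"m"`);
#'   purely informational.
#'
#' @return An object of class `"fisheye_intrinsics"`.
#' @seealso [project_to_pixel()], [backproject_to_world()], [calibrate()],
#'   [write_intrinsics()]
#' @examples
#' cam <- fisheye_intrinsics(kx = 1000, ky = 1000, u0 = 320, v0 = 320)
#' cam
#' @export
fisheye_intrinsics <- function(kx, ky, u0, v0, l = 0, units = "mm") {
  check_number(kx, "kx", positive = TRUE)
  check_number(ky, "ky", positive = TRUE)
  check_number(u0, "u0")
  check_number(v0, "v0")
  check_number(l, "l")
  if (l < 0) {
    stop_fisheye("`l` must be >= 0", "fisheyetree_invalid_argument")
  }
  structure(
    list(kx = as.numeric(kx), ky = as.numeric(ky),
         u0 = as.numeric(u0), v0 = as.numeric(v0),
         l = as.numeric(l), units = as.character(units)[1L]),
    class = "fisheye_intrinsics"
  )
}

#' @export
print.fisheye_intrinsics <- function(x, ...) {
  cat("Fisheye intrinsics (equidistant projection)\n")
  cat(sprintf("  kx = %.6g px/rad, ky = %.6g px/rad\n", x$kx, x$ky))
  cat(sprintf("  principal point (u0, v0) = (%.4g, %.4g) px\n", x$u0, x$v0))
  cat(sprintf("  virtual imaging distance l = %.6g %s\n", x$l, x$units))
  invisible(x)
}

assert_intrinsics <- function(cam) {
  if (!inherits(cam, "fisheye_intrinsics")) {
    stop_fisheye("`cam` must be a fisheye_intrinsics object",
                 "fisheyetree_invalid_argument")
  }
  invisible(cam)
}

#' Read and write calibration parameter files
#'
#' Calibration parameters serialize to a flat JSON document with keys
#' `kx`, `ky`, `u0`, `v0`, `l`, `units` and `created` (ISO-8601 timestamp).
#' The field names are fixed so files interoperate with other tools.
#'
#' @param cam A [fisheye_intrinsics()] object.
#' @param path File path of the JSON document.
#' @return `write_intrinsics()` returns `path` invisibly; `read_intrinsics()`
#'   returns a `fisheye_intrinsics` object.
#' @export
write_intrinsics <- function(cam, path) {
  assert_intrinsics(cam)
  doc <- list(kx = cam$kx, ky = cam$ky, u0 = cam$u0, v0 = cam$v0,
              l = cam$l, units = cam$units,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intrinsics
#' @export
read_intrinsics <- function(path) {
  if (!file.exists(path)) {
    stop_fisheye(sprintf("calibration file not found: %s", path),
                 "fisheyetree_missing_file")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("kx", "ky", "u0", "v0")
  if (!all(needed %in% names(doc))) {
    stop_fisheye(sprintf("calibration JSON must contain keys %s",
                         paste(needed, collapse = ", ")),
                 "fisheyetree_invalid_argument")
  }
  fisheye_intrinsics(kx = doc$kx, ky = doc$ky, u0 = doc$u0, v0 = doc$v0,
                     l = if (is.null(doc$l)) 0 else doc$l,
                     units = if (is.null(doc$units)) "mm" else doc$units)
}
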