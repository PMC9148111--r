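#' Incident angle of a world point
#'
#' Angle between the ray to a point in the fronto-parallel target plane and
#' the optical axis: `atan(sqrt(xw^2 + yw^2) / L)`.
#'
#' @param xw,yw World coordinates of the point in the target plane
#'   (any consistent length unit); vectorized.
#' @param L Horizontal distance from the lens to the target plane
#'   (same unit); must be positive.
#' @return Incident angle(s) in radians, in `[0, pi/2)`.
#' @examples
#' incident_angle(300, 400, 1000)  # atan(0.5)
#' @export
incident_angle <- function(xw, yw, L) {
  check_number(L, "L", positive = TRUE)
  atan(sqrt(xw^2 + yw^2) / L)
}

#' Forward fisheye projection: world plane to pixel coordinates
#'
#' Equidistant projection of points in a fronto-parallel plane at distance
#' `L` onto the image:
#' `u = u0 + kx * (xw/r) * atan(r/L)`, `v = v0 + ky * (yw/r) * atan(r/L)`
#' with `r = sqrt(xw^2 + yw^2)`. The on-axis point (`r = 0`) maps exactly to
#' the principal point (continuous limit).
#'
#' Pixel convention: origin at the image top-left, `u` = column increasing
#' rightward, `v` = row increasing downward, continuous sub-pixel values.
#' World `yw` increases in the same sense as `v` (downward in the image).
#'
#' @inheritParams incident_angle
#' @param cam A [fisheye_intrinsics()] object.
#' @return A data frame with columns `u`, `v` (pixels), one row per point.
#' @examples
#' cam <- fisheye_intrinsics(1000, 1000, 0, 0)
#' project_to_pixel(300, 400, L = 1000, cam = cam)
#' @export
project_to_pixel <- function(xw, yw, L, cam) {
  check_number(L, "L", positive = TRUE)
  assert_intrinsics(cam)
  n <- max(length(xw), length(yw))
  xw <- rep_len(as.numeric(xw), n)
  yw <- rep_len(as.numeric(yw), n)
  r <- sqrt(xw^2 + yw^2)
  # atan(r/L)/r -> 1/L as r -> 0, so the principal point is hit exactly
  s <- ifelse(r > 0, atan(r / L) / r, 1 / L)
  data.frame(u = cam$u0 + cam$kx * xw * s,
             v = cam$v0 + cam$ky * yw * s)
}

#' Inverse fisheye projection: pixel to world-plane coordinates
#'
#' Closed-form inverse of [project_to_pixel()]. Writing
#' `a = (u - u0)/kx`, `b = (v - v0)/ky`, the incident angle implied by the
#' pixel is `theta = sqrt(a^2 + b^2)` and the world point is
#' `xw = (a/theta) * L * tan(theta)`, `yw = (b/theta) * L * tan(theta)`
#' (with the continuous limit `(0, 0)` at the principal point). The azimuth
#' of the pixel offset is preserved exactly.
#'
#' @param u,v Pixel coordinates (continuous; out-of-frame values allowed);
#'   vectorized.
#' @inheritParams project_to_pixel
#' @return A data frame with columns `xw`, `yw` (length units of `L`).
#' @section Errors: pixels whose implied incident angle reaches `pi/2`
#'   (rays parallel to or behind the image plane) raise an out-of-field
#'   error of class `"fisheyetree_out_of_field"`.
#' @examples
#' cam <- fisheye_intrinsics(1000, 1000, 0, 0)
#' backproject_to_world(278.1886, 370.9181, L = 1000, cam = cam)
#' @export
backproject_to_world <- function(u, v, L, cam) {
  check_number(L, "L", positive = TRUE)
  assert_intrinsics(cam)
  n <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), n)
  v <- rep_len(as.numeric(v), n)
  a <- (u - cam$u0) / cam$kx
  b <- (v - cam$v0) / cam$ky
  theta <- sqrt(a^2 + b^2)
  bad <- which(theta >= pi / 2)
  if (length(bad) > 0L) {
    stop_fisheye(
      sprintf(paste0("pixel (%.4g, %.4g) implies incident angle %.4g rad ",
                     ">= pi/2: outside the field of view"),
              u[bad[1L]], v[bad[1L]], theta[bad[1L]]),
      "fisheyetree_out_of_field")
  }
  s <- ifelse(theta > 0, L * tan(theta) / theta, L)
  data.frame(xw = a * s, yw = b * s)
}

#' Euclidean distance between two points in the target plane
#'
#' The final height/distance statistic of the measurement model: the planar
#' Euclidean distance between two back-projected world points, e.g. the tree
#' top and base.
#'
#' @param x1,y1,x2,y2 World coordinates of the two points; vectorized.
#' @return Distance(s), same unit as the inputs.
#' @examples
#' planar_distance(-285.0330, -375.9156, -300.6751, 280.2142)
#' @export
planar_distance <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Model distance from measured distance
#'
#' The model distance used by projection is `L = h + l`, where `h` is the
#' measured horizontal distance from the camera to the target plane and `l`
#' the lens's virtual imaging distance stored in the intrinsics.
#'
#' @param h Measured horizontal distance; must be positive.
#' @inheritParams project_to_pixel
#' @return `h + cam$l`.
#' @export
horizontal_distance <- function(h, cam) {
  check_number(h, "h", positive = TRUE)
  assert_intrinsics(cam)
  h + cam$l
}
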