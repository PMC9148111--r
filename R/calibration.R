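#' Per-corner distortion-coefficient estimates
#'
#' Inverts the forward projection for a single checkerboard corner whose
#' pixel position, board-plane world position and board distance are known:
#' `kx = (u - u0) / [(xw/r) * atan(r/L)]` and symmetrically for `ky`.
#' An axis whose direction cosine `|xw|/r` (resp. `|yw|/r`) falls below
#' `min_axis_ratio` is too close to perpendicular to carry information about
#' that coefficient; its estimate is returned as `NA` rather than an
#' ill-conditioned number.
#'
#' @param corners A data frame of corner correspondences with columns
#'   `u`, `v` (pixels), `xw`, `yw` (board-plane world coordinates) and `L`
#'   (board distance, per corner).
#' @param principal Principal point as a length-2 numeric `c(u0, v0)`.
#' @param min_axis_ratio Conditioning threshold on `|xw|/r` and `|yw|/r`
#'   below which the axis estimate is suppressed (default 0.05).
#' @return A data frame with columns `kx`, `ky` (NA where suppressed), one
#'   row per corner.
#' @section Errors: a corner exactly on the optical axis (`r = 0`) carries no
#'   angular information and raises `"fisheyetree_degenerate_corner"`.
#' @examples
#' corners <- data.frame(u = 278.1886, v = 370.9181,
#'                       xw = 300, yw = 400, L = 1000)
#' per_corner_coefficients(corners, principal = c(0, 0))
#' @export
per_corner_coefficients <- function(corners, principal,
                                    min_axis_ratio = 0.05) {
  corners <- as.data.frame(corners)
  needed <- c("u", "v", "xw", "yw", "L")
  if (!all(needed %in% names(corners))) {
    stop_fisheye(sprintf("`corners` must have columns %s",
                         paste(needed, collapse = ", ")),
                 "fisheyetree_invalid_argument")
  }
  if (any(!is.finite(corners$L)) || any(corners$L <= 0)) {
    stop_fisheye("all corner distances `L` must be positive",
                 "fisheyetree_invalid_argument")
  }
  u0 <- principal[[1L]]
  v0 <- principal[[2L]]
  r <- sqrt(corners$xw^2 + corners$yw^2)
  if (any(r == 0)) {
    stop_fisheye(sprintf(
      "corner %d lies on the optical axis (xw = yw = 0): degenerate",
      which(r == 0)[1L]), "fisheyetree_degenerate_corner")
  }
  theta <- atan(r / corners$L)
  kx <- ifelse(abs(corners$xw) / r >= min_axis_ratio,
               (corners$u - u0) / (corners$xw / r * theta), NA_real_)
  ky <- ifelse(abs(corners$yw) / r >= min_axis_ratio,
               (corners$v - v0) / (corners$yw / r * theta), NA_real_)
  data.frame(kx = kx, ky = ky)
}

#' Calibrate fisheye distortion coefficients from checkerboard corners
#'
#' Estimates the composite coefficients `kx`, `ky` by solving each corner
#' correspondence independently ([per_corner_coefficients()]) and taking the
#' arithmetic mean per axis, pooling corners across all boards and distances.
#' The principal point is an input (from an external omnidirectional
#' calibration tool or the image center), not estimated here.
#'
#' @inheritParams per_corner_coefficients
#' @param l Virtual imaging distance to store in the result (default 0).
#' @param units Length-unit label for the resulting intrinsics.
#' @return An object of class `"fisheye_calibration"`: a list with
#'   `intrinsics` ([fisheye_intrinsics()]), `per_corner_kx`, `per_corner_ky`
#'   (estimate vectors, NAs dropped), `n_corners` (valid estimates per axis)
#'   and `residual_summary` (mean/max absolute pixel reprojection error of
#'   the averaged intrinsics over all corners).
#' @section Errors: if no corner yields a valid estimate for an axis, a
#'   `"fisheyetree_calibration_failed"` error names the axis.
#' @examples
#' cam <- fisheye_intrinsics(1200, 1200, 320, 320)
#' brd <- generate_board(board_spec(4, 4, 60, L = 800), cam)
#' fit <- calibrate(brd, principal = c(320, 320))
#' fit$intrinsics$kx
#' @export
calibrate <- function(corners, principal, l = 0, units = "mm",
                      min_axis_ratio = 0.05) {
  est <- per_corner_coefficients(corners, principal, min_axis_ratio)
  kx_all <- est$kx[!is.na(est$kx)]
  ky_all <- est$ky[!is.na(est$ky)]
  for (axis in c("x", "y")) {
    vals <- if (axis == "x") kx_all else ky_all
    if (length(vals) == 0L) {
      stop_fisheye(sprintf(
        "calibration failed: no corner constrains the %s axis", axis),
        "fisheyetree_calibration_failed")
    }
  }
  cam <- fisheye_intrinsics(kx = mean(kx_all), ky = mean(ky_all),
                            u0 = principal[[1L]], v0 = principal[[2L]],
                            l = l, units = units)
  # reprojection residuals of the averaged model, per corner, in pixels
  res <- vapply(seq_len(nrow(corners)), function(i) {
    p <- project_to_pixel(corners$xw[i], corners$yw[i], corners$L[i], cam)
    sqrt((p$u - corners$u[i])^2 + (p$v - corners$v[i])^2)
  }, numeric(1))
  structure(
    list(intrinsics = cam,
         per_corner_kx = kx_all, per_corner_ky = ky_all,
         n_corners = c(x = length(kx_all), y = length(ky_all)),
         residual_summary = c(mean = mean(res), max = max(res))),
    class = "fisheye_calibration")
}

#' @export
print.fisheye_calibration <- function(x, ...) {
  cat(sprintf("Fisheye calibration from %d/%d corner estimates (x/y axis)\n",
              x$n_corners[["x"]], x$n_corners[["y"]]))
  print(x$intrinsics)
  cat(sprintf("  reprojection residual: mean %.3g px, max %.3g px\n",
              x$residual_summary[["mean"]], x$residual_summary[["max"]]))
  invisible(x)
}

#' Verify a calibration by reproducing corner-pair distances
#'
#' Given pairs of back-projected (or surveyed) world points on the
#' calibration board together with tape-measured separations, computes the
#' model distance for each pair ([planar_distance()]), the per-pair relative
#' error `100 * |calculated - measured| / measured`, and their mean.
#'
#' @param pairs A data frame with columns `x1`, `y1`, `x2`, `y2` (world
#'   coordinates of the two corners) and `measured` (reference separation,
#'   > 0). Optional columns `label` and `board_distance` are carried through.
#' @return An object of class `"distance_verification"`: a list with `rows`
#'   (the input plus `calculated` and `relative_error_pct` columns) and
#'   `mean_relative_error_pct`.
#' @examples
#' verify_distances(data.frame(
#'   x1 = -274.3518, y1 = -401.1987, x2 = -292.3145, y2 = 250.6562,
#'   measured = 650))
#' @export
verify_distances <- function(pairs) {
  pairs <- as.data.frame(pairs)
  needed <- c("x1", "y1", "x2", "y2", "measured")
  if (!all(needed %in% names(pairs))) {
    stop_fisheye(sprintf("`pairs` must have columns %s",
                         paste(needed, collapse = ", ")),
                 "fisheyetree_invalid_argument")
  }
  if (any(!is.finite(pairs$measured)) || any(pairs$measured <= 0)) {
    stop_fisheye("all `measured` values must be positive",
                 "fisheyetree_invalid_argument")
  }
  pairs$calculated <- planar_distance(pairs$x1, pairs$y1, pairs$x2, pairs$y2)
  pairs$relative_error_pct <-
    100 * abs(pairs$calculated - pairs$measured) / pairs$measured
  structure(
    list(rows = pairs,
         mean_relative_error_pct = mean(pairs$relative_error_pct)),
    class = "distance_verification")
}

#' @export
print.distance_verification <- function(x, ...) {
  out <- x$rows
  out$calculated <- round(out$calculated, 4)
  out$relative_error_pct <- round(out$relative_error_pct, 4)
  print(out, row.names = FALSE)
  cat(sprintf("mean relative error: %.3f%%\n", x$mean_relative_error_pct))
  invisible(x)
}

#' Read and write corner-correspondence CSV files
#'
#' The on-disk format has header columns `corner_id, u, v, xw, yw, L`;
#' pixel coordinates in pixels, world coordinates and distances in the
#' caller's length unit.
#'
#' @param corners Data frame with columns `u, v, xw, yw, L` (a `corner_id`
#'   column is added if absent).
#' @param path CSV file path.
#' @return `read_corners_csv()` returns the corners data frame;
#'   `write_corners_csv()` returns `path` invisibly.
#' @export
write_corners_csv <- function(corners, path) {
  corners <- as.data.frame(corners)
  if (is.null(corners$corner_id)) {
    corners$corner_id <- seq_len(nrow(corners))
  }
  utils::write.csv(corners[, c("corner_id", "u", "v", "xw", "yw", "L")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corners_csv
#' @export
read_corners_csv <- function(path) {
  if (!file.exists(path)) {
    stop_fisheye(sprintf("corners file not found: %s", path),
                 "fisheyetree_missing_file")
  }
  utils::read.csv(path)
}

#' Write a distance-verification report CSV
#'
#' Columns `label, board_distance, calculated, measured, relative_error_pct`
#' (distances and percentages rounded to 4 decimals), with a final `mean`
#' row carrying the mean relative error.
#'
#' @param verification A `"distance_verification"` object from
#'   [verify_distances()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_verification_csv <- function(verification, path) {
  rows <- verification$rows
  label <- if (is.null(rows$label)) as.character(seq_len(nrow(rows)))
           else as.character(rows$label)
  board <- if (is.null(rows$board_distance)) rep(NA_real_, nrow(rows))
           else rows$board_distance
  out <- data.frame(
    label = label,
    board_distance = board,
    calculated = round(rows$calculated, 4),
    measured = rows$measured,
    relative_error_pct = round(rows$relative_error_pct, 4))
  out <- rbind(out, data.frame(
    label = "mean", board_distance = NA_real_, calculated = NA_real_,
    measured = NA_real_,
    relative_error_pct = round(verification$mean_relative_error_pct, 4)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
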