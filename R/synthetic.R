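#' Synthetic checkerboard specification
#'
#' Describes a planar checkerboard held fronto-parallel at distance `L`,
#' whose inner corners are imaged through a fisheye model to produce corner
#' correspondences for calibration experiments. Emulates the physical
#' calibration-plate procedure: a regular grid of corners at known
#' board-plane coordinates, observed at known distance, with optional
#' Gaussian pixel noise standing in for corner-detector error.
#'
#' @param rows,cols Corner grid size (>= 2 each).
#' @param square_size Grid pitch in length units.
#' @param board_center World coordinates `c(xw, yw)` of the grid center
#'   (default on the optical axis).
#' @param L Board distance (> 0), same unit as `square_size`.
#' @param pixel_noise_sd Standard deviation of isotropic Gaussian pixel
#'   noise added to each projected corner (default 0 = exact).
#' @param seed Integer seed making the noise reproducible.
#' @return A `"board_spec"` list.
#' @export
board_spec <- function(rows, cols, square_size, board_center = c(0, 0),
                       L, pixel_noise_sd = 0, seed = 1L) {
  if (rows < 2 || cols < 2) {
    stop_fisheye("board needs at least 2x2 corners",
                 "fisheyetree_invalid_argument")
  }
  check_number(square_size, "square_size", positive = TRUE)
  check_number(L, "L", positive = TRUE)
  check_number(pixel_noise_sd, "pixel_noise_sd")
  if (pixel_noise_sd < 0) {
    stop_fisheye("`pixel_noise_sd` must be >= 0",
                 "fisheyetree_invalid_argument")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 square_size = square_size,
                 board_center = as.numeric(board_center),
                 L = L, pixel_noise_sd = pixel_noise_sd,
                 seed = as.integer(seed)),
            class = "board_spec")
}

#' Generate checkerboard corner correspondences
#'
#' Places the corner grid in the board plane, projects every corner through
#' the supplied intrinsics ([project_to_pixel()]) and adds seeded Gaussian
#' pixel noise of `spec$pixel_noise_sd` to both pixel axes.
#'
#' @param spec A [board_spec()].
#' @param cam A [fisheye_intrinsics()] object.
#' @param max_incident_angle Usable half field of view of the lens in
#'   radians (default 85 degrees); corners seen under a larger angle are
#'   rejected.
#' @return A corner-correspondence data frame (`corner_id, u, v, xw, yw, L`)
#'   suitable for [calibrate()] / [write_corners_csv()].
#' @section Errors: a corner outside the usable field of view raises
#'   `"fisheyetree_generation_error"` naming the corner.
#' @examples
#' cam <- fisheye_intrinsics(1200, 1200, 320, 320)
#' generate_board(board_spec(2, 2, 100, L = 500), cam)
#' @export
generate_board <- function(spec, cam, max_incident_angle = 85 * pi / 180) {
  stopifnot(inherits(spec, "board_spec"))
  assert_intrinsics(cam)
  xs <- (seq_len(spec$cols) - (spec$cols + 1) / 2) * spec$square_size +
    spec$board_center[1L]
  ys <- (seq_len(spec$rows) - (spec$rows + 1) / 2) * spec$square_size +
    spec$board_center[2L]
  grid <- expand.grid(xw = xs, yw = ys)
  ang <- incident_angle(grid$xw, grid$yw, spec$L)
  if (any(ang > max_incident_angle)) {
    bad <- which(ang > max_incident_angle)[1L]
    stop_fisheye(sprintf(
      "corner %d at (%.4g, %.4g) is outside the field of view",
      bad, grid$xw[bad], grid$yw[bad]), "fisheyetree_generation_error")
  }
  px <- project_to_pixel(grid$xw, grid$yw, spec$L, cam)
  if (spec$pixel_noise_sd > 0) {
    px <- with_seed(spec$seed, {
      n <- nrow(px)
      data.frame(u = px$u + stats::rnorm(n, 0, spec$pixel_noise_sd),
                 v = px$v + stats::rnorm(n, 0, spec$pixel_noise_sd))
    })
  }
  data.frame(corner_id = seq_len(nrow(grid)),
             u = px$u, v = px$v, xw = grid$xw, yw = grid$yw, L = spec$L)
}

#' Synthetic tree-scene specification
#'
#' Describes a single standing tree in the vertical plane at distance `h`
#' from the camera, facing it fronto-parallel: a rectangular trunk (lower
#' 40% of the height) topped by an elliptical crown (upper 60%, horizontal
#' extent `crown_width`). By default the trunk stands on the optical-axis
#' column (`trunk_base[1] = 0`) with the tree vertically centered on the
#' axis, which is the configuration the bounding-box midpoint rule measures
#' exactly.
#'
#' World convention: `yw` grows downward (like image rows), so the treetop
#' is the minimum `yw` of the silhouette.
#'
#' @param tree_height True tree height (> 0), length units.
#' @param trunk_base World coordinates `c(xw, yw)` of the trunk's ground
#'   point; default `c(0, tree_height/2)` (camera at mid-height).
#' @param h Horizontal camera-to-tree distance (> 0).
#' @param cam A [fisheye_intrinsics()] object.
#' @param image_size Rendered image side length in pixels (square canvas).
#' @param crown_width Horizontal crown diameter, length units.
#' @param box_jitter_sd Gaussian noise (pixels) added independently to the
#'   four ground-truth box edges, emulating detector localization error
#'   (default 0).
#' @param seed Integer seed for the jitter.
#' @return A `"tree_scene_spec"` list.
#' @export
tree_scene_spec <- function(tree_height, trunk_base = c(0, tree_height / 2),
                            h, cam, image_size = 640, crown_width,
                            box_jitter_sd = 0, seed = 1L) {
  check_number(tree_height, "tree_height", positive = TRUE)
  check_number(h, "h", positive = TRUE)
  check_number(image_size, "image_size", positive = TRUE)
  check_number(crown_width, "crown_width", positive = TRUE)
  assert_intrinsics(cam)
  structure(list(tree_height = tree_height,
                 trunk_base = as.numeric(trunk_base), h = h, cam = cam,
                 image_size = as.integer(image_size),
                 crown_width = crown_width,
                 box_jitter_sd = box_jitter_sd, seed = as.integer(seed)),
            class = "tree_scene_spec")
}

# silhouette membership test in world-plane coordinates
tree_silhouette <- function(spec) {
  xb <- spec$trunk_base[1L]
  yb <- spec$trunk_base[2L]
  trunk_h <- 0.4 * spec$tree_height
  crown_h <- 0.6 * spec$tree_height
  trunk_w <- max(0.12 * spec$crown_width, 1e-9)
  crown_cy <- yb - trunk_h - crown_h / 2
  list(
    x_base = xb, y_base = yb, y_top = yb - spec$tree_height,
    trunk_h = trunk_h, crown_h = crown_h, trunk_w = trunk_w,
    crown_cy = crown_cy,
    contains = function(xw, yw) {
      in_trunk <- abs(xw - xb) <= trunk_w / 2 &
        yw <= yb & yw >= yb - trunk_h
      in_crown <- ((xw - xb) / (spec$crown_width / 2))^2 +
        ((yw - crown_cy) / (crown_h / 2))^2 <= 1
      in_trunk | in_crown
    })
}

#' Generate a synthetic fisheye tree scene with exact ground truth
#'
#' Forward-projects a tree silhouette (vertical trunk plus elliptical
#' crown, see [tree_scene_spec()]) through the fisheye model and returns
#' the ground-truth bounding box, the exact extreme-point pixels (the
#' projections of the tree's highest and lowest world points) and,
#' optionally, a rendered binary silhouette image.
#'
#' The box is computed geometrically: its top and bottom edges pass through
#' the projected extreme points and its sides through the horizontal
#' extremes of the projected silhouette boundary. With `box_jitter_sd > 0`
#' seeded Gaussian noise is added to the four edges.
#'
#' @param spec A [tree_scene_spec()].
#' @param render If `TRUE` (default) also rasterize the silhouette into an
#'   `image_size x image_size x 3` array in `[0, 1]` (dark tree on light
#'   background) by back-projecting each pixel center and testing silhouette
#'   membership.
#' @return A list with `image` (array or `NULL`), `boxes` (one-row box data
#'   frame, confidence 1) and `truth` (list: `height`, `h`, `top_pixel`,
#'   `bottom_pixel`, `seed`).
#' @section Errors: a tree whose top or base leaves the field of view
#'   raises `"fisheyetree_generation_error"`.
#' @export
generate_tree_scene <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "tree_scene_spec"))
  cam <- spec$cam
  L <- spec$h + cam$l
  sil <- tree_silhouette(spec)
  extremes <- data.frame(xw = c(sil$x_base, sil$x_base),
                         yw = c(sil$y_top, sil$y_base))
  ang <- incident_angle(extremes$xw, extremes$yw, L)
  if (any(ang >= pi / 2 * 0.999)) {
    stop_fisheye("tree extreme point outside the field of view",
                 "fisheyetree_generation_error")
  }
  ep <- project_to_pixel(extremes$xw, extremes$yw, L, cam)
  # silhouette boundary sample: crown ellipse + trunk rectangle outline
  tt <- seq(0, 2 * pi, length.out = 721L)[-721L]
  bx <- c(sil$x_base + spec$crown_width / 2 * cos(tt),
          sil$x_base + c(-1, -1, 1, 1) * sil$trunk_w / 2)
  by <- c(sil$crown_cy + sil$crown_h / 2 * sin(tt),
          c(sil$y_base, sil$y_base - sil$trunk_h,
            sil$y_base - sil$trunk_h, sil$y_base))
  bp <- project_to_pixel(bx, by, L, cam)
  box <- data.frame(x_min = min(bp$u), y_min = ep$v[1L],
                    x_max = max(bp$u), y_max = ep$v[2L],
                    confidence = 1, label = "tree")
  if (spec$box_jitter_sd > 0) {
    box <- with_seed(spec$seed, {
      j <- stats::rnorm(4, 0, spec$box_jitter_sd)
      box$x_min <- box$x_min + j[1L]
      box$y_min <- box$y_min + j[2L]
      box$x_max <- box$x_max + j[3L]
      box$y_max <- box$y_max + j[4L]
      box
    })
  }
  box <- validate_boxes(box)
  img <- NULL
  if (render) {
    n <- spec$image_size
    # restrict the membership test to a padded window around the box
    c0 <- max(0L, floor(min(bp$u, ep$u) - 2))
    c1 <- min(n - 1L, ceiling(max(bp$u, ep$u) + 2))
    r0 <- max(0L, floor(min(bp$v, ep$v) - 2))
    r1 <- min(n - 1L, ceiling(max(bp$v, ep$v) + 2))
    img <- array(0.92, dim = c(n, n, 3L))
    if (c1 >= c0 && r1 >= r0) {
      cols <- seq(c0, c1)
      rows <- seq(r0, r1)
      gg <- expand.grid(u = cols + 0.5, v = rows + 0.5)
      th <- sqrt(((gg$u - cam$u0) / cam$kx)^2 +
                 ((gg$v - cam$v0) / cam$ky)^2)
      ok <- th < pi / 2
      inside <- logical(nrow(gg))
      if (any(ok)) {
        w <- backproject_to_world(gg$u[ok], gg$v[ok], L, cam)
        inside[ok] <- sil$contains(w$xw, w$yw)
      }
      mask <- matrix(inside, nrow = length(cols))  # cols vary fastest
      for (ch in 1:3) {
        sub <- img[rows + 1L, cols + 1L, ch]
        sub[t(mask)] <- c(0.18, 0.25, 0.12)[ch]
        img[rows + 1L, cols + 1L, ch] <- sub
      }
    }
  }
  list(image = img, boxes = box,
       truth = list(height = spec$tree_height, h = spec$h,
                    top_pixel = c(u = ep$u[1L], v = ep$v[1L]),
                    bottom_pixel = c(u = ep$u[2L], v = ep$v[2L]),
                    seed = spec$seed))
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
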