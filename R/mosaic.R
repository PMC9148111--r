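#' Mosaic augmentation of four annotated images
#'
#' Combines four annotated images into one training image: each input is
#' optionally mirrored horizontally, rescaled, color-jittered in HSV space,
#' and placed into one quadrant of a square canvas around a randomly drawn
#' center point; bounding boxes undergo the same affine map and are clipped
#' to their quadrant. A box is dropped when clipping removes more than 75%
#' of its area or leaves a side shorter than 2 px. All randomness is drawn
#' from a single seeded stream, so a fixed `seed` reproduces the output
#' bit for bit.
#'
#' @param images List of exactly 4 arrays, each `h x w x 3` with values in
#'   `[0, 1]`.
#' @param boxes List of exactly 4 box data frames (possibly 0-row) in the
#'   corresponding image's pixel coordinates.
#' @param out_size Side length of the square output canvas in pixels
#'   (default 640).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param scale_range Range of the scale factor: each image's longer side
#'   becomes `factor * out_size` with `factor` drawn uniformly from this
#'   range (default `c(0.4, 1)`).
#' @param flip_prob Probability of a horizontal mirror per image
#'   (default 0.5).
#' @param hsv_jitter Maximum multiplicative jitter of hue/saturation/value
#'   as a length-3 vector of half-ranges (default `c(0.02, 0.3, 0.3)`);
#'   `c(0, 0, 0)` disables color jitter.
#' @param center Canvas center point `c(x, y)` splitting the quadrants;
#'   `NULL` (default) draws it uniformly from the central half of the
#'   canvas.
#' @return A list with `image` (`out_size x out_size x 3` array) and
#'   `boxes` (box data frame in canvas coordinates, with a `source` column
#'   giving the input index).
#' @examples
#' img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
#' bx <- bounding_box(2, 2, 10, 12)
#' m <- mosaic(rep(list(img), 4), rep(list(bx), 4), out_size = 16, seed = 1)
#' dim(m$image)
#' @export
mosaic <- function(images, boxes, out_size = 640, seed = NULL,
                   scale_range = c(0.4, 1), flip_prob = 0.5,
                   hsv_jitter = c(0.02, 0.3, 0.3), center = NULL) {
  if (!is.list(images) || length(images) != 4L) {
    stop_fisheye("mosaic needs exactly 4 input images",
                 "fisheyetree_invalid_argument")
  }
  if (!is.list(boxes) || length(boxes) != 4L) {
    stop_fisheye("mosaic needs exactly 4 box sets",
                 "fisheyetree_invalid_argument")
  }
  check_number(out_size, "out_size", positive = TRUE)
  run <- function() {
    canvas <- array(0.5, dim = c(out_size, out_size, 3L))
    cx <- if (is.null(center)) stats::runif(1, 0.25, 0.75) * out_size
          else center[1L]
    cy <- if (is.null(center)) stats::runif(1, 0.25, 0.75) * out_size
          else center[2L]
    out_boxes <- list()
    for (q in 1:4) {
      img <- images[[q]]
      bxs <- if (nrow(as.data.frame(boxes[[q]])) > 0L)
        validate_boxes(boxes[[q]]) else as.data.frame(boxes[[q]])
      h <- dim(img)[1L]
      w <- dim(img)[2L]
      flipped <- stats::runif(1) < flip_prob
      fac <- stats::runif(1, scale_range[1L], scale_range[2L])
      s <- fac * out_size / max(h, w)
      sh <- max(1L, round(h * s))
      sw <- max(1L, round(w * s))
      if (flipped) {
        img <- img[, rev(seq_len(w)), , drop = FALSE]
        if (nrow(bxs) > 0L) {
          xm <- bxs$x_min
          bxs$x_min <- w - bxs$x_max
          bxs$x_max <- w - xm
        }
      }
      img <- resize_nn(img, sh, sw)
      img <- jitter_hsv(img, hsv_jitter)
      # exact scale factors of the rounded resize, per axis
      sx <- sw / w
      sy <- sh / h
      off <- switch(q,
                    c(cx - sw, cy - sh),  # top-left: anchor bottom-right
                    c(cx, cy - sh),       # top-right: anchor bottom-left
                    c(cx - sw, cy),       # bottom-left: anchor top-right
                    c(cx, cy))            # bottom-right: anchor top-left
      quad <- switch(q,
                     c(0, 0, cx, cy),
                     c(cx, 0, out_size, cy),
                     c(0, cy, cx, out_size),
                     c(cx, cy, out_size, out_size))
      canvas <- blit(canvas, img, off, quad)
      if (nrow(bxs) > 0L) {
        tb <- data.frame(x_min = bxs$x_min * sx + off[1L],
                         y_min = bxs$y_min * sy + off[2L],
                         x_max = bxs$x_max * sx + off[1L],
                         y_max = bxs$y_max * sy + off[2L])
        area <- (tb$x_max - tb$x_min) * (tb$y_max - tb$y_min)
        cl <- data.frame(x_min = pmax(tb$x_min, quad[1L]),
                         y_min = pmax(tb$y_min, quad[2L]),
                         x_max = pmin(tb$x_max, quad[3L]),
                         y_max = pmin(tb$y_max, quad[4L]))
        wd <- cl$x_max - cl$x_min
        ht <- cl$y_max - cl$y_min
        keep <- wd >= 2 & ht >= 2 & (wd * ht) >= 0.25 * area
        if (any(keep)) {
          kept <- cl[keep, , drop = FALSE]
          kept$confidence <- if (is.null(bxs$confidence)) NA_real_
                             else bxs$confidence[keep]
          kept$label <- if (is.null(bxs$label)) "tree" else bxs$label[keep]
          kept$source <- q
          out_boxes[[length(out_boxes) + 1L]] <- kept
        }
      }
    }
    bout <- if (length(out_boxes) > 0L) do.call(rbind, out_boxes) else
      data.frame(x_min = numeric(), y_min = numeric(),
                 x_max = numeric(), y_max = numeric(),
                 confidence = numeric(), label = character(),
                 source = integer())
    rownames(bout) <- NULL
    list(image = canvas, boxes = bout)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# nearest-neighbor resize of an h x w x 3 array
resize_nn <- function(img, new_h, new_w) {
  h <- dim(img)[1L]
  w <- dim(img)[2L]
  if (new_h == h && new_w == w) return(img)
  ri <- pmin(h, pmax(1L, ceiling((seq_len(new_h) - 0.5) * h / new_h)))
  ci <- pmin(w, pmax(1L, ceiling((seq_len(new_w) - 0.5) * w / new_w)))
  img[ri, ci, , drop = FALSE]
}

# multiplicative HSV jitter; gains are half-ranges, hue wraps around
jitter_hsv <- function(img, gains) {
  if (all(gains == 0)) return(img)
  d <- dim(img)
  g <- 1 + stats::runif(3, -gains, gains)
  rgb <- matrix(c(img[, , 1L], img[, , 2L], img[, , 3L]),
                nrow = 3L, byrow = TRUE)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hsv[1L, ] <- (hsv[1L, ] * g[1L]) %% 1
  hsv[2L, ] <- pmin(1, hsv[2L, ] * g[2L])
  hsv[3L, ] <- pmin(1, hsv[3L, ] * g[3L])
  out <- grDevices::col2rgb(grDevices::hsv(hsv[1L, ], hsv[2L, ], hsv[3L, ])) / 255
  array(c(out[1L, ], out[2L, ], out[3L, ]), dim = d)
}

# paste `img` onto `canvas` with top-left at `off`, cropped to rect `quad`
# (all in 0-based continuous coordinates; pixel i covers [i-1, i))
blit <- function(canvas, img, off, quad) {
  sh <- dim(img)[1L]
  sw <- dim(img)[2L]
  x0 <- max(ceiling(off[1L]), ceiling(quad[1L]), 0)
  y0 <- max(ceiling(off[2L]), ceiling(quad[2L]), 0)
  x1 <- min(floor(off[1L] + sw), floor(quad[3L]), dim(canvas)[2L])
  y1 <- min(floor(off[2L] + sh), floor(quad[4L]), dim(canvas)[1L])
  if (x1 <= x0 || y1 <= y0) return(canvas)
  dest_c <- seq(x0 + 1L, x1)
  dest_r <- seq(y0 + 1L, y1)
  # source pixel containing each destination pixel center
  src_c <- pmin(sw, pmax(1L, floor(dest_c - 0.5 - off[1L]) + 1L))
  src_r <- pmin(sh, pmax(1L, floor(dest_r - 0.5 - off[2L]) + 1L))
  canvas[dest_r, dest_c, ] <- img[src_r, src_c, , drop = FALSE]
  canvas
}
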