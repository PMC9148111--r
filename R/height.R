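#' Axis-aligned bounding boxes
#'
#' Boxes are represented throughout the package as data frames with numeric
#' columns `x_min`, `y_min`, `x_max`, `y_max` (pixels, 0-based, corners
#' inclusive-exclusive `[min, max)`) plus optional `confidence` (in `[0,1]`)
#' and `label`. `bounding_box()` builds such a data frame and
#' `validate_boxes()` checks the invariants (`x_min < x_max`,
#' `y_min < y_max`, finite coordinates).
#'
#' @param x_min,y_min,x_max,y_max Box edges in pixels; vectorized.
#' @param confidence Optional detector confidence in `[0,1]`.
#' @param label Class label, default `"tree"`.
#' @return A validated box data frame.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max,
                         confidence = NA_real_, label = "tree") {
  validate_boxes(data.frame(x_min = x_min, y_min = y_min,
                            x_max = x_max, y_max = y_max,
                            confidence = confidence, label = label))
}

#' @param boxes A box data frame.
#' @rdname bounding_box
#' @export
validate_boxes <- function(boxes) {
  boxes <- as.data.frame(boxes)
  needed <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(needed %in% names(boxes))) {
    stop_fisheye(sprintf("boxes must have columns %s",
                         paste(needed, collapse = ", ")),
                 "fisheyetree_invalid_argument")
  }
  coords <- as.matrix(boxes[, needed])
  if (any(!is.finite(coords))) {
    stop_fisheye("box coordinates must be finite",
                 "fisheyetree_invalid_argument")
  }
  if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max)) {
    stop_fisheye("degenerate box: need x_min < x_max and y_min < y_max",
                 "fisheyetree_invalid_argument")
  }
  conf <- boxes$confidence
  if (!is.null(conf) && any(!is.na(conf) & (conf < 0 | conf > 1))) {
    stop_fisheye("box confidence must lie in [0, 1]",
                 "fisheyetree_invalid_argument")
  }
  boxes
}

#' Extreme points of a tree bounding box
#'
#' The image points of the tree's highest and lowest world points are taken
#' as the midpoints of the top and bottom edges of its detection box:
#' top `((x_min + x_max)/2, y_min)` and bottom `((x_min + x_max)/2, y_max)`.
#' "Top" is the smaller row coordinate (rows grow downward).
#'
#' @param boxes A box data frame (see [bounding_box()]); vectorized over rows.
#' @return A list with data frames `top` and `bottom`, each with columns
#'   `u`, `v`.
#' @examples
#' box_extremes(bounding_box(100, 40, 200, 400))
#' @export
box_extremes <- function(boxes) {
  boxes <- validate_boxes(boxes)
  mid <- (boxes$x_min + boxes$x_max) / 2
  list(top = data.frame(u = mid, v = boxes$y_min),
       bottom = data.frame(u = mid, v = boxes$y_max))
}

#' Tree height from a single bounding box
#'
#' The core measurement: back-project the two extreme points of the box
#' through the calibrated fisheye model to world-plane coordinates at model
#' distance `L = h + l`, then take their planar Euclidean distance.
#'
#' @param boxes A box data frame; vectorized over rows (all boxes share the
#'   same camera-to-tree distance `h`).
#' @param h Measured horizontal camera-to-tree distance (> 0), in the
#'   intrinsics' length unit.
#' @param cam A [fisheye_intrinsics()] object.
#' @param quiet Suppress the advisory message emitted when `cam$l == 0`
#'   (the virtual imaging distance is unset, so `L = h`).
#' @return Numeric vector of measured heights, same unit as `h`.
#' @section Errors: an extreme point outside the field of view raises
#'   `"fisheyetree_measurement_failed"` naming the offending point.
#' @examples
#' cam <- fisheye_intrinsics(1000, 1000, 320, 320)
#' scene <- generate_tree_scene(
#'   tree_scene_spec(tree_height = 12, h = 15, cam = cam, image_size = 640,
#'                   crown_width = 4), render = FALSE)
#' measure_tree_height(scene$boxes, h = 15, cam = cam, quiet = TRUE)
#' @export
measure_tree_height <- function(boxes, h, cam, quiet = FALSE) {
  check_number(h, "h", positive = TRUE)
  assert_intrinsics(cam)
  if (!quiet && cam$l == 0) {
    message("virtual imaging distance l = 0: using L = h for measurement")
  }
  ext <- box_extremes(boxes)
  L <- h + cam$l
  top <- tryCatch(
    backproject_to_world(ext$top$u, ext$top$v, L, cam),
    fisheyetree_out_of_field = function(e) {
      stop_fisheye(paste0("top extreme point out of field: ",
                          conditionMessage(e)),
                   "fisheyetree_measurement_failed")
    })
  bottom <- tryCatch(
    backproject_to_world(ext$bottom$u, ext$bottom$v, L, cam),
    fisheyetree_out_of_field = function(e) {
      stop_fisheye(paste0("bottom extreme point out of field: ",
                          conditionMessage(e)),
                   "fisheyetree_measurement_failed")
    })
  planar_distance(top$xw, top$yw, bottom$xw, bottom$yw)
}

#' Batch tree-height measurement with error summary
#'
#' Measures every annotated box of every image against its per-image
#' camera-to-tree distance and, where reference heights are supplied,
#' reports relative errors (`100 * |predicted - reference| / reference`)
#' and their mean/max.
#'
#' @param annotations A data frame of boxes with an `image` column plus the
#'   box columns of [bounding_box()].
#' @param distances A data frame with columns `image`, `h` and optionally
#'   `reference_height` (one row per image; every annotated image must
#'   appear).
#' @param cam A [fisheye_intrinsics()] object.
#' @param conf_threshold Boxes with known confidence below this value are
#'   dropped before measurement (default 0.5); boxes without confidence are
#'   kept.
#' @return A list with `measurements` (data frame: `tree_id`, `image`,
#'   `height`, `reference_height`, `relative_error_pct`) and `summary`
#'   (named vector `mean`/`max` of relative error in percent, or `NULL`
#'   when no references are available).
#' @section Errors: an annotated image missing from `distances` raises
#'   `"fisheyetree_configuration_error"`.
#' @export
batch_measure <- function(annotations, distances, cam,
                          conf_threshold = 0.5) {
  assert_intrinsics(cam)
  annotations <- as.data.frame(annotations)
  empty <- data.frame(tree_id = character(), image = character(),
                      height = numeric(), reference_height = numeric(),
                      relative_error_pct = numeric())
  if (nrow(annotations) == 0L) {
    return(list(measurements = empty, summary = NULL))
  }
  annotations <- validate_boxes(annotations)
  if (is.null(annotations$image)) {
    stop_fisheye("`annotations` must have an `image` column",
                 "fisheyetree_invalid_argument")
  }
  conf <- annotations$confidence
  if (!is.null(conf)) {
    annotations <- annotations[is.na(conf) | conf >= conf_threshold, ,
                               drop = FALSE]
  }
  if (nrow(annotations) == 0L) {
    return(list(measurements = empty, summary = NULL))
  }
  distances <- as.data.frame(distances)
  missing_img <- setdiff(unique(annotations$image), distances$image)
  if (length(missing_img) > 0L) {
    stop_fisheye(sprintf("no distance `h` supplied for image(s): %s",
                         paste(missing_img, collapse = ", ")),
                 "fisheyetree_configuration_error")
  }
  idx <- match(annotations$image, distances$image)
  h_all <- distances$h[idx]
  if (any(!is.finite(h_all)) || any(h_all <= 0)) {
    stop_fisheye("every image needs a positive distance `h`",
                 "fisheyetree_configuration_error")
  }
  refs <- if (is.null(distances$reference_height)) rep(NA_real_, nrow(annotations))
          else distances$reference_height[idx]
  if (!quiet_l_ok(cam)) {
    message("virtual imaging distance l = 0: using L = h for measurement")
  }
  heights <- vapply(seq_len(nrow(annotations)), function(i) {
    measure_tree_height(annotations[i, , drop = FALSE], h_all[i], cam,
                        quiet = TRUE)
  }, numeric(1))
  rel <- ifelse(is.na(refs), NA_real_, 100 * abs(heights - refs) / refs)
  ord <- stats::ave(seq_along(heights), annotations$image,
                    FUN = seq_along)
  meas <- data.frame(
    tree_id = paste0(annotations$image, "#", ord),
    image = annotations$image,
    height = heights,
    reference_height = refs,
    relative_error_pct = rel)
  summary <- if (all(is.na(rel))) NULL else
    c(mean = mean(rel, na.rm = TRUE), max = max(rel, na.rm = TRUE))
  list(measurements = meas, summary = summary)
}

quiet_l_ok <- function(cam) cam$l > 0

#' Write batch measurement results
#'
#' `write_results_csv()` writes one row per measured tree
#' (`tree_id, image, height, reference_height, relative_error_pct`);
#' `write_summary_json()` writes the mean/max relative error as JSON.
#'
#' @param result A list from [batch_measure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(result, path) {
  utils::write.csv(result$measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
write_summary_json <- function(result, path) {
  s <- result$summary
  doc <- if (is.null(s)) list() else
    list(mean_relative_error_pct = s[["mean"]],
         max_relative_error_pct = s[["max"]])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
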