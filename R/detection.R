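#' Intersection-over-union between two sets of boxes
#'
#' @param a,b Box data frames (see [bounding_box()]).
#' @return A `nrow(a) x nrow(b)` matrix of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- validate_boxes(a)
  b <- validate_boxes(b)
  ix <- pmax(0, outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax))
  iy <- pmax(0, outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (outer(area_a, area_b, `+`) - inter)
}

#' Match predicted boxes to ground truth
#'
#' Greedy one-to-one matching in descending confidence order: each
#' prediction is a true positive iff its best IoU against a still-unmatched
#' ground-truth box reaches `iou_threshold`; otherwise it is a false
#' positive. Unmatched ground truths are false negatives. Ties in
#' confidence are broken by input order, so the outcome is deterministic.
#'
#' @param preds Predicted boxes with a `confidence` column (missing
#'   confidences are treated as 1).
#' @param gts Ground-truth boxes.
#' @param iou_threshold IoU acceptance threshold in `[0, 1]` (default 0.5,
#'   the usual detection-benchmark convention).
#' @return An object of class `"match_outcome"`: a list with counts `tp`,
#'   `fp`, `fn`, the number of ground truths `n_gt`, and `ranked`, a data
#'   frame of `(confidence, is_tp)` in descending-confidence order, from
#'   which the precision-recall curve and AP are built.
#' @examples
#' gt <- bounding_box(c(0, 100), c(0, 0), c(50, 150), c(50, 50))
#' match_detections(gt, gt, iou_threshold = 0.5)
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  if (!is.numeric(iou_threshold) || length(iou_threshold) != 1L ||
      is.na(iou_threshold) || iou_threshold < 0 || iou_threshold > 1) {
    stop_fisheye("`iou_threshold` must lie in [0, 1]",
                 "fisheyetree_invalid_argument")
  }
  preds <- as.data.frame(preds)
  gts <- as.data.frame(gts)
  n_gt <- nrow(gts)
  if (nrow(preds) == 0L) {
    return(structure(list(tp = 0L, fp = 0L, fn = n_gt, n_gt = n_gt,
                          ranked = data.frame(confidence = numeric(),
                                              is_tp = logical())),
                     class = "match_outcome"))
  }
  preds <- validate_boxes(preds)
  conf <- preds$confidence
  if (is.null(conf)) conf <- rep(1, nrow(preds))
  conf[is.na(conf)] <- 1
  ord <- order(-conf)  # stable: ties keep input order
  iou <- if (n_gt > 0L) box_iou(preds, validate_boxes(gts)) else NULL
  gt_taken <- rep(FALSE, n_gt)
  is_tp <- logical(nrow(preds))
  for (i in ord) {
    if (n_gt == 0L) break
    free <- which(!gt_taken)
    if (length(free) == 0L) next
    j <- free[which.max(iou[i, free])]
    if (iou[i, j] >= iou_threshold) {
      gt_taken[j] <- TRUE
      is_tp[i] <- TRUE
    }
  }
  tp <- sum(is_tp)
  structure(
    list(tp = tp, fp = nrow(preds) - tp, fn = n_gt - tp, n_gt = n_gt,
         ranked = data.frame(confidence = conf[ord], is_tp = is_tp[ord])),
    class = "match_outcome")
}

undefined_metric <- function(what) {
  stop_fisheye(sprintf("%s is undefined (zero denominator)", what),
               "fisheyetree_undefined_metric")
}

#' Single-class detection metrics
#'
#' Precision `P = TP/(TP+FP)` and recall `R = TP/(TP+FN)` in percent, and
#' the F1 score — the harmonic mean `2PR/(P+R)` — reported as a ratio in
#' `[0, 1]` rounded to two decimals, the convention under which detection
#' benchmarks print it.
#'
#' @param m A `"match_outcome"` from [match_detections()].
#' @return `precision()`/`recall()`: percent; `f1_score()`: ratio in `[0,1]`.
#' @section Errors: a zero denominator (no predictions, no ground truths, or
#'   `p + r = 0`) raises `"fisheyetree_undefined_metric"` rather than
#'   silently returning 0.
#' @examples
#' f1_score(92.27, 97.95)
#' @export
precision <- function(m) {
  if (m$tp + m$fp == 0L) undefined_metric("precision")
  100 * m$tp / (m$tp + m$fp)
}

#' @rdname precision
#' @export
recall <- function(m) {
  if (m$tp + m$fn == 0L) undefined_metric("recall")
  100 * m$tp / (m$tp + m$fn)
}

#' @param p,r Precision and recall in percent.
#' @rdname precision
#' @export
f1_score <- function(p, r) {
  if (p + r == 0) undefined_metric("F1")
  round(2 * p * r / (p + r) / 100, 2)
}

#' Precision-recall curve of a ranked detection list
#'
#' Cumulative precision and recall down the confidence-ranked list of
#' predictions.
#'
#' @inheritParams precision
#' @return A data frame with columns `confidence`, `recall`, `precision`
#'   (ratios in `[0, 1]`), one row per prediction.
#' @export
pr_curve <- function(m) {
  if (m$n_gt == 0L) undefined_metric("PR curve")
  k <- seq_len(nrow(m$ranked))
  cum_tp <- cumsum(m$ranked$is_tp)
  data.frame(confidence = m$ranked$confidence,
             recall = cum_tp / m$n_gt,
             precision = cum_tp / k)
}

#' Average precision (area under the precision-recall curve)
#'
#' All-point interpolated AP: the area under the monotone precision
#' envelope as a function of recall, `integral_0^1 p_interp(R) dR`, where
#' `p_interp(R)` is the maximum precision attained at any recall `>= R`.
#'
#' @inheritParams precision
#' @return AP in percent.
#' @examples
#' # 2 ground truths, ranked flags TP, FP, TP
#' m <- structure(list(tp = 2L, fp = 1L, fn = 0L, n_gt = 2L,
#'                     ranked = data.frame(confidence = c(.9, .8, .7),
#'                                         is_tp = c(TRUE, FALSE, TRUE))),
#'                class = "match_outcome")
#' average_precision(m)  # 83.33
#' @export
average_precision <- function(m) {
  if (m$n_gt == 0L) undefined_metric("average precision")
  if (nrow(m$ranked) == 0L || !any(m$ranked$is_tp)) return(0)
  curve <- pr_curve(m)
  rec <- c(0, curve$recall)
  # precision envelope: running max of precision from the right
  env <- rev(cummax(rev(curve$precision)))
  100 * sum((rec[-1] - rec[-length(rec)]) * env)
}

#' Evaluate predictions against ground truth in one call
#'
#' Convenience wrapper chaining [match_detections()], [precision()],
#' [recall()], [f1_score()], [average_precision()] and [pr_curve()].
#'
#' @inheritParams match_detections
#' @return A list with `P`, `R` (percent), `F1` (ratio), `AP` (percent),
#'   `counts` (tp/fp/fn) and `curve` (the PR curve data frame).
#' @export
evaluate_detections <- function(preds, gts, iou_threshold = 0.5) {
  m <- match_detections(preds, gts, iou_threshold)
  p <- precision(m)
  r <- recall(m)
  list(P = p, R = r, F1 = f1_score(p, r), AP = average_precision(m),
       counts = c(tp = m$tp, fp = m$fp, fn = m$fn),
       curve = pr_curve(m))
}
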