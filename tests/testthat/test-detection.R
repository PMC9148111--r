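test_that("matching handles perfect, disjoint and mixed detectors", {
  gts <- bounding_box(c(0, 100, 200), c(0, 0, 0),
                      c(50, 150, 250), c(50, 50, 50))
  perfect <- gts
  perfect$confidence <- c(0.9, 0.8, 0.7)
  m <- match_detections(perfect, gts)
  expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))
  far <- perfect
  far$x_min <- far$x_min + 1000
  far$x_max <- far$x_max + 1000
  m2 <- match_detections(far, gts)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 3L, 3L))
  expect_error(match_detections(perfect, gts, iou_threshold = 1.5),
               class = "fisheyetree_invalid_argument")
})

test_that("ranked flags follow the greedy confidence-ordered trace", {
  gts <- bounding_box(c(0, 100), c(0, 0), c(50, 150), c(50, 50))
  preds <- bounding_box(c(0, 400, 100), c(0, 0, 0),
                        c(50, 450, 150), c(50, 50, 50),
                        confidence = c(0.9, 0.8, 0.7))
  m <- match_detections(preds, gts)
  expect_equal(m$ranked$is_tp, c(TRUE, FALSE, TRUE))
  expect_equal(average_precision(m), oracle_ap(c(TRUE, FALSE, TRUE), 2))
  expect_equal(average_precision(m), 100 * 5 / 6, tolerance = 1e-12)
})

test_that("matching agrees with the exhaustive IoU-matrix oracle", {
  set.seed(29)
  for (i in 1:60) {
    preds <- random_boxes(sample(0:8, 1))
    gts <- random_boxes(sample(1:8, 1), conf = FALSE)
    thr <- runif(1, 0.1, 0.9)
    m <- match_detections(preds, gts, iou_threshold = thr)
    expect_equal(m$tp + m$fn, nrow(gts))
    expect_equal(m$tp + m$fp, nrow(preds))
    if (nrow(preds) > 0) {
      iou <- outer(seq_len(nrow(preds)), seq_len(nrow(gts)),
                   Vectorize(function(i, j) {
                     oracle_iou(as.numeric(preds[i, 1:4]),
                                as.numeric(gts[j, 1:4]))
                   }))
      expect_equal(m$ranked$is_tp,
                   oracle_match_flags(iou, preds$confidence, thr))
      # AP equals the brute-force envelope oracle on every instance
      if (m$tp + m$fp > 0) {
        expect_equal(average_precision(m),
                     oracle_ap(m$ranked$is_tp, m$n_gt), tolerance = 1e-12)
      }
    }
  }
})

test_that("raising the IoU threshold never adds true positives", {
  set.seed(31)
  for (i in 1:20) {
    preds <- random_boxes(6)
    gts <- random_boxes(5, conf = FALSE)
    tps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(t) {
      match_detections(preds, gts, iou_threshold = t)$tp
    }, integer(1))
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("precision, recall and F1 reproduce the printed benchmarks", {
  expect_equal(f1_score(92.27, 97.95), 0.95)
  expect_equal(f1_score(93.03, 95.90), 0.94)
  expect_equal(f1_score(100, 100), 1.00)
  m <- structure(list(tp = 9L, fp = 1L, fn = 3L, n_gt = 12L,
                      ranked = data.frame(confidence = numeric(0),
                                          is_tp = logical(0))),
                 class = "match_outcome")
  expect_equal(precision(m), 90)
  expect_equal(recall(m), 75)
  empty <- structure(list(tp = 0L, fp = 0L, fn = 0L, n_gt = 0L,
                          ranked = data.frame(confidence = numeric(0),
                                              is_tp = logical(0))),
                     class = "match_outcome")
  expect_error(precision(empty), class = "fisheyetree_undefined_metric")
  expect_error(recall(empty), class = "fisheyetree_undefined_metric")
  expect_error(f1_score(0, 0), class = "fisheyetree_undefined_metric")
  expect_error(average_precision(empty),
               class = "fisheyetree_undefined_metric")
})

test_that("F1 lies between precision and recall (harmonic-mean bound)", {
  set.seed(37)
  for (i in 1:100) {
    p <- runif(1, 1, 100)
    r <- runif(1, 1, 100)
    f1 <- 2 * p * r / (p + r)  # unrounded harmonic mean
    expect_gte(f1, min(p, r) - 1e-9)
    expect_lte(f1, max(p, r) + 1e-9)
    expect_equal(f1_score(p, r), round(f1 / 100, 2))
  }
})

test_that("AP is 100 for a perfect ranking and 0 with no true positive", {
  gts <- bounding_box(c(0, 100), c(0, 0), c(50, 150), c(50, 50))
  perfect <- gts
  perfect$confidence <- c(0.9, 0.8)
  expect_equal(average_precision(match_detections(perfect, gts)), 100)
  off <- perfect
  off$x_min <- off$x_min + 500
  off$x_max <- off$x_max + 500
  expect_equal(average_precision(match_detections(off, gts)), 0)
})

test_that("inserting false positives never raises AP before full recall", {
  set.seed(43)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    flags <- runif(n) < 0.6
    n_gt <- sum(flags) + sample(0:2, 1)
    if (sum(flags) == 0 || n_gt == 0) next
    base <- oracle_ap(flags, n_gt)
    at <- sample(seq_len(n + 1), 1)
    with_fp <- append(flags, FALSE, after = at - 1)
    expect_lte(oracle_ap(with_fp, n_gt), base + 1e-12)
    # and the implementation tracks the oracle on both lists
    mk <- function(fl) structure(
      list(tp = sum(fl), fp = sum(!fl), fn = n_gt - sum(fl), n_gt = n_gt,
           ranked = data.frame(confidence = seq(1, 0.5,
                                                length.out = length(fl)),
                               is_tp = fl)),
      class = "match_outcome")
    expect_equal(average_precision(mk(flags)), base, tolerance = 1e-12)
    expect_equal(average_precision(mk(with_fp)), oracle_ap(with_fp, n_gt),
                 tolerance = 1e-12)
  }
})

test_that("evaluate_detections chains counts, metrics and the PR curve", {
  gts <- bounding_box(c(0, 100, 200), c(0, 0, 0),
                      c(60, 160, 260), c(60, 60, 60))
  preds <- bounding_box(c(2, 400, 202), c(2, 0, 2),
                        c(62, 450, 262), c(62, 50, 62),
                        confidence = c(0.95, 0.9, 0.85))
  ev <- evaluate_detections(preds, gts)
  expect_equal(as.numeric(ev$counts), c(2, 1, 1))
  expect_equal(ev$P, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(ev$R, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(ev$F1, 0.67)
  expect_equal(nrow(ev$curve), 3)
  expect_equal(ev$curve$recall, c(1, 1, 2) / 3)
})
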