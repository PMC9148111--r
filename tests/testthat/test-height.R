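test_that("box extreme points are the top/bottom edge midpoints", {
  e <- box_extremes(bounding_box(0, 0, 10, 100))
  expect_equal(c(e$top$u, e$top$v), c(5, 0))
  expect_equal(c(e$bottom$u, e$bottom$v), c(5, 100))
  e2 <- box_extremes(bounding_box(100, 40, 200, 400))
  expect_equal(c(e2$top$u, e2$top$v), c(150, 40))
  expect_equal(c(e2$bottom$u, e2$bottom$v), c(150, 400))
  expect_error(box_extremes(data.frame(x_min = 5, y_min = 0,
                                       x_max = 5, y_max = 10)),
               class = "fisheyetree_invalid_argument")
})

test_that("axial boxes obey the closed-form height formula", {
  # box symmetric about the principal row on the principal column:
  # height = 2 (h + l) tan((y_max - y_min) / (2 ky))
  cam <- fisheye_intrinsics(1000, 1000, 320, 320, l = 5)
  box <- bounding_box(300, 320 - 250, 340, 320 + 250)
  got <- measure_tree_height(box, h = 95, cam = cam, quiet = TRUE)
  expect_equal(got, 2 * 100 * tan(500 / (2 * 1000)), tolerance = 1e-12)
  # coincident extremes measure zero height
  degenerate <- data.frame(x_min = 100, y_min = 200, x_max = 140,
                           y_max = 200 + 1e-9)
  expect_equal(measure_tree_height(degenerate, 10, cam, quiet = TRUE), 0,
               tolerance = 1e-6)
  # an extreme point outside the field fails, naming the point
  wild <- bounding_box(318, 320, 322, 320 + 1000 * pi / 2)
  expect_error(measure_tree_height(wild, 10, cam, quiet = TRUE),
               regexp = "bottom",
               class = "fisheyetree_measurement_failed")
})

test_that("measurement inverts the scene generator exactly at zero noise", {
  set.seed(23)
  for (i in 1:30) {
    cam <- fisheye_intrinsics(runif(1, 500, 3000), runif(1, 500, 3000),
                              runif(1, 200, 800), runif(1, 200, 800),
                              l = runif(1, 0, 1))
    height <- runif(1, 3, 30)
    h <- runif(1, 0.8, 3) * height
    spec <- tree_scene_spec(height, h = h, cam = cam, image_size = 640,
                            crown_width = runif(1, 0.2, 0.6) * height)
    scene <- generate_tree_scene(spec, render = FALSE)
    got <- measure_tree_height(scene$boxes, h = h, cam = cam, quiet = TRUE)
    expect_equal(got, height, tolerance = 1e-6)
  }
})

test_that("lowering the bottom edge never shrinks the measured height", {
  cam <- fisheye_intrinsics(800, 900, 320, 320)
  y_max <- seq(330, 320 + 0.95 * 900 * pi / 2, length.out = 40)
  hts <- vapply(y_max, function(y) {
    measure_tree_height(bounding_box(310, 100, 330, y), 20, cam,
                        quiet = TRUE)
  }, numeric(1))
  expect_true(all(diff(hts) > 0))
})

test_that("scaling world lengths scales the measurement equally", {
  cam <- fisheye_intrinsics(1200, 1100, 320, 320, l = 2)
  spec1 <- tree_scene_spec(10, h = 12, cam = cam, crown_width = 3)
  s1 <- generate_tree_scene(spec1, render = FALSE)
  fac <- 7.5
  cam_scaled <- fisheye_intrinsics(1200, 1100, 320, 320, l = 2 * fac)
  spec2 <- tree_scene_spec(10 * fac, h = 12 * fac, cam = cam_scaled,
                           crown_width = 3 * fac)
  s2 <- generate_tree_scene(spec2, render = FALSE)
  # identical pixels, scaled measurement
  expect_equal(s1$boxes[, 1:4], s2$boxes[, 1:4], tolerance = 1e-9)
  h1 <- measure_tree_height(s1$boxes, 12, cam, quiet = TRUE)
  h2 <- measure_tree_height(s2$boxes, 12 * fac, cam_scaled, quiet = TRUE)
  expect_equal(h2, fac * h1, tolerance = 1e-9)
})

test_that("batch measurement summarizes relative errors per reference", {
  cam <- fisheye_intrinsics(1000, 1000, 320, 320)
  mk_scene <- function(height, h, seed) {
    generate_tree_scene(tree_scene_spec(height, h = h, cam = cam,
                                        crown_width = height / 4,
                                        seed = seed), render = FALSE)
  }
  s1 <- mk_scene(10, 14, 1)
  s2 <- mk_scene(18, 25, 2)
  annotations <- rbind(cbind(image = "a.png", s1$boxes),
                       cbind(image = "b.png", s2$boxes))
  distances <- data.frame(image = c("a.png", "b.png"), h = c(14, 25),
                          reference_height = c(10, 18))
  res <- suppressMessages(batch_measure(annotations, distances, cam))
  expect_equal(nrow(res$measurements), 2)
  expect_equal(res$measurements$height, c(10, 18), tolerance = 1e-6)
  expect_equal(res$summary[["mean"]],
               mean(res$measurements$relative_error_pct))
  expect_equal(res$summary[["max"]],
               max(res$measurements$relative_error_pct))
  # empty annotations: empty table, no summary
  res3 <- batch_measure(annotations[0, ], distances, cam)
  expect_equal(nrow(res3$measurements), 0)
  expect_null(res3$summary)
  # missing distance row is a configuration error
  expect_error(
    suppressMessages(batch_measure(annotations,
                                   distances[distances$image == "a.png", ],
                                   cam)),
    class = "fisheyetree_configuration_error")
  # low-confidence boxes are filtered before measurement
  ann_low <- annotations
  ann_low$confidence <- c(0.9, 0.2)
  res4 <- suppressMessages(batch_measure(ann_low, distances, cam))
  expect_equal(nrow(res4$measurements), 1)
  expect_equal(res4$measurements$image, "a.png")
})

test_that("a jittered 30-tree batch stays under 2% mean relative error", {
  cam <- fisheye_intrinsics(1000, 1000, 320, 320)
  rows <- lapply(1:30, function(i) {
    height <- 5 + (i %% 10) * 2
    h <- height * 1.3
    s <- generate_tree_scene(
      tree_scene_spec(height, h = h, cam = cam, crown_width = height / 4,
                      box_jitter_sd = 1, seed = 1000 + i), render = FALSE)
    list(ann = cbind(image = sprintf("t%02d.png", i), s$boxes),
         dist = data.frame(image = sprintf("t%02d.png", i), h = h,
                           reference_height = height))
  })
  annotations <- do.call(rbind, lapply(rows, `[[`, "ann"))
  distances <- do.call(rbind, lapply(rows, `[[`, "dist"))
  res <- suppressMessages(batch_measure(annotations, distances, cam))
  expect_equal(nrow(res$measurements), 30)
  expect_lt(res$summary[["mean"]], 2)
})
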