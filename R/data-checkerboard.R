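#' Bundled checkerboard corner-pair verification dataset
#'
#' Corner-pair measurements from a fisheye checkerboard verification
#' experiment: a calibration plate photographed at five camera-to-board
#' distances, with four reference corners A, B, C, D. For each board
#' distance, three corner pairs (AB, AC, AD) are recorded with the raw
#' pixel coordinates of both corners, their board-plane world coordinates
#' recovered through the calibrated fisheye model (mm), and the
#' tape-measured corner separation (mm). Feeding the world-coordinate pairs
#' to [verify_distances()] reproduces the model's distance estimates and
#' relative errors.
#'
#' @return A data frame with one row per corner pair and columns `label`
#'   (pair name), `board_distance` (mm), `u1, v1, u2, v2` (pixel
#'   coordinates of the two corners), `x1, y1, x2, y2` (world coordinates,
#'   mm) and `measured` (reference separation, mm).
#' @examples
#' v <- verify_distances(checkerboard_corner_pairs())
#' v$mean_relative_error_pct
#' @export
checkerboard_corner_pairs <- function() {
  a <- data.frame(
    board_distance = c(320, 612, 993, 1502, 2041),
    u1 = c(898, 1091, 1179, 1374, 1405),
    v1 = c(687, 966, 1160, 1282, 1346),
    x1 = c(-285.0330, -307.0069, -375.2495, -274.3518, -312.3874),
    y1 = c(-375.9156, -388.4370, -395.9568, -401.1987, -422.4221))
  second <- list(
    AB = data.frame(
      u2 = c(810, 1062, 1150, 1358, 1389),
      v2 = c(2290, 2021, 1860, 1766, 1707),
      x2 = c(-300.6751, -310.4134, -394.4027, -292.3145, -338.4833),
      y2 = c(280.2142, 267.7916, 260.9612, 250.6562, 231.5497),
      measured = 650),
    AC = data.frame(
      u2 = c(2414, 2126, 1870, 1850, 1760),
      v2 = c(782, 1000, 1195, 1301, 1365),
      x2 = c(362.2036, 347.9883, 267.0121, 368.0232, 328.3721),
      y2 = c(-347.1019, -369.4865, -352.6874, -377.6071, -387.3684),
      measured = 650),
    AD = data.frame(
      u2 = c(2410, 2086, 1850, 1829, 1741),
      v2 = c(2314, 2065, 1890, 1785, 1723),
      x2 = c(344.7874, 308.7236, 244.6171, 335.5699, 291.7372),
      y2 = c(306.5740, 297.3699, 281.7389, 277.6474, 260.0696),
      measured = 919.238))
  out <- do.call(rbind, lapply(names(second), function(lab) {
    cbind(data.frame(label = lab), a, second[[lab]])
  }))
  rownames(out) <- NULL
  out[, c("label", "board_distance", "u1", "v1", "u2", "v2",
          "x1", "y1", "x2", "y2", "measured")]
}
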