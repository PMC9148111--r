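#' Read and write Pascal-VOC style XML annotations
#'
#' One XML document per image, with `<object><name>` and
#' `<bndbox><xmin>...<ymax>` children. Box coordinates are written exactly
#' as stored (0-based, corners inclusive-exclusive `[min, max)`); an
#' optional `<confidence>` child is read/written when present.
#'
#' @param path XML file path.
#' @return `read_voc_xml()` returns a list with `filename`, `width`,
#'   `height` and `boxes` (a box data frame, possibly 0-row).
#' @export
read_voc_xml <- function(path) {
  if (!file.exists(path)) {
    stop_fisheye(sprintf("annotation file not found: %s", path),
                 "fisheyetree_missing_file")
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop_fisheye(sprintf("cannot parse XML %s: %s", path,
                         conditionMessage(e)),
                 "fisheyetree_parse_error")
  })
  num <- function(node, xp) {
    x <- xml2::xml_find_first(node, xp)
    if (inherits(x, "xml_missing")) NA_real_
    else as.numeric(xml2::xml_text(x))
  }
  txt <- function(node, xp) {
    x <- xml2::xml_find_first(node, xp)
    if (inherits(x, "xml_missing")) NA_character_ else xml2::xml_text(x)
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- if (length(objs) == 0L) {
    data.frame(x_min = numeric(), y_min = numeric(), x_max = numeric(),
               y_max = numeric(), confidence = numeric(),
               label = character())
  } else {
    do.call(rbind, lapply(objs, function(o) {
      data.frame(x_min = num(o, "./bndbox/xmin"),
                 y_min = num(o, "./bndbox/ymin"),
                 x_max = num(o, "./bndbox/xmax"),
                 y_max = num(o, "./bndbox/ymax"),
                 confidence = num(o, "./confidence"),
                 label = txt(o, "./name"))
    }))
  }
  list(filename = txt(doc, "./filename"),
       width = num(doc, "./size/width"),
       height = num(doc, "./size/height"),
       boxes = boxes)
}

#' @param boxes A box data frame (see [bounding_box()]).
#' @param filename Image file name recorded in the annotation.
#' @param width,height Image size in pixels.
#' @rdname read_voc_xml
#' @export
write_voc_xml <- function(boxes, path, filename = "image.png",
                          width = NA, height = NA) {
  boxes <- as.data.frame(boxes)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(width))
  xml2::xml_add_child(size, "height", as.character(height))
  fmt <- function(x) sprintf("%.10g", x)
  for (i in seq_len(nrow(boxes))) {
    o <- xml2::xml_add_child(doc, "object")
    lab <- if (is.null(boxes$label)) "tree" else boxes$label[i]
    xml2::xml_add_child(o, "name", lab)
    if (!is.null(boxes$confidence) && !is.na(boxes$confidence[i])) {
      xml2::xml_add_child(o, "confidence", fmt(boxes$confidence[i]))
    }
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", fmt(boxes$x_min[i]))
    xml2::xml_add_child(bb, "ymin", fmt(boxes$y_min[i]))
    xml2::xml_add_child(bb, "xmax", fmt(boxes$x_max[i]))
    xml2::xml_add_child(bb, "ymax", fmt(boxes$y_max[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read and write images as PNG
#'
#' Thin wrappers around [png::readPNG()] / [png::writePNG()] normalizing to
#' `h x w x 3` arrays in `[0, 1]` (grayscale is expanded, alpha dropped).
#'
#' @param path PNG file path.
#' @param image An array as produced by [generate_tree_scene()] or
#'   [mosaic()].
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) {
    stop_fisheye(sprintf("image not found: %s", path),
                 "fisheyetree_missing_file")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3L] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read annotation and distance tables
#'
#' `read_boxes_csv()` reads a flat annotation table
#' (`image, x_min, y_min, x_max, y_max[, confidence[, label]]`);
#' `read_distances_csv()` reads per-image measurement inputs
#' (`image, h[, reference_height]`).
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_boxes_csv <- function(path) {
  if (!file.exists(path)) {
    stop_fisheye(sprintf("file not found: %s", path),
                 "fisheyetree_missing_file")
  }
  out <- utils::read.csv(path)
  needed <- c("image", "x_min", "y_min", "x_max", "y_max")
  if (!all(needed %in% names(out))) {
    stop_fisheye(sprintf("%s must have columns %s", path,
                         paste(needed, collapse = ", ")),
                 "fisheyetree_invalid_argument")
  }
  out
}

#' @rdname read_boxes_csv
#' @export
read_distances_csv <- function(path) {
  if (!file.exists(path)) {
    stop_fisheye(sprintf("file not found: %s", path),
                 "fisheyetree_missing_file")
  }
  out <- utils::read.csv(path)
  if (!all(c("image", "h") %in% names(out))) {
    stop_fisheye(sprintf("%s must have columns image, h", path),
                 "fisheyetree_invalid_argument")
  }
  out
}
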