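# Reading and writing the standard formats around the pipeline:
# PASCAL-VOC XML annotations, PNG images, MOT-challenge detection streams,
# COCO-JSON detection export, plus the letterbox preprocessing and the
# training-time augmentation.
#
# Coordinate convention: boxes are 0-based half-open floats internally;
# VOC files store 1-based inclusive integer corners and are converted on
# read/write (xmin0 = xmin1 - 1, xmax0 = xmax1, so width = xmax1 - xmin1 + 1).

#' Construct an annotated image
#'
#' @param image `[H, W, 3]` numeric array with values in 0..255, or `NULL`
#'   when only the annotation is carried.
#' @param boxes numeric matrix `[n, 4]` of `(xmin, ymin, xmax, ymax)`.
#' @param labels character vector of class names, one per box.
#' @param size image size `c(W, H)`; taken from `image` when present.
#' @param source_path provenance string.
#' @return object of class `annotated_image`.
#' @export
annotated_image <- function(image = NULL, boxes = matrix(0, 0, 4),
                            labels = character(0), size = NULL,
                            source_path = "") {
  boxes <- matrix(as.numeric(boxes), ncol = 4)
  colnames(boxes) <- c("xmin", "ymin", "xmax", "ymax")
  if (!is.null(image)) size <- c(dim(image)[2], dim(image)[1])
  if (is.null(size)) stop("either image or size must be given")
  if (nrow(boxes) != length(labels)) stop("boxes and labels differ in length")
  if (nrow(boxes)) {
    if (any(boxes[, 1] >= boxes[, 3]) || any(boxes[, 2] >= boxes[, 4])) {
      stop("invalid box: xmax <= xmin or ymax <= ymin")
    }
    if (any(boxes[, 1] < 0) || any(boxes[, 2] < 0) ||
        any(boxes[, 3] > size[1]) || any(boxes[, 4] > size[2])) {
      stop("box outside image bounds")
    }
  }
  structure(list(image = image, boxes = boxes, labels = labels,
                 size = as.numeric(size), source_path = source_path),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat("annotated image ", x$size[1], "x", x$size[2], ", ",
      nrow(x$boxes), " box(es)",
      if (nzchar(x$source_path)) paste0(" [", x$source_path, "]"), "\n", sep = "")
  invisible(x)
}

#' Read a PASCAL-VOC XML annotation
#'
#' Parses the `object` entries whose class name is in `classes`, converting
#' the 1-based inclusive VOC corners to the package's 0-based half-open
#' convention.
#'
#' @param path XML file path.
#' @param classes class names to keep (default `"sheep"`); `NULL` keeps all.
#' @return an [annotated_image()] (without pixels; see the `filename` field
#'   of the XML for the image).
#' @export
read_voc_xml <- function(path, classes = "sheep") {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed VOC XML in '", path, "': ", conditionMessage(e))
  })
  W <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  H <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  objs <- xml2::xml_find_all(doc, "./object")
  boxes <- matrix(0, 0, 4)
  labels <- character(0)
  for (o in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    if (!is.null(classes) && !nm %in% classes) next
    val <- function(tag) {
      as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", tag))))
    }
    b <- c(val("xmin") - 1, val("ymin") - 1, val("xmax"), val("ymax"))
    if (any(is.na(b))) stop("missing bndbox coordinates in '", path, "'")
    if (b[3] <= b[1] || b[4] <= b[2]) {
      stop("invalid box in '", path, "': xmax <= xmin or ymax <= ymin")
    }
    boxes <- rbind(boxes, b)
    labels <- c(labels, nm)
  }
  annotated_image(boxes = boxes, labels = labels, size = c(W, H),
                  source_path = path)
}

#' Write a PASCAL-VOC XML annotation
#'
#' @param ann an [annotated_image()].
#' @param path output XML path.
#' @param filename image file name recorded in the annotation.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(ann, path, filename = basename(ann$source_path)) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(ann$size[1]))
  xml2::xml_add_child(size, "height", format(ann$size[2]))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(ann$boxes))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", ann$labels[i])
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    b <- ann$boxes[i, ]
    xml2::xml_add_child(bb, "xmin", format(round(b[1] + 1)))
    xml2::xml_add_child(bb, "ymin", format(round(b[2] + 1)))
    xml2::xml_add_child(bb, "xmax", format(round(b[3])))
    xml2::xml_add_child(bb, "ymax", format(round(b[4])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read / write an RGB image
#'
#' PNG-backed image IO; pixel values are 0..255 doubles in `[H, W, 3]`.
#' @param path file path.
#' @return `read_image`: numeric array; `write_image`: `path`, invisibly.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE][, , 1:3] * 255
}

#' @rdname read_image
#' @param image `[H, W, 3]` array, values 0..255.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

# nearest-neighbour resize of an [H, W, 3] array
resize_image <- function(image, out_h, out_w) {
  H <- dim(image)[1]; W <- dim(image)[2]
  ri <- pmin(H, pmax(1L, ceiling((seq_len(out_h) - 0.5) * H / out_h)))
  ci <- pmin(W, pmax(1L, ceiling((seq_len(out_w) - 0.5) * W / out_w)))
  image[ri, ci, , drop = FALSE]
}

#' Letterbox an image to a square frame
#'
#' Scales the longest side to `size` preserving aspect ratio, pads the
#' remainder symmetrically with the fill colour, and transforms the boxes
#' by the same scale and offset.
#'
#' @param ann an [annotated_image()] with pixels, or a bare `[H, W, 3]`
#'   array.
#' @param size output side length (default 640).
#' @param fill RGB fill for the padded bands, default `c(114, 114, 114)`.
#' @return list of class `preprocessed_sample` with `image` (`size x size x 3`),
#'   `boxes`, `labels`, `scale`, `pad` (`c(x, y)` offsets) and `orig_size`,
#'   enough to invert the mapping.
#' @export
letterbox <- function(ann, size = 640L, fill = c(114, 114, 114)) {
  if (is.array(ann)) ann <- annotated_image(image = ann)
  if (is.null(ann$image)) stop("letterbox needs pixel data")
  H <- dim(ann$image)[1]; W <- dim(ann$image)[2]
  if (H == 0L || W == 0L) stop("zero-area image")
  r <- size / max(H, W)
  new_h <- round(H * r); new_w <- round(W * r)
  canvas <- array(rep(fill, each = size * size), c(size, size, 3))
  resized <- resize_image(ann$image, new_h, new_w)
  pad_x <- (size - new_w) %/% 2
  pad_y <- (size - new_h) %/% 2
  canvas[pad_y + seq_len(new_h), pad_x + seq_len(new_w), ] <- resized
  boxes <- ann$boxes
  if (nrow(boxes)) {
    boxes[, c(1, 3)] <- boxes[, c(1, 3)] * r + pad_x
    boxes[, c(2, 4)] <- boxes[, c(2, 4)] * r + pad_y
  }
  structure(list(image = canvas, boxes = boxes, labels = ann$labels,
                 scale = r, pad = c(pad_x, pad_y), orig_size = c(W, H),
                 source_path = ann$source_path),
            class = "preprocessed_sample")
}

#' Map letterboxed boxes back to original image coordinates
#'
#' @param sample a `preprocessed_sample` from [letterbox()].
#' @param boxes `[n, 4]` matrix in the letterboxed frame; defaults to the
#'   sample's own boxes.
#' @return `[n, 4]` matrix in original-image pixels.
#' @export
unletterbox_boxes <- function(sample, boxes = sample$boxes) {
  if (!nrow(boxes)) return(boxes)
  boxes[, c(1, 3)] <- (boxes[, c(1, 3)] - sample$pad[1]) / sample$scale
  boxes[, c(2, 4)] <- (boxes[, c(2, 4)] - sample$pad[2]) / sample$scale
  boxes
}

# RGB (0..255) <-> HSV helpers operating on [H, W, 3] arrays
rgb_to_hsv_array <- function(img) {
  m <- grDevices::rgb2hsv(matrix(aperm(img, c(3, 1, 2)), nrow = 3), maxColorValue = 255)
  aperm(array(m, c(3, dim(img)[1], dim(img)[2])), c(2, 3, 1))
}

hsv_to_rgb_array <- function(hsv) {
  h <- pmin(pmax(hsv[, , 1], 0), 1) * 360
  s <- pmin(pmax(hsv[, , 2], 0), 1)
  v <- pmin(pmax(hsv[, , 3], 0), 1)
  c <- v * s
  hp <- h / 60
  x <- c * (1 - abs(hp %% 2 - 1))
  m <- v - c
  r <- g <- b <- array(0, dim(h))
  i <- floor(hp) %% 6
  r[] <- ifelse(i %in% c(0, 5), c, ifelse(i %in% c(1, 4), x, 0))
  g[] <- ifelse(i %in% c(1, 2), c, ifelse(i %in% c(0, 3), x, 0))
  b[] <- ifelse(i %in% c(3, 4), c, ifelse(i %in% c(2, 5), x, 0))
  out <- array(0, c(dim(h), 3))
  out[, , 1] <- (r + m) * 255
  out[, , 2] <- (g + m) * 255
  out[, , 3] <- (b + m) * 255
  out
}

#' Training-time augmentation
#'
#' Random horizontal flip, random scale-crop (crop area uniform in
#' `[0.6, 1]` of the frame, resized back), and bounded HSV colour jitter
#' (gains within ±0.1 hue, ±0.3 saturation, ±0.3 value). Boxes keep a crop
#' only if their center lies inside it; a crop that would lose every box is
#' resampled up to `retries` times, after which the identity crop is used.
#' Fully deterministic given the RNG state.
#'
#' @param sample a `preprocessed_sample` from [letterbox()].
#' @param flip_prob probability of horizontal flip.
#' @param crop_range area fraction range of the random crop.
#' @param hsv_gain jitter half-widths for hue, saturation, value.
#' @param retries resample cap for degenerate crops.
#' @return augmented `preprocessed_sample`.
#' @export
augment <- function(sample, flip_prob = 0.5, crop_range = c(0.6, 1),
                    hsv_gain = c(0.1, 0.3, 0.3), retries = 10L) {
  img <- sample$image
  boxes <- sample$boxes
  size <- dim(img)[1]
  if (runif(1) < flip_prob) {
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    if (nrow(boxes)) {
      x1 <- size - boxes[, 3]; x2 <- size - boxes[, 1]
      boxes[, 1] <- x1; boxes[, 3] <- x2
    }
  }
  for (try in seq_len(retries)) {
    area <- runif(1, crop_range[1], crop_range[2])
    side <- round(size * sqrt(area))
    x0 <- sample.int(size - side + 1L, 1L) - 1L
    y0 <- sample.int(size - side + 1L, 1L) - 1L
    if (!nrow(boxes)) break
    cx <- (boxes[, 1] + boxes[, 3]) / 2
    cy <- (boxes[, 2] + boxes[, 4]) / 2
    inside <- cx >= x0 & cx < x0 + side & cy >= y0 & cy < y0 + side
    if (any(inside)) break
    if (try == retries) { x0 <- 0L; y0 <- 0L; side <- size; inside <- rep(TRUE, nrow(boxes)) }
  }
  if (side < size || x0 > 0L || y0 > 0L) {
    crop <- img[y0 + seq_len(side), x0 + seq_len(side), , drop = FALSE]
    img <- resize_image(crop, size, size)
    r <- size / side
    if (nrow(boxes)) {
      boxes <- boxes[inside, , drop = FALSE]
      labels <- sample$labels[inside]
      boxes[, c(1, 3)] <- pmin(pmax((boxes[, c(1, 3)] - x0) * r, 0), size)
      boxes[, c(2, 4)] <- pmin(pmax((boxes[, c(2, 4)] - y0) * r, 0), size)
      ok <- boxes[, 3] > boxes[, 1] & boxes[, 4] > boxes[, 2]
      boxes <- boxes[ok, , drop = FALSE]
      labels <- labels[ok]
    } else {
      labels <- sample$labels
    }
  } else {
    labels <- if (nrow(boxes)) sample$labels else sample$labels
  }
  hsv <- rgb_to_hsv_array(img)
  g <- stats::runif(3, -hsv_gain, hsv_gain)
  hsv[, , 1] <- (hsv[, , 1] + g[1]) %% 1
  hsv[, , 2] <- pmin(pmax(hsv[, , 2] * (1 + g[2]), 0), 1)
  hsv[, , 3] <- pmin(pmax(hsv[, , 3] * (1 + g[3]), 0), 1)
  img <- hsv_to_rgb_array(hsv)
  out <- sample
  out$image <- img
  out$boxes <- boxes
  out$labels <- labels
  out
}

#' Read / write MOT-challenge detection streams
#'
#' CSV rows `frame,id,x,y,w,h,score,-1,-1,-1` with top-left `x,y` and box
#' width/height in pixels; `id` is -1 for raw detections.
#'
#' @param path CSV file path.
#' @return `read_mot_csv`: data.frame with columns `frame, id, xmin, ymin,
#'   xmax, ymax, score`; `write_mot_csv`: `path`, invisibly.
#' @export
read_mot_csv <- function(path) {
  raw <- utils::read.csv(path, header = FALSE)
  data.frame(frame = as.integer(raw[[1]]), id = as.integer(raw[[2]]),
             xmin = raw[[3]], ymin = raw[[4]],
             xmax = raw[[3]] + raw[[5]], ymax = raw[[4]] + raw[[6]],
             score = raw[[7]])
}

#' @rdname read_mot_csv
#' @param det data.frame with columns `frame, id, xmin, ymin, xmax, ymax,
#'   score` (`id` optional).
#' @export
write_mot_csv <- function(det, path) {
  id <- if ("id" %in% names(det)) det$id else rep(-1L, nrow(det))
  out <- data.frame(det$frame, id, det$xmin, det$ymin,
                    det$xmax - det$xmin, det$ymax - det$ymin,
                    det$score, -1, -1, -1)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Export detections as COCO-JSON results
#'
#' @param dets_list list of box sets, one per image.
#' @param image_ids integer ids parallel to `dets_list`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco_json <- function(dets_list, image_ids, path) {
  rows <- list()
  for (i in seq_along(dets_list)) {
    d <- dets_list[[i]]
    for (j in seq_len(nrow(d))) {
      rows[[length(rows) + 1L]] <- list(
        image_id = image_ids[i], category_id = d$label[j],
        bbox = c(d$xmin[j], d$ymin[j], d$xmax[j] - d$xmin[j], d$ymax[j] - d$ymin[j]),
        score = d$score[j])
    }
  }
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
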