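# Anchor machinery, box geometry, SSD-style decoding and NMS.
#
# Boxes are 0-based half-open [xmin, xmax) x [ymin, ymax) floats in image
# pixel coordinates; a "box set" is a data.frame with columns
# xmin, ymin, xmax, ymax, score, label.

box_set <- function(xmin = numeric(0), ymin = numeric(0),
                    xmax = numeric(0), ymax = numeric(0),
                    score = rep(1, length(xmin)),
                    label = rep(1L, length(xmin))) {
  df <- data.frame(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
                   score = score, label = as.integer(label))
  if (nrow(df) && any(df$xmax <= df$xmin | df$ymax <= df$ymin)) {
    stop("invalid box: xmax <= xmin or ymax <= ymin")
  }
  df
}

empty_box_set <- function() box_set()

#' Anchor boxes for the three pyramid levels
#'
#' Three square anchors per cell at each level, sized
#' `scale * 2^(0/3, 1/3, 2/3)` with base scales per level, centered on the
#' cell centers. Anchor order matches the flattened prediction maps
#' (row fastest, then column, then anchor index).
#'
#' @param model an [sh_ssd()] model (supplies strides and base scales).
#' @param input_size input image size `c(H, W)` in pixels.
#' @return list with per-level matrices and `all`, each `[n, 4]`
#'   `(cx, cy, w, h)`.
#' @export
anchor_grid <- function(model, input_size = c(640L, 640L)) {
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  levels <- lapply(seq_along(model$strides), function(i) {
    s <- model$strides[i]
    Hs <- input_size[1] %/% s
    Ws <- input_size[2] %/% s
    scales <- model$anchor_scales[i] * 2^((0:2) / 3)
    cy <- (seq_len(Hs) - 0.5) * s
    cx <- (seq_len(Ws) - 0.5) * s
    # order: row (y) fastest, then column, then anchor
    do.call(rbind, lapply(scales, function(sc) {
      cbind(cx = rep(cx, each = Hs), cy = rep(cy, Ws), w = sc, h = sc)
    }))
  })
  list(levels = levels, all = do.call(rbind, levels),
       counts = vapply(levels, nrow, integer(1)))
}

cxcywh_to_corners <- function(a) {
  cbind(xmin = a[, 1] - a[, 3] / 2, ymin = a[, 2] - a[, 4] / 2,
        xmax = a[, 1] + a[, 3] / 2, ymax = a[, 2] + a[, 4] / 2)
}

corners_to_cxcywh <- function(b) {
  cbind(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2,
        w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes as `(xmin, ymin, xmax, ymax)` vectors.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

# pairwise IoU matrix between rows of A [n,4] and B [m,4] (corner form)
box_iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  iw <- pmax(0, outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax))
  ih <- pmax(0, outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax))
  inter <- iw * ih
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  u <- outer(areaA, areaB, `+`) - inter
  out <- inter / pmax(u, .Machine$double.eps)
  out[u <= 0] <- 0
  out
}

#' Greedy non-maximum suppression
#'
#' Class-wise greedy suppression: repeatedly keep the highest-scoring box
#' and drop every remaining box of the same class with IoU above the
#' threshold. Ties on score break toward the lower row index (stable).
#'
#' @param dets box set data.frame (`xmin, ymin, xmax, ymax, score, label`).
#' @param iou_thresh suppression threshold (default 0.5).
#' @return the surviving box set, ordered by decreasing score.
#' @export
nms <- function(dets, iou_thresh = 0.5) {
  if (nrow(dets) == 0L) return(dets)
  keep_all <- integer(0)
  for (lb in unique(dets$label)) {
    idx <- which(dets$label == lb)
    ord <- idx[order(-dets$score[idx], idx)]
    B <- as.matrix(dets[, c("xmin", "ymin", "xmax", "ymax")])
    alive <- rep(TRUE, length(ord))
    for (i in seq_along(ord)) {
      if (!alive[i]) next
      keep_all <- c(keep_all, ord[i])
      if (i < length(ord)) {
        rest <- (i + 1):length(ord)
        rest <- rest[alive[rest]]
        if (length(rest)) {
          ious <- box_iou_matrix(B[ord[i], , drop = FALSE], B[ord[rest], , drop = FALSE])
          alive[rest[ious[1, ] > iou_thresh]] <- FALSE
        }
      }
    }
  }
  out <- dets[keep_all, , drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# SSD offset encoding of ground-truth corners against anchors [n,4] cxcywh
encode_boxes <- function(gt_corners, anchors) {
  g <- corners_to_cxcywh(gt_corners)
  cbind(tx = (g[, 1] - anchors[, 1]) / anchors[, 3],
        ty = (g[, 2] - anchors[, 2]) / anchors[, 4],
        tw = log(g[, 3] / anchors[, 3]),
        th = log(g[, 4] / anchors[, 4]))
}

decode_boxes <- function(offsets, anchors) {
  cx <- anchors[, 1] + offsets[, 1] * anchors[, 3]
  cy <- anchors[, 2] + offsets[, 2] * anchors[, 4]
  w <- anchors[, 3] * exp(pmin(offsets[, 3], 10))
  h <- anchors[, 4] * exp(pmin(offsets[, 4], 10))
  cxcywh_to_corners(cbind(cx, cy, w, h))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Flatten one level's raw head maps into per-anchor score and offset
# matrices following the anchor ordering (single sample n).
flatten_level <- function(lvl, A, K, n = 1L) {
  d <- dim(lvl$cls)
  HW <- d[1] * d[2]
  cls <- matrix(0, HW * A, K)
  reg <- matrix(0, HW * A, 4)
  for (a in seq_len(A)) {
    rows <- (a - 1L) * HW + seq_len(HW)
    for (k in seq_len(K)) cls[rows, k] <- as.vector(lvl$cls[, , (a - 1L) * K + k, n])
    for (j in 1:4) reg[rows, j] <- as.vector(lvl$reg[, , (a - 1L) * 4L + j, n])
  }
  list(cls = cls, reg = reg)
}

# Decode raw head outputs for sample n into a thresholded, NMS-filtered
# box set in input-image pixels.
decode_predictions <- function(model, maps, anchors, input_size,
                               score_thresh = 0.05, iou_thresh = 0.5,
                               n = 1L, apply_nms = TRUE) {
  A <- model$anchors_per_cell
  K <- model$num_classes
  flat <- lapply(maps, flatten_level, A = A, K = K, n = n)
  cls <- do.call(rbind, lapply(flat, `[[`, "cls"))
  reg <- do.call(rbind, lapply(flat, `[[`, "reg"))
  scores <- sigmoid(cls)
  best <- max.col(scores, ties.method = "first")
  sc <- scores[cbind(seq_len(nrow(scores)), best)]
  keep <- which(sc >= score_thresh)
  if (!length(keep)) return(empty_box_set())
  boxes <- decode_boxes(reg[keep, , drop = FALSE], anchors$all[keep, , drop = FALSE])
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), input_size[2])
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), input_size[1])
  ok <- boxes[, 3] > boxes[, 1] & boxes[, 4] > boxes[, 2]
  if (!any(ok)) return(empty_box_set())
  dets <- box_set(boxes[ok, 1], boxes[ok, 2], boxes[ok, 3], boxes[ok, 4],
                  score = sc[keep][ok], label = best[keep][ok])
  if (apply_nms) nms(dets, iou_thresh) else dets
}

#' Detect heads in images
#'
#' Runs the detector on one image or a batch and returns detections after
#' score thresholding and greedy NMS.
#'
#' @param object an [sh_ssd()] model.
#' @param newdata image array `[H, W, 3]` (values in `[0, 1]`) or
#'   `[H, W, 3, N]` batch; spatial size divisible by 32.
#' @param score_thresh minimum score (default 0.05 for evaluation; 0.4 is
#'   the recommended cut for tracking input).
#' @param iou_thresh NMS threshold (default 0.5).
#' @param ... unused.
#' @return a box-set data.frame for a single image, or a list of box sets.
#' @export
predict.sh_ssd <- function(object, newdata, score_thresh = 0.05,
                           iou_thresh = 0.5, ...) {
  x <- newdata
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x), 1L)
  maps <- forward_shssd(object, x, train = FALSE)
  anchors <- anchor_grid(object, dim(x)[1:2])
  out <- lapply(seq_len(dim(x)[4]), function(n) {
    decode_predictions(object, maps, anchors, dim(x)[1:2],
                       score_thresh, iou_thresh, n = n)
  })
  if (single) out[[1]] else out
}
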