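# COCO-style precision/recall/AP evaluation.
#
# Detections and ground truths are box-set data.frames; multi-image
# evaluation takes parallel lists (one element per image).

#' Match detections to ground truth at one IoU threshold
#'
#' Detections are visited in decreasing score order; each is matched to the
#' unmatched ground-truth box of highest IoU, provided that IoU reaches the
#' threshold. Matching is one-to-one: duplicates of an already-matched
#' ground truth count as false positives.
#'
#' @param dets,gts box-set data.frames for one image.
#' @param iou_thresh IoU threshold.
#' @return list with counts `TP`, `FP`, `FN` and the per-detection logical
#'   vector `det_tp` (in the original row order of `dets`).
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  nd <- nrow(dets); ng <- nrow(gts)
  det_tp <- logical(nd)
  det_gt <- integer(nd)
  if (nd > 0L && ng > 0L) {
    M <- box_iou_matrix(as.matrix(dets[, 1:4]), as.matrix(gts[, 1:4]))
    gt_used <- logical(ng)
    for (i in order(-dets$score)) {
      cand <- which(!gt_used & M[i, ] >= iou_thresh)
      if (length(cand)) {
        j <- cand[which.max(M[i, cand])]
        gt_used[j] <- TRUE
        det_tp[i] <- TRUE
        det_gt[i] <- j
      }
    }
  }
  list(TP = sum(det_tp), FP = nd - sum(det_tp), FN = ng - sum(det_tp),
       det_tp = det_tp, det_gt = det_gt)
}

#' Precision in percent
#'
#' `P = TP / (TP + FP) * 100`; defined as 0 when no detections were made.
#'
#' @param counts list with `TP` and `FP` (as from [match_detections()]).
#' @return percentage in `[0, 100]`.
#' @export
precision <- function(counts) {
  denom <- counts$TP + counts$FP
  if (denom == 0) return(0)
  100 * counts$TP / denom
}

#' Recall in percent
#'
#' `R = TP / (TP + FN) * 100`; defined as 0 when there is nothing to recall
#' and no true positives.
#'
#' @param counts list with `TP` and `FN`.
#' @return percentage in `[0, 100]`.
#' @export
recall <- function(counts) {
  denom <- counts$TP + counts$FN
  if (denom == 0) return(0)
  100 * counts$TP / denom
}

# Pooled PR points over a list of images at one IoU threshold:
# rank all detections by score, accumulate TP/FP.
pr_points <- function(dets_list, gts_list, iou_thresh) {
  flags <- list(); scores <- list()
  n_gt <- 0L
  for (i in seq_along(gts_list)) {
    d <- dets_list[[i]]; g <- gts_list[[i]]
    n_gt <- n_gt + nrow(g)
    if (nrow(d)) {
      mm <- match_detections(d, g, iou_thresh)
      flags[[length(flags) + 1L]] <- mm$det_tp
      scores[[length(scores) + 1L]] <- d$score
    }
  }
  tp <- unlist(flags); sc <- unlist(scores)
  if (!length(tp) || n_gt == 0L) {
    return(list(precision = numeric(0), recall = numeric(0), n_gt = n_gt))
  }
  ord <- order(-sc)
  ctp <- cumsum(tp[ord]); cfp <- cumsum(!tp[ord])
  list(precision = ctp / (ctp + cfp), recall = ctp / n_gt, n_gt = n_gt)
}

#' Average precision from PR points
#'
#' Area under the precision-recall curve by the 101-point interpolation
#' rule (COCO convention): the precision envelope is sampled at recalls
#' 0, 0.01, ..., 1 and averaged.
#'
#' @param pr list with `precision` and `recall` vectors (parallel,
#'   in increasing-recall order).
#' @return AP in percent.
#' @export
average_precision <- function(pr) {
  p <- pr$precision; r <- pr$recall
  if (!length(p)) return(0)
  # precision envelope: max precision at recall >= r
  env <- rev(cummax(rev(p)))
  grid <- seq(0, 1, by = 0.01)
  idx <- findInterval(grid, r, left.open = TRUE) + 1L  # first point with recall >= grid
  vals <- ifelse(idx <= length(env), env[idx], 0)
  100 * mean(vals)
}

ap_at <- function(dets_list, gts_list, iou_thresh) {
  average_precision(pr_points(dets_list, gts_list, iou_thresh))
}

#' Restrict ground truth (and matched detections) to small targets
#'
#' Keeps ground-truth boxes with area below `max_area` (default 32 x 32);
#' detections whose best match at the given IoU threshold is a removed
#' large ground truth are dropped rather than counted as false positives.
#' @keywords internal
filter_small <- function(dets, gts, max_area = 1024, iou_thresh = 0.5) {
  area <- (gts$xmax - gts$xmin) * (gts$ymax - gts$ymin)
  small <- area < max_area
  keep_det <- rep(TRUE, nrow(dets))
  if (nrow(dets) && any(!small)) {
    mm <- match_detections(dets, gts, iou_thresh)
    keep_det <- !(mm$det_tp & !small[pmax(mm$det_gt, 1L)])
  }
  list(dets = dets[keep_det, , drop = FALSE], gts = gts[small, , drop = FALSE])
}

#' Small-target average precision
#'
#' AP restricted to ground-truth boxes of area below 32 x 32 pixels.
#' Returns `NA` when no image contains a small ground truth.
#'
#' @param dets_list,gts_list parallel lists of box sets.
#' @param iou_thresh IoU threshold (or vector; the mean AP is returned).
#' @return AP in percent, or `NA` for an empty stratum.
#' @export
small_target_ap <- function(dets_list, gts_list, iou_thresh = 0.5) {
  out <- vapply(iou_thresh, function(t) {
    f <- Map(filter_small, dets_list, gts_list,
             MoreArgs = list(iou_thresh = t))
    gts <- lapply(f, `[[`, "gts")
    if (sum(vapply(gts, nrow, integer(1))) == 0L) return(NA_real_)
    ap_at(lapply(f, `[[`, "dets"), gts, t)
  }, numeric(1))
  mean(out)
}

#' Full detection evaluation
#'
#' Computes precision and recall at a score cut, AP at IoU 0.5, the COCO
#' AP over IoU 0.5:0.95 (ten thresholds), and the small-target AP.
#'
#' @param dets_list,gts_list parallel lists of box sets (one per image).
#' @param score_cut score threshold for the P/R operating point.
#' @return list with `P`, `R`, `AP50`, `AP50_95`, `APs`, and per-threshold
#'   APs in `AP_by_thresh`.
#' @export
evaluate_detections <- function(dets_list, gts_list, score_cut = 0.5) {
  threshs <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(threshs, function(t) ap_at(dets_list, gts_list, t), numeric(1))
  cut_dets <- lapply(dets_list, function(d) d[d$score >= score_cut, , drop = FALSE])
  counts <- Map(match_detections, cut_dets, gts_list, MoreArgs = list(iou_thresh = 0.5))
  tot <- list(TP = sum(vapply(counts, `[[`, numeric(1), "TP")),
              FP = sum(vapply(counts, `[[`, numeric(1), "FP")),
              FN = sum(vapply(counts, `[[`, numeric(1), "FN")))
  list(P = precision(tot), R = recall(tot),
       AP50 = aps[1], AP50_95 = mean(aps),
       APs = small_target_ap(dets_list, gts_list, threshs),
       AP_by_thresh = stats::setNames(aps, threshs))
}

#' Throughput of a detector function
#'
#' Frames per second: `FPS = M / S`, the number of images `M` processed
#' divided by the elapsed time `S` in seconds. Hardware dependent; provided
#' as a utility, not an evaluation target.
#'
#' @param fn function of one image.
#' @param images list of images.
#' @return frames per second (numeric).
#' @export
measure_fps <- function(fn, images) {
  S <- system.time(for (img in images) fn(img))[["elapsed"]]
  M <- length(images)
  if (S <= 0) return(Inf)
  M / S
}
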