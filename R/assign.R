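# Training-time dynamic sample matching and the detection loss.
#
# The matching rule is a documented SimOTA-style reconstruction of dynamic
# sample matching (the strategy adapts positives to the current
# predictions rather than fixed IoU rules): candidate anchors are those
# whose center lies in a ground-truth box or its center region; the
# assignment cost combines the classification loss and the localization
# quality; the number of positives per ground truth adapts to how many
# predictions already overlap it.

#' Dynamic sample matching
#'
#' For each ground-truth box, candidate anchors are those whose center
#' falls inside the box or within `center_radius` cells of its center.
#' Each candidate's cost is `BCE(pred score, target) +
#' lambda * (-log IoU(pred box, gt))`; the ground truth takes its
#' `k = clamp(floor(sum of top-10 candidate IoUs), 1, 10)` lowest-cost
#' candidates, and an anchor claimed by several ground truths goes to the
#' one with the lowest cost.
#'
#' @param pred_boxes decoded predicted boxes `[n, 4]` (corners).
#' @param pred_scores predicted class probabilities `[n, K]` (sigmoid).
#' @param gt ground-truth box set (`xmin..ymax`, `label`).
#' @param anchors anchor matrix `[n, 4]` `(cx, cy, w, h)`.
#' @param anchor_strides per-anchor stride vector (cell size in pixels).
#' @param lambda weight of the localization term (default 3).
#' @param center_radius center-region half-width in cells (default 2.5).
#' @param k_max cap on the per-ground-truth positive budget (default 10).
#' @param ignore_band when `TRUE`, candidate anchors that were not
#'   selected as positives are marked `ignore` and get no classification
#'   target this step. Off by default: unselected candidates then drift to
#'   high scores while their regression stays untrained, producing
#'   confident mislocalized duplicates.
#' @param level_restrict when `TRUE` (default), a ground truth draws
#'   candidates only from the pyramid level whose base anchor scale is
#'   closest (in log ratio) to the box size, preventing the same head from
#'   being supervised as positive at several scales and then detected
#'   twice by boxes too dissimilar for NMS to merge.
#' @return list of class `assignment`: `label` (0 = negative, otherwise the
#'   1-based ground-truth index), `targets` (encoded offsets, rows for
#'   positive anchors), `pos` (positive anchor indices), and `cost`
#'   diagnostics.
#' @export
dynamic_match <- function(pred_boxes, pred_scores, gt, anchors,
                          anchor_strides, lambda = 3, center_radius = 2.5,
                          level_restrict = TRUE,
                          loc_iou = c("pred", "anchor"), k_max = 10L,
                          ignore_band = FALSE) {
  loc_iou <- match.arg(loc_iou)
  n <- nrow(anchors)
  K <- ncol(pred_scores)
  label <- integer(n)
  ng <- nrow(gt)
  if (ng == 0L) {
    return(structure(list(label = label, targets = NULL, pos = integer(0),
                          ignore = integer(0), cost = NULL),
                     class = "assignment"))
  }
  gtb <- as.matrix(gt[, c("xmin", "ymin", "xmax", "ymax")])
  gcx <- (gtb[, 1] + gtb[, 3]) / 2
  gcy <- (gtb[, 2] + gtb[, 4]) / 2
  acx <- anchors[, 1]; acy <- anchors[, 2]
  eps <- 1e-8
  # base anchor scale of each anchor's level (scale = 4 x stride here)
  scales <- 4 * anchor_strides
  lvls <- sort(unique(scales))
  cand <- matrix(FALSE, n, ng)
  for (g in seq_len(ng)) {
    in_box <- acx >= gtb[g, 1] & acx < gtb[g, 3] & acy >= gtb[g, 2] & acy < gtb[g, 4]
    r <- center_radius * anchor_strides
    in_ctr <- abs(acx - gcx[g]) <= r & abs(acy - gcy[g]) <= r
    ok <- in_box | in_ctr
    if (level_restrict && length(lvls) > 1L) {
      s <- sqrt((gtb[g, 3] - gtb[g, 1]) * (gtb[g, 4] - gtb[g, 2]))
      best <- lvls[which.min(abs(log(s / lvls)))]
      ok <- ok & scales == best
    }
    cand[, g] <- ok
  }
  loc_boxes <- if (loc_iou == "anchor") cxcywh_to_corners(anchors) else pred_boxes
  iou_m <- box_iou_matrix(loc_boxes, gtb)    # n x ng
  # per-candidate cost
  cost <- matrix(Inf, n, ng)
  for (g in seq_len(ng)) {
    ci <- which(cand[, g])
    if (!length(ci)) next
    tgt <- numeric(K)
    tgt[gt$label[g]] <- 1
    p <- pmin(pmax(pred_scores[ci, , drop = FALSE], 1e-7), 1 - 1e-7)
    bce <- -(matrix(tgt, length(ci), K, byrow = TRUE) * log(p) +
               (1 - matrix(tgt, length(ci), K, byrow = TRUE)) * log(1 - p))
    cost[ci, g] <- rowSums(bce) + lambda * (-log(iou_m[ci, g] + eps))
  }
  # dynamic k and provisional selection
  claim_cost <- rep(Inf, n)
  for (g in seq_len(ng)) {
    ci <- which(cand[, g])
    if (!length(ci)) next
    ious <- sort(iou_m[ci, g], decreasing = TRUE)
    k <- min(max(1L, floor(sum(ious[seq_len(min(10L, length(ious)))]))), k_max, length(ci))
    sel <- ci[order(cost[ci, g])][seq_len(k)]
    for (a in sel) {
      if (cost[a, g] < claim_cost[a]) {   # conflict: lowest cost wins
        label[a] <- g
        claim_cost[a] <- cost[a, g]
      }
    }
  }
  # every ground truth with candidates keeps at least one positive; orphans
  # are rescued cheapest-first (canonical order, independent of gt order)
  repeat {
    orphans <- Filter(function(g) {
      !any(label == g) && any(cand[, g] & label == 0L)
    }, seq_len(ng))
    if (!length(orphans)) break
    rescue <- vapply(orphans, function(g) {
      min(cost[cand[, g] & label == 0L, g])
    }, numeric(1))
    g <- orphans[which.min(rescue)]
    ci <- which(cand[, g] & label == 0L)
    label[ci[which.min(cost[ci, g])]] <- g
  }
  pos <- which(label > 0L)
  ignore <- integer(0)
  if (ignore_band) ignore <- setdiff(which(rowSums(cand) > 0), pos)
  targets <- NULL
  if (length(pos)) {
    targets <- encode_boxes(gtb[label[pos], , drop = FALSE],
                            anchors[pos, , drop = FALSE])
  }
  structure(list(label = label, targets = targets, pos = pos,
                 ignore = ignore, cost = cost),
            class = "assignment")
}

smooth_l1 <- function(d, beta = 1) {
  ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
}

smooth_l1_grad <- function(d, beta = 1) {
  ifelse(abs(d) < beta, d / beta, sign(d))
}

#' Detection loss with hard-negative mining
#'
#' Classification: per-anchor, per-class binary cross-entropy on logits;
#' negatives are mined at `neg_ratio` : 1 against the positive count
#' (highest-loss negatives kept); anchors in the assignment's ignore band
#' receive no classification supervision. Regression: smooth-L1 between
#' predicted offsets and the encoded targets of positive anchors. Both
#' terms are normalized by the positive count.
#'
#' @param cls_logits `[n, K]` raw classification outputs.
#' @param reg_preds `[n, 4]` raw regression outputs.
#' @param assignment an [dynamic_match()] result.
#' @param gt_labels ground-truth class labels (indexed by assignment).
#' @param neg_ratio mined negatives per positive (default 3).
#' @return list `cls_loss`, `reg_loss`, and gradients `dcls` `[n, K]`,
#'   `dreg` `[n, 4]`.
#' @export
detection_loss <- function(cls_logits, reg_preds, assignment, gt_labels,
                           neg_ratio = 3) {
  n <- nrow(cls_logits); K <- ncol(cls_logits)
  pos <- assignment$pos
  n_pos <- length(pos)
  tgt <- matrix(0, n, K)
  if (n_pos) tgt[cbind(pos, gt_labels[assignment$label[pos]])] <- 1
  p <- sigmoid(cls_logits)
  bce <- -(tgt * log(pmax(p, 1e-12)) + (1 - tgt) * log(pmax(1 - p, 1e-12)))
  anchor_loss <- rowSums(bce)
  neg <- setdiff(seq_len(n), c(pos, assignment$ignore))
  n_neg_keep <- min(length(neg), neg_ratio * max(1L, n_pos))
  neg_keep <- neg[order(-anchor_loss[neg])][seq_len(n_neg_keep)]
  active <- c(pos, neg_keep)
  norm <- max(1L, n_pos)
  cls_loss <- sum(anchor_loss[active]) / norm
  dcls <- matrix(0, n, K)
  dcls[active, ] <- (p - tgt)[active, , drop = FALSE] / norm
  reg_loss <- 0
  dreg <- matrix(0, n, 4)
  if (n_pos) {
    d <- reg_preds[pos, , drop = FALSE] - assignment$targets
    reg_loss <- sum(smooth_l1(d)) / norm
    dreg[pos, ] <- smooth_l1_grad(d) / norm
  }
  list(cls_loss = cls_loss, reg_loss = reg_loss, dcls = dcls, dreg = dreg)
}
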