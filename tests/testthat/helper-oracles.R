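# Independent brute-force / textbook oracles used to cross-check the
# package implementations. These deliberately share no code with R/.

# greedy NMS by direct O(M^2) pairwise suppression
brute_nms <- function(dets, iou_thresh) {
  n <- nrow(dets)
  if (n == 0L) return(integer(0))
  ord <- order(-dets$score, seq_len(n))
  alive <- rep(TRUE, n)
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    for (j in ord) {
      if (!alive[j] || j == i) next
      if (dets$label[j] != dets$label[i]) next
      a <- as.numeric(dets[i, 1:4]); b <- as.numeric(dets[j, 1:4])
      iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
      ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
      inter <- iw * ih
      uni <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
      if (uni > 0 && inter / uni > iou_thresh) alive[j] <- FALSE
    }
  }
  sort(kept)
}

# exhaustive minimum-cost assignment by permutation enumeration
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

brute_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost); k <- min(n, m)
  best <- Inf
  for (rows in utils::combn(seq_len(n), k, simplify = FALSE)) {
    for (cols in utils::combn(seq_len(m), k, simplify = FALSE)) {
      for (p in all_perms(cols)) {
        v <- sum(cost[cbind(rows, p)])
        if (v < best) best <- v
      }
    }
  }
  best
}

# textbook Kalman filter with the same model matrices, written directly
textbook_kalman <- function(zs) {
  wp <- 1 / 20; wv <- 1 / 160
  Fm <- diag(8); Fm[cbind(1:4, 5:8)] <- 1
  Hm <- cbind(diag(4), matrix(0, 4, 4))
  h0 <- max(zs[1, 4], 1e-3)
  std0 <- c(2 * wp * h0, 2 * wp * h0, 1e-2, 2 * wp * h0,
            10 * wv * h0, 10 * wv * h0, 1e-5, 10 * wv * h0)
  mean <- c(zs[1, ], rep(0, 4))
  P <- diag(std0^2)
  means <- matrix(0, nrow(zs), 8)
  means[1, ] <- mean
  for (t in 2:nrow(zs)) {
    h <- max(mean[4], 1e-3)
    q <- c(wp * h, wp * h, 1e-2, wp * h, wv * h, wv * h, 1e-5, wv * h)
    mean <- as.numeric(Fm %*% mean)
    P <- Fm %*% P %*% t(Fm) + diag(q^2)
    h <- max(mean[4], 1e-3)
    r <- c(wp * h, wp * h, 1e-1, wp * h)
    S <- Hm %*% P %*% t(Hm) + diag(r^2)
    K <- P %*% t(Hm) %*% solve(S)
    mean <- as.numeric(mean + K %*% (zs[t, ] - Hm %*% mean))
    mean[4] <- max(mean[4], 1e-3)
    P <- (diag(8) - K %*% Hm) %*% P
    P <- (P + t(P)) / 2
    means[t, ] <- mean
  }
  means
}

# direct sliding-window maximum over k x k windows (stride 1, same padding)
brute_window_max <- function(x, k) {
  d <- dim(x)
  pad <- k %/% 2
  y <- array(0, d)
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    for (w in seq_len(d[2])) for (h in seq_len(d[1])) {
      hs <- max(1, h - pad):min(d[1], h + pad)
      ws <- max(1, w - pad):min(d[2], w + pad)
      y[h, w, c, n] <- max(x[hs, ws, c, n])
    }
  }
  y
}

# area under a piecewise-constant P(R) curve by fine rectangle integration
# of the precision envelope (independent of the 101-point implementation)
rect_ap <- function(prec, rec, dr = 1e-3) {
  env <- rev(cummax(rev(prec)))
  grid <- seq(0, 1, by = dr)
  vals <- vapply(grid, function(g) {
    i <- which(rec >= g - 1e-12)
    if (length(i)) env[min(i)] else 0
  }, numeric(1))
  100 * mean(vals)
}

# independent direct implementation of the dynamic matching rule
oracle_dynamic_match <- function(pred_boxes, pred_scores, gt, anchors,
                                 strides, lambda = 3, radius = 2.5,
                                 loc_iou = "pred") {
  n <- nrow(anchors); ng <- nrow(gt)
  label <- integer(n)
  if (ng == 0) return(label)
  cost <- matrix(Inf, n, ng)
  iou_m <- matrix(0, n, ng)
  lvls <- sort(unique(4 * strides))
  for (a in seq_len(n)) for (g in seq_len(ng)) {
    gb <- as.numeric(gt[g, c("xmin", "ymin", "xmax", "ymax")])
    lb <- if (loc_iou == "anchor") {
      c(anchors[a, 1] - anchors[a, 3] / 2, anchors[a, 2] - anchors[a, 4] / 2,
        anchors[a, 1] + anchors[a, 3] / 2, anchors[a, 2] + anchors[a, 4] / 2)
    } else pred_boxes[a, ]
    iou_m[a, g] <- shssd::iou(lb, gb)
    cx <- anchors[a, 1]; cy <- anchors[a, 2]
    gcx <- (gb[1] + gb[3]) / 2; gcy <- (gb[2] + gb[4]) / 2
    inb <- cx >= gb[1] && cx < gb[3] && cy >= gb[2] && cy < gb[4]
    inc <- abs(cx - gcx) <= radius * strides[a] && abs(cy - gcy) <= radius * strides[a]
    s_gt <- sqrt((gb[3] - gb[1]) * (gb[4] - gb[2]))
    lv_ok <- length(lvls) == 1L ||
      4 * strides[a] == lvls[which.min(abs(log(s_gt / lvls)))]
    if ((inb || inc) && lv_ok) {
      p <- pmin(pmax(pred_scores[a, ], 1e-7), 1 - 1e-7)
      tgt <- numeric(length(p)); tgt[gt$label[g]] <- 1
      bce <- sum(-(tgt * log(p) + (1 - tgt) * log(1 - p)))
      cost[a, g] <- bce + lambda * (-log(iou_m[a, g] + 1e-8))
    }
  }
  claim <- rep(Inf, n)
  for (g in seq_len(ng)) {
    ci <- which(is.finite(cost[, g]))
    if (!length(ci)) next
    ious <- sort(iou_m[ci, g], decreasing = TRUE)
    k <- min(max(1, floor(sum(ious[seq_len(min(10, length(ious)))]))), 10, length(ci))
    sel <- ci[order(cost[ci, g])][seq_len(k)]
    for (a in sel) if (cost[a, g] < claim[a]) { label[a] <- g; claim[a] <- cost[a, g] }
  }
  repeat {
    orphans <- Filter(function(g) {
      !any(label == g) && any(is.finite(cost[, g]) & label == 0L)
    }, seq_len(ng))
    if (!length(orphans)) break
    rescue <- vapply(orphans, function(g) {
      min(cost[is.finite(cost[, g]) & label == 0L, g])
    }, numeric(1))
    g <- orphans[which.min(rescue)]
    ci <- which(is.finite(cost[, g]) & label == 0L)
    label[ci[which.min(cost[ci, g])]] <- g
  }
  label
}

# constant-velocity fully visible synthetic detection stream (no clipping)
linear_detections <- function(n_targets, n_frames, W = 400, H = 400,
                              speed = 3, size = 40) {
  xs <- seq(60, W - 60, length.out = max(n_targets, 2))[seq_len(n_targets)]
  lapply(seq_len(n_frames), function(f) {
    cy <- 60 + speed * (f - 1)
    data.frame(xmin = xs - size / 2, ymin = cy - size / 2,
               xmax = xs + size / 2, ymax = cy + size / 2,
               score = 0.95, label = 1L)
  })
}
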