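# DeepSort-style multi-object tracking: constant-velocity Kalman filter on
# (cx, cy, aspect, h), appearance-aided cascade association solved by the
# Hungarian algorithm, and IoU association for the remainder.

# --- Kalman filter (standard DeepSort parametrization) -------------------

KF_WP <- 1 / 20   # position std weight, relative to box height
KF_WV <- 1 / 160  # velocity std weight

kf_F <- function() {
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- 1
  F
}
kf_H <- function() cbind(diag(4), matrix(0, 4, 4))

#' Initialize a Kalman state from a measurement
#'
#' State is the 8-vector `(cx, cy, a, h, vcx, vcy, va, vh)` with `a` the
#' width/height aspect ratio; uncertainties scale with box height.
#'
#' @param z measurement `(cx, cy, a, h)`.
#' @return list with `mean` (8-vector) and `cov` (8x8 matrix).
#' @export
kalman_init <- function(z) {
  h <- max(z[4], 1e-3)
  std <- c(2 * KF_WP * h, 2 * KF_WP * h, 1e-2, 2 * KF_WP * h,
           10 * KF_WV * h, 10 * KF_WV * h, 1e-5, 10 * KF_WV * h)
  list(mean = c(z, rep(0, 4)), cov = diag(std^2))
}

#' Kalman predict step
#'
#' Advances the state one frame under the constant-velocity model and
#' inflates the covariance with process noise.
#'
#' @param s state list (`mean`, `cov`).
#' @return predicted state.
#' @export
kalman_predict <- function(s) {
  h <- max(s$mean[4], 1e-3)
  std <- c(KF_WP * h, KF_WP * h, 1e-2, KF_WP * h,
           KF_WV * h, KF_WV * h, 1e-5, KF_WV * h)
  F <- kf_F()
  list(mean = as.numeric(F %*% s$mean),
       cov = F %*% s$cov %*% t(F) + diag(std^2))
}

#' Kalman update step
#'
#' Standard Kalman gain update against a box measurement.
#'
#' @param s predicted state.
#' @param z measurement `(cx, cy, a, h)`.
#' @return updated state.
#' @export
kalman_update <- function(s, z) {
  h <- max(s$mean[4], 1e-3)
  Rm <- diag(c(KF_WP * h, KF_WP * h, 1e-1, KF_WP * h)^2)
  Hm <- kf_H()
  S <- Hm %*% s$cov %*% t(Hm) + Rm
  K <- s$cov %*% t(Hm) %*% solve(S)
  innov <- z - as.numeric(Hm %*% s$mean)
  mean <- as.numeric(s$mean + K %*% innov)
  cov <- (diag(8) - K %*% Hm) %*% s$cov
  cov <- (cov + t(cov)) / 2
  mean[4] <- max(mean[4], 1e-3)
  list(mean = mean, cov = cov)
}

# squared Mahalanobis distance of measurements (rows of Z) from the
# predicted measurement distribution of state s
kalman_gating_distance <- function(s, Z) {
  h <- max(s$mean[4], 1e-3)
  Rm <- diag(c(KF_WP * h, KF_WP * h, 1e-1, KF_WP * h)^2)
  Hm <- kf_H()
  S <- Hm %*% s$cov %*% t(Hm) + Rm
  mu <- as.numeric(Hm %*% s$mean)
  d <- sweep(Z, 2, mu)
  rowSums((d %*% solve(S)) * d)
}

box_to_z <- function(b) {
  w <- b[3] - b[1]; h <- b[4] - b[2]
  c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2, w / max(h, 1e-6), h)
}

z_to_box <- function(z) {
  w <- z[3] * z[4]; h <- z[4]
  c(z[1] - w / 2, z[2] - h / 2, z[1] + w / 2, z[2] + h / 2)
}

# --- Hungarian algorithm -------------------------------------------------

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Jonker-Volgenant style shortest augmenting path solution of the linear
#' assignment problem on an `n x m` cost matrix (rows assigned to distinct
#' columns; with `n > m` some rows stay unassigned, handled by square
#' padding with a large finite cost).
#'
#' @param cost numeric matrix; `Inf` marks forbidden pairs.
#' @return integer vector of length `nrow(cost)`: assigned column per row,
#'   `NA` for unassigned/forbidden.
#' @export
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  sz <- max(n, m)
  BIG <- if (all(!is.finite(cost))) 1 else max(abs(cost[is.finite(cost)])) * sz + 1
  C <- matrix(BIG, sz, sz)
  fin <- is.finite(cost)
  C[seq_len(n), seq_len(m)][fin] <- cost[fin]
  # shortest augmenting path (lawler / jonker-volgenant), 1-based
  u <- numeric(sz + 1); v <- numeric(sz + 1)
  p <- integer(sz + 1)      # p[j]: row assigned to column j (0 = none)
  way <- integer(sz + 1)
  for (i in seq_len(sz)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, sz + 1)
    used <- rep(FALSE, sz + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(sz) + 1L) {
        if (used[j]) next
        cur <- C[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(sz + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (j in seq_len(sz) + 1L) {
    r <- p[j]
    if (r >= 1L && r <= n && (j - 1L) <= m) {
      if (is.finite(cost[r, j - 1L])) assign[r] <- j - 1L
    }
  }
  assign
}

# --- appearance embedding ------------------------------------------------

#' RGB histogram appearance embedding of a box crop
#'
#' 8 x 8 x 8 joint RGB histogram of the crop, L2-normalized; a trained
#' re-identification network can be plugged in instead via the tracker's
#' `embed` argument.
#'
#' @param image `[H, W, 3]` array, values 0..255.
#' @param box `(xmin, ymin, xmax, ymax)`.
#' @param bins histogram bins per channel.
#' @return numeric vector of length `bins^3` with unit L2 norm.
#' @export
rgb_hist_embedding <- function(image, box, bins = 8L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  x0 <- max(1L, floor(box[1]) + 1L); x1 <- min(W, ceiling(box[3]))
  y0 <- max(1L, floor(box[2]) + 1L); y1 <- min(H, ceiling(box[4]))
  out <- numeric(bins^3)
  if (x1 < x0 || y1 < y0) return(out)
  crop <- image[y0:y1, x0:x1, , drop = FALSE]
  q <- pmin(floor(crop / 256 * bins), bins - 1L)
  idx <- q[, , 1] + bins * q[, , 2] + bins * bins * q[, , 3] + 1
  tab <- tabulate(as.integer(idx), nbins = bins^3)
  nrm <- sqrt(sum(tab^2))
  if (nrm > 0) tab / nrm else out
}

cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  1 - sum(a * b) / (na * nb)
}

# --- tracker -------------------------------------------------------------

#' Create a multi-object tracker
#'
#' DeepSort-style tracker: tracks carry a Kalman state and a lifecycle
#' (`tentative` until `n_init` consecutive hits, `confirmed`, then deleted
#' after `max_age` missed frames; tentative tracks are dropped on their
#' first miss). Confirmed tracks are associated first, in a cascade over
#' time since last update, with cost
#' `(1 - appearance_weight) * normalized Mahalanobis + appearance_weight *
#' cosine appearance distance`, gated at the 0.99 chi-square quantile
#' (4 dof); leftovers fall back to IoU association.
#'
#' @param max_age frames a confirmed track survives without detections.
#' @param n_init consecutive hits required to confirm a track.
#' @param appearance_weight weight of the appearance term (0 disables it;
#'   it is also ignored when no frame pixels are supplied).
#' @param iou_thresh minimum IoU for the fallback association.
#' @param embed embedding function `(image, box) -> vector`.
#' @return object of class `sheep_tracker`.
#' @export
sheep_tracker <- function(max_age = 30L, n_init = 3L,
                          appearance_weight = 0.2, iou_thresh = 0.3,
                          embed = rgb_hist_embedding) {
  structure(list(tracks = list(), next_id = 1L, frame = 0L,
                 max_age = as.integer(max_age), n_init = as.integer(n_init),
                 w_app = appearance_weight, iou_thresh = iou_thresh,
                 gate = stats::qchisq(0.99, df = 4), embed = embed),
            class = "sheep_tracker")
}

#' @export
print.sheep_tracker <- function(x, ...) {
  st <- vapply(x$tracks, `[[`, character(1), "status")
  cat("tracker at frame ", x$frame, ": ", sum(st == "confirmed"),
      " confirmed / ", sum(st == "tentative"), " tentative track(s), ",
      x$next_id - 1L, " id(s) issued\n", sep = "")
  invisible(x)
}

new_track <- function(id, det_box, embedding = NULL) {
  z <- box_to_z(det_box)
  list(id = id, state = kalman_init(z), status = "tentative",
       hits = 1L, age = 1L, time_since_update = 0L,
       embedding = embedding)
}

track_box <- function(tr) z_to_box(tr$state$mean[1:4])

#' Associate current detections with tracks
#'
#' Implements the association cascade described in [sheep_tracker()];
#' exposed separately for testing.
#'
#' @param tracker a `sheep_tracker`.
#' @param dets box-set data.frame.
#' @param embeddings optional list of detection embeddings.
#' @return list `matches` (2-column matrix of track index, det index),
#'   `unmatched_tracks`, `unmatched_dets`.
#' @export
associate <- function(tracker, dets, embeddings = NULL) {
  nt <- length(tracker$tracks); nd <- nrow(dets)
  if (nt == 0L || nd == 0L) {
    return(list(matches = matrix(0L, 0, 2),
                unmatched_tracks = seq_len(nt), unmatched_dets = seq_len(nd)))
  }
  Z <- t(apply(as.matrix(dets[, c("xmin", "ymin", "xmax", "ymax")]), 1, box_to_z))
  matches <- matrix(0L, 0, 2)
  rem_d <- seq_len(nd)
  st <- vapply(tracker$tracks, `[[`, character(1), "status")
  tsu <- vapply(tracker$tracks, `[[`, integer(1), "time_since_update")
  confirmed <- which(st == "confirmed")
  # cascade: most recently updated confirmed tracks first
  for (level in sort(unique(tsu[confirmed]))) {
    ti <- confirmed[tsu[confirmed] == level]
    if (!length(ti) || !length(rem_d)) next
    cost <- matrix(Inf, length(ti), length(rem_d))
    for (a in seq_along(ti)) {
      tr <- tracker$tracks[[ti[a]]]
      md <- kalman_gating_distance(tr$state, Z[rem_d, , drop = FALSE])
      ok <- md <= tracker$gate
      cc <- md / tracker$gate
      if (!is.null(embeddings) && !is.null(tr$embedding) && tracker$w_app > 0) {
        appd <- vapply(rem_d, function(j) cosine_distance(tr$embedding, embeddings[[j]]),
                       numeric(1))
        cc <- (1 - tracker$w_app) * cc + tracker$w_app * appd
      }
      cost[a, ok] <- cc[ok]
    }
    asg <- hungarian(cost)
    for (a in seq_along(asg)) {
      if (!is.na(asg[a])) {
        matches <- rbind(matches, c(ti[a], rem_d[asg[a]]))
      }
    }
    if (length(matches)) rem_d <- setdiff(seq_len(nd), matches[, 2])
  }
  # IoU fallback: tentative tracks + confirmed tracks missed exactly once
  matched_t <- if (nrow(matches)) matches[, 1] else integer(0)
  iou_t <- setdiff(which(st == "tentative" | tsu <= 1L), matched_t)
  if (length(iou_t) && length(rem_d)) {
    TB <- do.call(rbind, lapply(tracker$tracks[iou_t], track_box))
    DB <- as.matrix(dets[rem_d, c("xmin", "ymin", "xmax", "ymax")])
    M <- box_iou_matrix(TB, DB)
    cost <- 1 - M
    cost[M < tracker$iou_thresh] <- Inf
    asg <- hungarian(cost)
    for (a in seq_along(asg)) {
      if (!is.na(asg[a])) matches <- rbind(matches, c(iou_t[a], rem_d[asg[a]]))
    }
    if (nrow(matches)) rem_d <- setdiff(seq_len(nd), matches[, 2])
  }
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), if (nrow(matches)) matches[, 1] else integer(0)),
       unmatched_dets = rem_d)
}

#' Advance the tracker by one frame
#'
#' Predict, associate, update matched tracks, age and retire missed ones,
#' and spawn tentative tracks for unmatched detections.
#'
#' @param tracker a `sheep_tracker`.
#' @param dets box-set data.frame of this frame's detections.
#' @param image optional `[H, W, 3]` frame pixels enabling the appearance
#'   term.
#' @return list with the updated `tracker` and `tracks`, a data.frame of
#'   confirmed tracks (`id, xmin, ymin, xmax, ymax`).
#' @export
tracker_step <- function(tracker, dets, image = NULL) {
  tracker$frame <- tracker$frame + 1L
  for (i in seq_along(tracker$tracks)) {
    tracker$tracks[[i]]$state <- kalman_predict(tracker$tracks[[i]]$state)
    tracker$tracks[[i]]$age <- tracker$tracks[[i]]$age + 1L
    tracker$tracks[[i]]$time_since_update <- tracker$tracks[[i]]$time_since_update + 1L
  }
  embeddings <- NULL
  if (!is.null(image) && nrow(dets) && tracker$w_app > 0) {
    embeddings <- lapply(seq_len(nrow(dets)), function(j) {
      tracker$embed(image, as.numeric(dets[j, c("xmin", "ymin", "xmax", "ymax")]))
    })
  }
  as <- associate(tracker, dets, embeddings)
  for (k in seq_len(nrow(as$matches))) {
    ti <- as$matches[k, 1]; dj <- as$matches[k, 2]
    z <- box_to_z(as.numeric(dets[dj, c("xmin", "ymin", "xmax", "ymax")]))
    tr <- tracker$tracks[[ti]]
    tr$state <- kalman_update(tr$state, z)
    tr$hits <- tr$hits + 1L
    tr$time_since_update <- 0L
    if (tr$status == "tentative" && tr$hits >= tracker$n_init) tr$status <- "confirmed"
    if (!is.null(embeddings)) {
      e <- embeddings[[dj]]
      tr$embedding <- if (is.null(tr$embedding)) e else {
        v <- 0.9 * tr$embedding + 0.1 * e
        v / max(sqrt(sum(v^2)), 1e-12)
      }
    }
    tracker$tracks[[ti]] <- tr
  }
  # lifecycle of missed tracks
  drop <- logical(length(tracker$tracks))
  for (i in as$unmatched_tracks) {
    tr <- tracker$tracks[[i]]
    if (tr$status == "tentative" ||
        tr$time_since_update > tracker$max_age) drop[i] <- TRUE
  }
  tracker$tracks[drop] <- NULL
  # spawn new tracks
  for (j in as$unmatched_dets) {
    emb <- if (!is.null(embeddings)) embeddings[[j]] else NULL
    tracker$tracks[[length(tracker$tracks) + 1L]] <-
      new_track(tracker$next_id, as.numeric(dets[j, c("xmin", "ymin", "xmax", "ymax")]), emb)
    tracker$next_id <- tracker$next_id + 1L
  }
  conf <- Filter(function(t) t$status == "confirmed" && t$time_since_update == 0L,
                 tracker$tracks)
  tracks_df <- if (length(conf)) {
    B <- do.call(rbind, lapply(conf, track_box))
    data.frame(id = vapply(conf, `[[`, integer(1), "id"),
               xmin = B[, 1], ymin = B[, 2], xmax = B[, 3], ymax = B[, 4])
  } else {
    data.frame(id = integer(0), xmin = numeric(0), ymin = numeric(0),
               xmax = numeric(0), ymax = numeric(0))
  }
  list(tracker = tracker, tracks = tracks_df)
}
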