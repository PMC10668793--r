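# Seeded synthetic corridor scenes: a fixed overhead camera over a passage,
# head-like targets entering at the top and walking down through a counting
# line. Ground truth carries per-frame boxes with persistent track ids, so
# the tracker and counter can be tested without field footage.

#' Scene configuration
#'
#' Conditions emulate a 2 m corridor viewed from above: up to a handful of
#' animals moving in parallel, entering at staggered times, head sizes of a
#' few tens of pixels, moderate per-frame motion.
#'
#' @param n_tracks number of targets (default 4, the corridor's capacity
#'   for simultaneous animals).
#' @param frame_size `c(W, H)` in pixels.
#' @param n_frames scene length in frames.
#' @param speed_range per-frame downward speed range, pixels.
#' @param size_range head side-length range, pixels.
#' @param occlusion_prob probability that a target's lane is drawn close to
#'   another target's lane, producing overlap and occlusion.
#' @param miss_rate detector miss probability per box (degraded streams).
#' @param fp_rate expected false positives per frame (degraded streams).
#' @param jitter_sd Gaussian corner jitter, pixels (degraded streams).
#' @param seed RNG seed making the scene fully reproducible.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(n_tracks = 4L, frame_size = c(640L, 640L),
                         n_frames = 140L, speed_range = c(4, 9),
                         size_range = c(36, 80), occlusion_prob = 0.2,
                         miss_rate = 0, fp_rate = 0, jitter_sd = 0,
                         seed = 1L) {
  stopifnot(n_tracks >= 0, all(frame_size > 0), n_frames >= 1,
            miss_rate >= 0, miss_rate <= 1, fp_rate >= 0, jitter_sd >= 0)
  structure(list(n_tracks = as.integer(n_tracks),
                 frame_size = as.integer(frame_size),
                 n_frames = as.integer(n_frames),
                 speed_range = speed_range, size_range = size_range,
                 occlusion_prob = occlusion_prob, miss_rate = miss_rate,
                 fp_rate = fp_rate, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate a synthetic corridor scene
#'
#' Draws per-track motion parameters from the seeded RNG and produces the
#' exact per-frame ground truth: boxes with persistent track ids, plus the
#' set of tracks whose head-center trajectory crosses the counting line
#' downwards within the scene.
#'
#' @param cfg a [scene_config()].
#' @param line counting line as `c(x1, y1, x2, y2)`; default horizontal at
#'   55% of the frame height.
#' @return object of class `sheep_scene` with fields `config`, `line`,
#'   `tracks` (per-track parameters), `truth` (per-frame data.frames with
#'   `id, xmin, ymin, xmax, ymax`), and `crossings` (ids crossing down).
#' @export
generate_scene <- function(cfg = scene_config(), line = NULL) {
  W <- cfg$frame_size[1]; H <- cfg$frame_size[2]
  if (is.null(line)) line <- c(0, 0.55 * H, W, 0.55 * H)
  set.seed(cfg$seed)
  n <- cfg$n_tracks
  tracks <- NULL
  if (n > 0L) {
    size <- runif(n, cfg$size_range[1], cfg$size_range[2])
    lane <- runif(n, 0.12 * W, 0.88 * W)
    if (n > 1L) for (i in 2:n) {
      if (runif(1) < cfg$occlusion_prob) {
        lane[i] <- min(max(lane[sample.int(i - 1L, 1L)] + rnorm(1, 0, size[i] / 3),
                           0.08 * W), 0.92 * W)
      }
    }
    tracks <- data.frame(
      id = seq_len(n),
      spawn = sample.int(max(1L, cfg$n_frames %/% 5L), n, replace = TRUE),
      speed = runif(n, cfg$speed_range[1], cfg$speed_range[2]),
      lane = lane,
      drift_amp = runif(n, 0, 12),
      drift_per = runif(n, 40, 90),
      w = size * runif(n, 0.9, 1.15),
      h = size,
      hue = runif(n)
    )
  }
  truth <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    rows <- NULL
    for (i in seq_len(n)) {
      tr <- tracks[i, ]
      if (f < tr$spawn) next
      t <- f - tr$spawn
      cy <- -tr$h / 2 + tr$speed * t
      cx <- tr$lane + tr$drift_amp * sin(2 * pi * t / tr$drift_per)
      b <- c(cx - tr$w / 2, cy - tr$h / 2, cx + tr$w / 2, cy + tr$h / 2)
      # keep the box while it intersects the frame
      if (b[3] <= 0 || b[1] >= W || b[4] <= 0 || b[2] >= H) next
      b <- c(max(b[1], 0), max(b[2], 0), min(b[3], W), min(b[4], H))
      if (b[3] - b[1] < 2 || b[4] - b[2] < 2) next
      rows <- rbind(rows, data.frame(id = tr$id, xmin = b[1], ymin = b[2],
                                     xmax = b[3], ymax = b[4],
                                     cx = cx, cy = cy))
    }
    truth[[f]] <- if (is.null(rows)) {
      data.frame(id = integer(0), xmin = numeric(0), ymin = numeric(0),
                 xmax = numeric(0), ymax = numeric(0),
                 cx = numeric(0), cy = numeric(0))
    } else rows
  }
  # a track crosses if the signed side of its observed center flips - to +
  crossings <- integer(0)
  for (i in seq_len(n)) {
    sides <- unlist(lapply(truth, function(fr) {
      j <- match(i, fr$id)
      if (is.na(j)) return(NULL)
      line_side(c(fr$cx[j], fr$cy[j]), line)
    }))
    sides <- sides[sides != 0]
    if (length(sides) >= 2 && any(sides[-1] > 0 & sides[-length(sides)] < 0)) {
      crossings <- c(crossings, i)
    }
  }
  structure(list(config = cfg, line = line, tracks = tracks, truth = truth,
                 crossings = crossings),
            class = "sheep_scene")
}

#' @export
print.sheep_scene <- function(x, ...) {
  cat("synthetic corridor scene: ", x$config$n_tracks, " track(s), ",
      x$config$n_frames, " frames, ",
      length(x$crossings), " downward crossing(s)\n", sep = "")
  invisible(x)
}

#' Ground-truth detections for one frame
#'
#' @param scene a `sheep_scene`.
#' @param frame frame index (1-based).
#' @return box-set data.frame with an extra `id` column.
#' @export
scene_truth_boxes <- function(scene, frame) {
  fr <- scene$truth[[frame]]
  out <- data.frame(xmin = fr$xmin, ymin = fr$ymin, xmax = fr$xmax,
                    ymax = fr$ymax, score = rep(1, nrow(fr)),
                    label = rep(1L, nrow(fr)), id = fr$id)
  out
}

#' Degrade ground-truth boxes into a noisy detection stream
#'
#' Drops each true box with probability `miss_rate`, jitters surviving
#' corners with Gaussian noise, and adds Poisson-many uniform false
#' positives per frame. Deterministic given `seed`.
#'
#' @param scene a `sheep_scene`.
#' @param miss_rate,fp_rate,jitter_sd noise levels; default from the scene
#'   config.
#' @param seed RNG seed.
#' @return list of per-frame box sets.
#' @export
degrade_detections <- function(scene, miss_rate = scene$config$miss_rate,
                               fp_rate = scene$config$fp_rate,
                               jitter_sd = scene$config$jitter_sd,
                               seed = scene$config$seed + 1000L) {
  set.seed(seed)
  W <- scene$config$frame_size[1]; H <- scene$config$frame_size[2]
  lapply(seq_along(scene$truth), function(f) {
    fr <- scene$truth[[f]]
    keep <- runif(nrow(fr)) >= miss_rate
    fr <- fr[keep, , drop = FALSE]
    n <- nrow(fr)
    if (n && jitter_sd > 0) {
      fr$xmin <- fr$xmin + rnorm(n, 0, jitter_sd)
      fr$ymin <- fr$ymin + rnorm(n, 0, jitter_sd)
      fr$xmax <- fr$xmax + rnorm(n, 0, jitter_sd)
      fr$ymax <- fr$ymax + rnorm(n, 0, jitter_sd)
      ok <- fr$xmax > fr$xmin + 1 & fr$ymax > fr$ymin + 1
      fr <- fr[ok, , drop = FALSE]
      n <- nrow(fr)
    }
    out <- data.frame(xmin = fr$xmin, ymin = fr$ymin, xmax = fr$xmax,
                      ymax = fr$ymax,
                      score = if (n) runif(n, 0.75, 0.99) else numeric(0),
                      label = rep(1L, n))
    nfp <- stats::rpois(1, fp_rate)
    if (nfp > 0) {
      for (k in seq_len(nfp)) {
        w <- runif(1, 20, 70); h <- runif(1, 20, 70)
        x0 <- runif(1, 0, W - w); y0 <- runif(1, 0, H - h)
        out <- rbind(out, data.frame(xmin = x0, ymin = y0, xmax = x0 + w,
                                     ymax = y0 + h,
                                     score = runif(1, 0.3, 0.7), label = 1L))
      }
    }
    rownames(out) <- NULL
    out
  })
}

# soft-edged ellipse head with per-track hue and a deterministic speckle
# texture, drawn over the background patchwork
draw_head <- function(img, cx, cy, w, h, hue, track_id) {
  H <- dim(img)[1]; W <- dim(img)[2]
  y0 <- max(1L, floor(cy - h / 2)); y1 <- min(H, ceiling(cy + h / 2))
  x0 <- max(1L, floor(cx - w / 2)); x1 <- min(W, ceiling(cx + w / 2))
  if (y1 < y0 || x1 < x0) return(img)
  ys <- y0:y1; xs <- x0:x1
  dy <- (ys - cy) / (h / 2)
  dx <- (xs - cx) / (w / 2)
  mask <- outer(dy^2, dx^2, `+`) <= 1
  base <- grDevices::hsv(hue, 0.55, 0.8)
  rgbv <- grDevices::col2rgb(base)
  # cheap value-noise texture, fixed by track id so appearance is stable
  tex <- 0.75 + 0.25 * (sin(outer(ys * (0.35 + 0.02 * track_id), xs * 0.41, `+`)) + 1) / 2
  shade <- 1 - 0.35 * outer(dy^2, dx^2, `+`)
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    val <- rgbv[ch] * tex * shade
    plane[mask] <- val[mask]
    img[ys, xs, ch] <- plane
  }
  img
}

#' Render one frame of a synthetic scene
#'
#' Concrete-grey corridor background with mild static texture, heads drawn
#' as soft-shaded ellipses with per-track hue and speckle (so appearance
#' embeddings are discriminative); later track ids are drawn on top,
#' giving a fixed occlusion z-order.
#'
#' @param scene a `sheep_scene`.
#' @param frame frame index.
#' @return `[H, W, 3]` array, values 0..255.
#' @export
render_scene_frame <- function(scene, frame) {
  W <- scene$config$frame_size[1]; H <- scene$config$frame_size[2]
  bg <- 120 + 18 * sin(outer(seq_len(H) * 0.11, seq_len(W) * 0.07, `+`))
  img <- array(rep(bg, 3), c(H, W, 3))
  fr <- scene$truth[[frame]]
  for (j in seq_len(nrow(fr))) {
    tr <- scene$tracks[scene$tracks$id == fr$id[j], ]
    img <- draw_head(img, fr$cx[j], fr$cy[j],
                     fr$xmax[j] - fr$xmin[j], fr$ymax[j] - fr$ymin[j],
                     tr$hue, tr$id)
  }
  img
}

#' Export a scene to disk as images + VOC XML + truth JSON
#'
#' @param scene a `sheep_scene`.
#' @param dir output directory (created).
#' @param render write PNG frames (else annotations only).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, render = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(scene$truth)) {
    stem <- sprintf("frame_%04d", f)
    fr <- scene$truth[[f]]
    ann <- annotated_image(
      boxes = as.matrix(fr[, c("xmin", "ymin", "xmax", "ymax")]),
      labels = rep("sheep", nrow(fr)),
      size = scene$config$frame_size,
      source_path = paste0(stem, ".png"))
    write_voc_xml(ann, file.path(dir, paste0(stem, ".xml")),
                  filename = paste0(stem, ".png"))
    if (render) {
      write_image(render_scene_frame(scene, f), file.path(dir, paste0(stem, ".png")))
    }
  }
  jsonlite::write_json(
    list(line = scene$line, crossings = scene$crossings,
         n_frames = scene$config$n_frames,
         truth = lapply(scene$truth, function(fr) fr[, c("id", "xmin", "ymin", "xmax", "ymax")])),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Synthetic detection training set
#'
#' Renders standalone frames from seeded corridor scenes (1 to 4 heads per
#' frame, sizes drawn from the scene defaults scaled to the frame) for
#' CPU-scale detector training experiments.
#'
#' @param n number of images.
#' @param image_size square frame side in pixels (multiple of 32).
#' @param seed RNG seed.
#' @return list of samples `list(image, boxes, labels)` as consumed by
#'   [train_shssd()].
#' @export
synth_training_samples <- function(n = 20L, image_size = 320L, seed = 1L) {
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    nt <- 1L + (i - 1L) %% 4L
    sc <- generate_scene(scene_config(
      n_tracks = nt, frame_size = c(image_size, image_size),
      n_frames = 60L, speed_range = c(3, 6),
      size_range = c(0.09, 0.2) * image_size,
      seed = seed * 1000L + i))
    # pick the frame with the most fully visible (unclipped) heads and no
    # partial slivers at the frame border
    score <- vapply(seq_along(sc$truth), function(f) {
      fr <- sc$truth[[f]]
      if (!nrow(fr)) return(-1)
      inside <- fr$xmin > 0 & fr$ymin > 0 &
        fr$xmax < image_size & fr$ymax < image_size
      sum(inside) - 10 * sum(!inside)
    }, numeric(1))
    f <- which.max(score)
    fr <- sc$truth[[f]]
    inside <- fr$xmin > 0 & fr$ymin > 0 &
      fr$xmax < image_size & fr$ymax < image_size
    fr <- fr[inside, , drop = FALSE]
    samples[[i]] <- list(image = render_scene_frame(sc, f),
                         boxes = as.matrix(fr[, c("xmin", "ymin", "xmax", "ymax")]),
                         labels = rep(1L, nrow(fr)))
  }
  samples
}
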