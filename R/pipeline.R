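# End-to-end dynamic counting: detections (from the network, a detection
# stream, or synthetic truth) -> tracking -> line-crossing counting.

#' Run the counting pipeline over a stream of per-frame detections
#'
#' @param detections list of per-frame box sets, or a MOT-style data.frame
#'   with a `frame` column.
#' @param line a [count_line()].
#' @param frames optional list of `[H, W, 3]` arrays (or a function of the
#'   frame index returning one) enabling the appearance term.
#' @param tracker a [sheep_tracker()]; a fresh default one if missing.
#' @param score_thresh minimum detection score fed to the tracker.
#' @return list of class `count_report`: `total`, `events`, `n_ids`,
#'   per-frame confirmed `tracks`, and the final `tracker`.
#' @export
count_detections <- function(detections, line, frames = NULL,
                             tracker = sheep_tracker(),
                             score_thresh = 0.4) {
  if (is.data.frame(detections)) {
    n_frames <- max(detections$frame)
    detections <- lapply(seq_len(n_frames), function(f) {
      d <- detections[detections$frame == f, , drop = FALSE]
      data.frame(xmin = d$xmin, ymin = d$ymin, xmax = d$xmax, ymax = d$ymax,
                 score = d$score, label = 1L)
    })
  }
  st <- count_state()
  per_frame <- vector("list", length(detections))
  for (f in seq_along(detections)) {
    dets <- detections[[f]]
    dets <- dets[dets$score >= score_thresh, , drop = FALSE]
    img <- if (is.function(frames)) frames(f) else if (!is.null(frames)) frames[[f]] else NULL
    stp <- tracker_step(tracker, dets, img)
    tracker <- stp$tracker
    st <- update_count(st, stp$tracks, line, frame = f)
    per_frame[[f]] <- stp$tracks
  }
  structure(list(total = st$total, events = st$events,
                 n_ids = tracker$next_id - 1L, tracks = per_frame,
                 tracker = tracker, state = st),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  cat("count report: total =", x$total, "crossing(s),",
      x$n_ids, "track id(s) issued\n")
  invisible(x)
}

#' Count a synthetic scene
#'
#' Convenience wrapper: takes a scene, a detection source (clean truth,
#' degraded truth, or the detector itself), runs tracking + counting, and
#' compares with the scene's ground-truth crossing count.
#'
#' @param scene a [generate_scene()] result.
#' @param detections `"truth"` (noise-free ground-truth boxes),
#'   `"degraded"` (noise per the scene config), or a list of per-frame box
#'   sets.
#' @param line a [count_line()]; defaults to the scene's line, counting
#'   downward.
#' @param use_appearance render frames and use the appearance term.
#' @param ... passed to [sheep_tracker()].
#' @return a `count_report` with extra fields `truth_total` and `exact`.
#' @export
count_scene <- function(scene, detections = c("truth", "degraded"),
                        line = NULL, use_appearance = FALSE, ...) {
  if (is.character(detections)) {
    detections <- match.arg(detections)
    dets <- switch(detections,
                   truth = lapply(seq_along(scene$truth), function(f) {
                     scene_truth_boxes(scene, f)
                   }),
                   degraded = degrade_detections(scene))
  } else {
    dets <- detections
  }
  if (is.null(line)) {
    line <- count_line(scene$line[1], scene$line[2], scene$line[3],
                       scene$line[4], direction = "down")
  }
  frames <- if (use_appearance) function(f) render_scene_frame(scene, f) else NULL
  rep <- count_detections(dets, line, frames = frames,
                          tracker = sheep_tracker(...), score_thresh = 0)
  rep$truth_total <- length(scene$crossings)
  rep$exact <- rep$total == rep$truth_total
  rep
}

#' Detect-track-count over image frames with a trained model
#'
#' The full workflow: per-frame detection with the network, DeepSort-style
#' tracking, and line-crossing counting.
#'
#' @param model an [sh_ssd()] model.
#' @param frames list of `[H, W, 3]` arrays (values 0..255), or a function
#'   of the frame index.
#' @param n_frames number of frames when `frames` is a function.
#' @param line a [count_line()].
#' @param score_thresh detection score cut for tracking (default 0.4).
#' @param ... passed to [sheep_tracker()].
#' @return a `count_report`.
#' @export
run_pipeline <- function(model, frames, n_frames = length(frames), line,
                         score_thresh = 0.4, ...) {
  get_frame <- if (is.function(frames)) frames else function(f) frames[[f]]
  dets <- lapply(seq_len(n_frames), function(f) {
    predict(model, get_frame(f) / 255, score_thresh = score_thresh,
            iou_thresh = 0.5)
  })
  count_detections(dets, line, frames = get_frame,
                   tracker = sheep_tracker(...), score_thresh = score_thresh)
}
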