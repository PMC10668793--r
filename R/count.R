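# Line-crossing counter: a virtual line across the frame and a monotone
# tally incremented when a tracked head center crosses it in the counted
# direction. Each track id is counted at most once per direction.

#' Center point of a head box
#'
#' The head-center is the positional reference for counting.
#'
#' @param box `(xmin, ymin, xmax, ymax)` vector.
#' @return `c(x, y)` center.
#' @export
head_center <- function(box) {
  c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)
}

# signed side of point p w.r.t. line c(x1,y1,x2,y2): for the default
# left-to-right horizontal line, negative above and positive below, so a
# downward passage is a - to + flip.
line_side <- function(p, line) {
  v <- (line[3] - line[1]) * (p[2] - line[2]) - (line[4] - line[2]) * (p[1] - line[1])
  sign(v)
}

#' Create a counting line
#'
#' @param x1,y1,x2,y2 endpoints in pixel coordinates.
#' @param direction which crossings to count: `"down"` (the default,
#'   negative-to-positive side flips; top to bottom for a horizontal line
#'   stated left to right), `"up"`, or `"both"`.
#' @return object of class `count_line`.
#' @export
count_line <- function(x1, y1, x2, y2, direction = c("down", "up", "both")) {
  if (x1 == x2 && y1 == y2) stop("count line endpoints must be distinct")
  structure(list(line = c(x1, y1, x2, y2), direction = match.arg(direction)),
            class = "count_line")
}

#' Create an empty counting state
#'
#' @return object of class `count_state` holding the running total, each
#'   track's last observed side, and the set of already-counted ids.
#' @export
count_state <- function() {
  structure(list(total = 0L, last_side = integer(0),
                 counted = integer(0), events = list()),
            class = "count_state")
}

#' @export
print.count_state <- function(x, ...) {
  cat("count state: total =", x$total, "(", length(x$counted),
      "id(s) counted )\n")
  invisible(x)
}

#' Advance the counting state by one frame of tracks
#'
#' For every track, the signed side of its head center relative to the line
#' is compared with the side last seen for that id; a strict flip in the
#' counted direction increments the total, once per id per direction.
#' A center exactly on the line keeps the previous side, so boundary jitter
#' cannot double-count. Tracks first observed already past the line are not
#' counted.
#'
#' @param st a `count_state`.
#' @param tracks data.frame with columns `id, xmin, ymin, xmax, ymax`
#'   (current confirmed tracks).
#' @param cl a [count_line()].
#' @param frame frame index recorded with counting events.
#' @return the updated `count_state`.
#' @export
update_count <- function(st, tracks, cl, frame = NA_integer_) {
  for (j in seq_len(nrow(tracks))) {
    id <- as.character(tracks$id[j])
    ctr <- head_center(as.numeric(tracks[j, c("xmin", "ymin", "xmax", "ymax")]))
    s <- line_side(ctr, cl$line)
    prev <- st$last_side[id]
    if (is.na(prev) || length(prev) == 0L) {
      st$last_side[id] <- s          # first observation: record side only
      next
    }
    if (s == 0L) next                 # on the line: keep previous side
    if (prev != 0L && s != prev) {
      dir_ok <- switch(cl$direction,
                       down = prev < 0 && s > 0,
                       up = prev > 0 && s < 0,
                       both = TRUE)
      if (dir_ok && !(tracks$id[j] %in% st$counted)) {
        st$total <- st$total + 1L
        st$counted <- c(st$counted, tracks$id[j])
        st$events[[length(st$events) + 1L]] <-
          list(id = tracks$id[j], frame = frame,
               direction = if (s > 0) "down" else "up")
      }
    }
    st$last_side[id] <- s
  }
  st
}
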