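fake_track <- function(id, cx, cy, size = 20) {
  data.frame(id = id, xmin = cx - size / 2, ymin = cy - size / 2,
             xmax = cx + size / 2, ymax = cy + size / 2)
}

test_that("head_center is the box midpoint and translation-equivariant", {
  expect_equal(head_center(c(0, 0, 10, 10)), c(5, 5))
  expect_equal(head_center(c(4, 4, 5, 5)), c(4.5, 4.5))
  b <- c(3, 7, 21, 40)
  expect_equal(head_center(b + c(5, 9, 5, 9)), head_center(b) + c(5, 9))
})

test_that("a single downward crossing counts exactly once", {
  cl <- count_line(0, 120, 640, 120)
  st <- count_state()
  for (y in c(100, 118, 130, 150)) {
    st <- update_count(st, fake_track(1L, 300, y), cl)
  }
  expect_equal(st$total, 1L)
})

test_that("oscillation around the line is counted once per id", {
  cl <- count_line(0, 120, 640, 120)
  st <- count_state()
  for (y in c(118, 121, 119, 122, 118, 125)) {
    st <- update_count(st, fake_track(1L, 300, y), cl)
  }
  expect_equal(st$total, 1L)
})

test_that("non-crossing and wrong-direction trajectories do not count", {
  cl <- count_line(0, 120, 640, 120)
  st <- count_state()
  for (y in seq(130, 200, by = 10)) {
    st <- update_count(st, fake_track(1L, 300, y), cl)  # always below
  }
  expect_equal(st$total, 0L)
  # upward motion with direction = "down" does not count ...
  st2 <- count_state()
  for (y in c(150, 130, 110, 90)) st2 <- update_count(st2, fake_track(2L, 300, y), cl)
  expect_equal(st2$total, 0L)
  # ... but does with direction = "up"
  cl_up <- count_line(0, 120, 640, 120, direction = "up")
  st3 <- count_state()
  for (y in c(150, 130, 110, 90)) st3 <- update_count(st3, fake_track(2L, 300, y), cl_up)
  expect_equal(st3$total, 1L)
})

test_that("a center landing exactly on the line keeps the previous side", {
  cl <- count_line(0, 120, 640, 120)
  st <- count_state()
  for (y in c(110, 120, 110, 120, 115)) {
    st <- update_count(st, fake_track(1L, 300, y), cl)
  }
  expect_equal(st$total, 0L)
  st <- update_count(st, fake_track(1L, 300, 125), cl)
  expect_equal(st$total, 1L)
})

test_that("tracks first observed past the line are not counted", {
  cl <- count_line(0, 120, 640, 120)
  st <- count_state()
  for (y in c(130, 140, 150)) st <- update_count(st, fake_track(7L, 300, y), cl)
  expect_equal(st$total, 0L)
})

test_that("the total is monotone non-decreasing over frames", {
  set.seed(21)
  cl <- count_line(0, 120, 640, 120)
  st <- count_state()
  prev <- 0L
  for (f in 1:200) {
    tracks <- do.call(rbind, lapply(1:4, function(id) {
      fake_track(id, 300 + 20 * id, runif(1, 60, 180))
    }))
    st <- update_count(st, tracks, cl, frame = f)
    expect_gte(st$total, prev)
    prev <- st$total
  }
  expect_lte(st$total, 4L)
})
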