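test_that("Kalman predict follows linear motion and inflates uncertainty", {
  s <- kalman_init(c(10, 50, 1, 40))
  s$mean[5] <- 2                      # vx = 2 px/frame
  p <- kalman_predict(s)
  expect_equal(p$mean[1], 12)
  # zero velocity: position unchanged, covariance strictly grows
  s0 <- kalman_init(c(30, 30, 1, 40))
  p0 <- kalman_predict(s0)
  expect_equal(p0$mean[1:4], s0$mean[1:4])
  expect_gt(sum(diag(p0$cov)), sum(diag(s0$cov)))
  # five predictions track constant-velocity truth exactly
  s2 <- kalman_init(c(0, 0, 1, 40))
  s2$mean[5:6] <- c(3, 4)
  for (i in 1:5) s2 <- kalman_predict(s2)
  expect_equal(s2$mean[1:2], c(15, 20))
})

test_that("Kalman update shrinks uncertainty and converges to measurements", {
  s <- kalman_init(c(10, 10, 1, 40))
  p <- kalman_predict(s)
  # measurement equal to the predicted mean leaves the mean unchanged
  u <- kalman_update(p, p$mean[1:4])
  expect_equal(u$mean[1:4], p$mean[1:4], tolerance = 1e-10)
  expect_lt(sum(diag(u$cov[1:4, 1:4])), sum(diag(p$cov[1:4, 1:4])))
  # repeated identical measurements: monotone innovation shrinkage
  z <- c(50, 60, 1.1, 44)
  s2 <- kalman_init(c(10, 10, 1, 40))
  innov <- numeric(40)
  for (t in 1:40) {
    s2 <- kalman_predict(s2)
    innov[t] <- sqrt(sum((z[1:2] - s2$mean[1:2])^2))
    s2 <- kalman_update(s2, z)
  }
  expect_lt(innov[40], 0.1)
  expect_true(all(diff(innov[3:40]) <= 1e-9))
})

test_that("Kalman filter matches the textbook reference on random tracks", {
  set.seed(11)
  for (trial in 1:10) {
    n <- 20
    v <- c(runif(1, -4, 4), runif(1, 1, 6))
    start <- c(runif(1, 50, 300), runif(1, 20, 100))
    h <- runif(1, 30, 60)
    zs <- cbind(start[1] + v[1] * (0:(n - 1)) + rnorm(n, 0, 0.5),
                start[2] + v[2] * (0:(n - 1)) + rnorm(n, 0, 0.5),
                runif(1, 0.8, 1.2) + rnorm(n, 0, 0.01),
                h + rnorm(n, 0, 0.5))
    ref <- textbook_kalman(zs)
    s <- kalman_init(zs[1, ])
    for (t in 2:n) {
      s <- kalman_predict(s)
      s <- kalman_update(s, zs[t, ])
      expect_equal(s$mean, ref[t, ], tolerance = 1e-8)
    }
  }
})

test_that("association handles empty inputs, small costs and gating", {
  tk <- sheep_tracker()
  dets <- box_set(c(10, 60), c(10, 60), c(30, 90), c(30, 90), score = c(0.9, 0.9))
  as0 <- associate(tk, dets)
  expect_equal(as0$unmatched_dets, 1:2)
  expect_equal(nrow(as0$matches), 0)
  # 2x2 cost [[1,2],[2,1]] resolved to the diagonal, total cost 2
  a <- hungarian(matrix(c(1, 2, 2, 1), 2, 2))
  expect_equal(a, c(1L, 2L))
  # a detection far outside the chi-square gate never matches
  tk2 <- sheep_tracker(n_init = 1)
  stp <- tracker_step(tk2, box_set(100, 100, 140, 140, score = 0.9))
  far <- box_set(400, 400, 440, 440, score = 0.99)
  as2 <- associate(stp$tracker, far)
  expect_equal(nrow(as2$matches), 0)
})

test_that("clean constant-velocity targets keep their ids for a whole pass", {
  dets <- linear_detections(3, 50)
  tk <- sheep_tracker()
  ids_seen <- integer(0)
  for (f in seq_along(dets)) {
    stp <- tracker_step(tk, dets[[f]])
    tk <- stp$tracker
    ids_seen <- union(ids_seen, stp$tracks$id)
  }
  expect_equal(tk$next_id - 1L, 3L)       # exactly 3 ids ever issued
  expect_length(ids_seen, 3)
})

test_that("a one-frame dropout within max_age preserves the id", {
  dets <- linear_detections(1, 30)
  dets[[15]] <- dets[[15]][0, ]           # dropout
  tk <- sheep_tracker(max_age = 30)
  last_id <- NA_integer_
  for (f in seq_along(dets)) {
    stp <- tracker_step(tk, dets[[f]])
    tk <- stp$tracker
    if (nrow(stp$tracks)) last_id <- stp$tracks$id[1]
  }
  expect_equal(last_id, 1L)
  expect_equal(tk$next_id - 1L, 1L)
  # empty video: no tracks at all
  tke <- sheep_tracker()
  for (f in 1:10) tke <- tracker_step(tke, shssd:::empty_box_set())$tracker
  expect_length(tke$tracks, 0)
  expect_equal(tke$next_id, 1L)
})

test_that("appearance embeddings separate differently coloured targets", {
  img <- array(0, c(100, 100, 3))
  img[20:40, 20:40, 1] <- 220            # red patch
  img[60:80, 60:80, 3] <- 220            # blue patch
  e_red <- rgb_hist_embedding(img, c(20, 20, 40, 40))
  e_blue <- rgb_hist_embedding(img, c(60, 60, 80, 80))
  expect_equal(sqrt(sum(e_red^2)), 1, tolerance = 1e-9)
  expect_gt(shssd:::cosine_distance(e_red, e_blue), 0.5)
  expect_lt(shssd:::cosine_distance(e_red, e_red), 1e-9)
})
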