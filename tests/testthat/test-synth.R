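test_that("scene generation is seed-deterministic with valid ground truth", {
  cfg <- scene_config(n_tracks = 3, seed = 5, n_frames = 60)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(render_scene_frame(s1, 30), render_scene_frame(s2, 30))
  # zero-track scene: empty annotations everywhere
  s0 <- generate_scene(scene_config(n_tracks = 0, seed = 1, n_frames = 10))
  expect_true(all(vapply(s0$truth, nrow, integer(1)) == 0))
  # boxes stay inside the frame and ids are contiguous per track
  for (fr in s1$truth) {
    if (!nrow(fr)) next
    expect_true(all(fr$xmin >= 0 & fr$xmax <= 640))
    expect_true(all(fr$xmax > fr$xmin & fr$ymax > fr$ymin))
  }
  for (id in 1:3) {
    seen <- which(vapply(s1$truth, function(fr) id %in% fr$id, logical(1)))
    if (length(seen) > 1) expect_equal(seen, seq(min(seen), max(seen)))
  }
})

test_that("downward-moving tracks all cross the default line", {
  sc <- generate_scene(scene_config(n_tracks = 5, n_frames = 200, seed = 9))
  expect_equal(sort(sc$crossings), 1:5)
})

test_that("degraded detections obey the configured noise model", {
  sc <- generate_scene(scene_config(n_tracks = 4, seed = 3))
  clean <- degrade_detections(sc, miss_rate = 0, fp_rate = 0, jitter_sd = 0)
  for (f in seq_along(clean)) {
    expect_equal(nrow(clean[[f]]), nrow(sc$truth[[f]]))
    if (nrow(clean[[f]])) {
      expect_equal(clean[[f]]$xmin, sc$truth[[f]]$xmin)
    }
  }
  gone <- degrade_detections(sc, miss_rate = 1, fp_rate = 0, jitter_sd = 0)
  expect_true(all(vapply(gone, nrow, integer(1)) == 0))
  # empirical drop fraction within 3 binomial sigma of the miss rate
  n_true <- sum(vapply(sc$truth, nrow, integer(1)))
  expect_gt(n_true, 300)
  miss <- 0.3
  deg <- degrade_detections(sc, miss_rate = miss, fp_rate = 0, jitter_sd = 0)
  n_kept <- sum(vapply(deg, nrow, integer(1)))
  frac_dropped <- 1 - n_kept / n_true
  sigma <- sqrt(miss * (1 - miss) / n_true)
  expect_lt(abs(frac_dropped - miss), 3 * sigma)
})

test_that("scene export writes frames, VOC XML and truth JSON", {
  sc <- generate_scene(scene_config(n_tracks = 2, n_frames = 3,
                                    frame_size = c(128, 128), seed = 4))
  dir <- tempfile("scene")
  write_scene(sc, dir, render = TRUE)
  expect_length(list.files(dir, pattern = "\\.xml$"), 3)
  expect_length(list.files(dir, pattern = "\\.png$"), 3)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$n_frames, 3)
  # the written annotations parse back to the truth boxes (rounded to
  # integer pixels by the VOC format)
  f <- which(vapply(sc$truth, nrow, integer(1)) > 0)[1]
  if (!is.na(f)) {
    ann <- read_voc_xml(file.path(dir, sprintf("frame_%04d.xml", f)))
    expect_equal(nrow(ann$boxes), nrow(sc$truth[[f]]))
    expect_equal(as.numeric(ann$boxes[, 1]), round(sc$truth[[f]]$xmin),
                 tolerance = 1.01)
  }
  unlink(dir, recursive = TRUE)
})

test_that("training samples are renderable frames with in-bounds boxes", {
  samples <- synth_training_samples(6, 160, seed = 2)
  expect_length(samples, 6)
  for (s in samples) {
    expect_equal(dim(s$image), c(160, 160, 3))
    expect_gte(nrow(s$boxes), 1)
    expect_true(all(s$boxes[, c(1, 3)] >= 0 & s$boxes[, c(1, 3)] <= 160))
  }
})
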