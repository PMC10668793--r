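test_that("detection matching applies the greedy one-to-one rule", {
  gts <- box_set(c(0, 100), c(0, 100), c(50, 150), c(50, 150))
  perfect <- gts
  m <- match_detections(perfect, gts, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(2, 0, 0))
  # duplicate detection of one ground truth: 1 TP + 1 FP
  dup <- box_set(c(0, 1), c(0, 1), c(50, 51), c(50, 51), score = c(0.9, 0.8))
  m2 <- match_detections(dup, gts[1, ], 0.5)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1, 1, 0))
  expect_true(m2$det_tp[1])      # higher score claims the match
  expect_false(m2$det_tp[2])
  m3 <- match_detections(shssd:::empty_box_set(), gts, 0.5)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(0, 0, 2))
})

test_that("precision and recall follow the published formulas", {
  expect_equal(precision(list(TP = 9, FP = 1)), 90)
  expect_equal(precision(list(TP = 0, FP = 0)), 0)
  expect_equal(round(precision(list(TP = 518, FP = 12)), 2), 97.74)
  expect_equal(recall(list(TP = 9, FN = 3)), 75)
  expect_equal(recall(list(TP = 5, FN = 0)), 100)
  expect_equal(recall(list(TP = 0, FN = 7)), 0)
})

test_that("average precision integrates hand-built PR curves", {
  # perfect precision at every recall: unit square
  expect_equal(average_precision(list(precision = c(1, 1), recall = c(0.5, 1))), 100)
  # step curve: P=1 on [0, 0.5], P=0.5 on (0.5, 1] -> 75
  n <- 200
  prec <- c(rep(1, n / 2), rep(0.5, n / 2))
  rec <- seq_len(n) / n
  expect_equal(average_precision(list(precision = prec, recall = rec)), 75,
               tolerance = 0.5)
  expect_equal(average_precision(list(precision = numeric(0), recall = numeric(0))), 0)
})

test_that("the AP integrator matches rectangle integration on random curves", {
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(5:60, 1)
    rec <- sort(runif(n))
    prec <- runif(n)
    ap <- average_precision(list(precision = prec, recall = rec))
    expect_equal(ap, rect_ap(prec, rec), tolerance = 0.1)
  }
})

test_that("adding a true positive never decreases AP", {
  set.seed(32)
  for (trial in 1:10) {
    k <- sample(2:6, 1)
    gts <- box_set(seq(0, by = 100, length.out = k),
                   rep(0, k),
                   seq(40, by = 100, length.out = k),
                   rep(40, k))
    found <- sample(k, sample(k - 1, 1))
    dets <- gts[found, ]
    dets$score <- runif(length(found), 0.5, 1)
    ap1 <- shssd:::ap_at(list(dets), list(gts), 0.5)
    extra <- setdiff(seq_len(k), found)[1]
    dets2 <- rbind(dets, transform(gts[extra, ], score = runif(1, 0.5, 1)))
    ap2 <- shssd:::ap_at(list(dets2), list(gts), 0.5)
    expect_gte(ap2, ap1 - 1e-9)
  }
})

test_that("small-target AP restricts to the sub-1024 px^2 stratum", {
  # all ground truths large: empty stratum -> NA
  big <- box_set(0, 0, 40, 40)
  expect_true(is.na(small_target_ap(list(big), list(big))))
  # all small and perfectly detected -> 100
  small <- box_set(c(0, 50), c(0, 50), c(16, 66), c(16, 66))
  expect_equal(small_target_ap(list(small), list(small)), 100)
  # mixed sizes equal the filter-then-evaluate oracle
  gts <- box_set(c(0, 100, 200), c(0, 0, 0), c(16, 140, 216), c(16, 40, 216))
  dets <- gts; dets$score <- c(0.9, 0.8, 0.7)
  manual_gts <- gts[c(1, 3), ]        # areas 256 and 256 < 1024; 40x40 excluded
  manual_dets <- dets[c(1, 3), ]      # its detection is ignored, not an FP
  expect_equal(small_target_ap(list(dets), list(gts)),
               shssd:::ap_at(list(manual_dets), list(manual_gts), 0.5))
})

test_that("the COCO AP band is the mean of its ten thresholds", {
  set.seed(33)
  gts <- box_set(c(0, 100), c(0, 100), c(40, 160), c(60, 160))
  dets <- box_set(c(2, 105), c(1, 98), c(41, 158), c(59, 162),
                  score = c(0.9, 0.7))
  ev <- evaluate_detections(list(dets), list(gts))
  expect_equal(ev$AP50_95, mean(ev$AP_by_thresh))
  expect_length(ev$AP_by_thresh, 10)
  expect_equal(as.numeric(names(ev$AP_by_thresh)), seq(0.5, 0.95, 0.05))
  expect_true(all(ev$AP_by_thresh >= 0 & ev$AP_by_thresh <= 100))
  expect_gte(ev$P, 0); expect_lte(ev$P, 100)
})

test_that("the FPS utility reports images per second", {
  fps <- measure_fps(function(img) Sys.sleep(0.01), as.list(1:5))
  expect_gt(fps, 1)
  expect_lt(fps, 110)
})
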