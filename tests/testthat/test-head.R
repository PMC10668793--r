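test_that("decoupled head emits A*K cls and A*4 reg channels from disjoint branches", {
  set.seed(1)
  h <- shssd:::nn_dchead(8, A = 3, K = 1)
  x <- array(runif(6 * 6 * 8), c(6, 6, 8, 1))
  out <- h$forward(x, FALSE)
  expect_equal(dim(out$cls)[3], 3)
  expect_equal(dim(out$reg)[3], 12)
  # cls and reg branches share no parameters beyond the stem
  cls_ps <- c(shssd:::nn_params(h$cls_stack), shssd:::nn_params(h$cls_pred))
  reg_ps <- c(shssd:::nn_params(h$reg_stack), shssd:::nn_params(h$reg_pred))
  cls_envs <- vapply(cls_ps, function(p) format(p$env), character(1))
  reg_envs <- vapply(reg_ps, function(p) format(p$env), character(1))
  expect_length(intersect(cls_envs, reg_envs), 0)
  # each branch: 2 sets of DW-CBR + CBR
  expect_length(h$cls_stack$children, 4)
})

test_that("anchors tile the grids in prediction-map order", {
  m <- sh_ssd("tiny")
  a <- anchor_grid(m, c(64, 64))
  expect_equal(a$counts, c(8 * 8 * 3, 4 * 4 * 3, 2 * 2 * 3))
  lv1 <- a$levels[[1]]
  # first anchor: cell center (4, 4) at stride 8, scale 32
  expect_equal(as.numeric(lv1[1, ]), c(4, 4, 32, 32))
  # row index runs fastest (y), then column, then anchor scale
  expect_equal(as.numeric(lv1[2, "cy"] - lv1[1, "cy"]), 8)
  expect_equal(as.numeric(lv1[2, "cx"]), as.numeric(lv1[1, "cx"]))
  expect_equal(as.numeric(lv1[8 * 8 + 1, "w"]), 32 * 2^(1 / 3))
})

test_that("iou matches hand arithmetic and is symmetric", {
  a <- c(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(20, 20, 30, 30)), 0)
  b <- c(5, 0, 15, 10)
  expect_equal(iou(a, b), 50 / 150)
  expect_equal(iou(b, a), iou(a, b))
  set.seed(2)
  for (i in 1:20) {
    p <- c(sort(runif(2, 0, 50)), sort(runif(2, 0, 50)))[c(1, 3, 2, 4)]
    q <- c(sort(runif(2, 0, 50)), sort(runif(2, 0, 50)))[c(1, 3, 2, 4)]
    expect_equal(iou(p, q), iou(q, p))
    expect_gte(iou(p, q), 0)
    expect_lte(iou(p, q), 1)
  }
})

test_that("greedy NMS keeps the right boxes", {
  one <- box_set(0, 0, 10, 10, score = 0.9)
  expect_equal(nrow(nms(one, 0.5)), 1)
  dup <- box_set(c(0, 0), c(0, 0), c(10, 10), c(10, 10), score = c(0.9, 0.8))
  kept <- nms(dup, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)
  disj <- box_set(c(0, 20), c(0, 20), c(10, 30), c(10, 30), score = c(0.7, 0.9))
  kept2 <- nms(disj, 0.5)
  expect_equal(nrow(kept2), 2)
  expect_equal(kept2$score, c(0.9, 0.7))  # sorted by descending score
})

test_that("box decode matches hand-computed offsets and inverts encode", {
  anchors <- rbind(c(100, 100, 40, 40))
  # zero offsets decode to the anchor itself
  z <- shssd:::decode_boxes(rbind(c(0, 0, 0, 0)), anchors)
  expect_equal(as.numeric(z), c(80, 80, 120, 120))
  # offsets (0.1, 0.1, log2, log2): center +4, size doubled
  d <- shssd:::decode_boxes(rbind(c(0.1, 0.1, log(2), log(2))), anchors)
  expect_equal(as.numeric(d), c(104 - 40, 104 - 40, 104 + 40, 104 + 40))
  # encode then decode is the identity
  set.seed(3)
  for (i in 1:20) {
    anc <- cbind(runif(5, 50, 200), runif(5, 50, 200),
                 runif(5, 20, 80), runif(5, 20, 80))
    gt <- shssd:::cxcywh_to_corners(
      cbind(runif(5, 60, 180), runif(5, 60, 180), runif(5, 10, 60), runif(5, 10, 60)))
    enc <- shssd:::encode_boxes(gt, anc)
    dec <- shssd:::decode_boxes(enc, anc)
    expect_equal(dec, gt, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("prediction decoding respects the score threshold", {
  set.seed(4)
  m <- sh_ssd("tiny")
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  none <- predict(m, x, score_thresh = 1.0)
  expect_equal(nrow(none), 0)
  some <- predict(m, x, score_thresh = 0)
  if (nrow(some)) {
    expect_true(all(some$score >= 0 & some$score <= 1))
    expect_true(all(some$xmax > some$xmin & some$ymax > some$ymin))
    expect_true(all(some$xmax <= 64 & some$ymax <= 64))
    expect_true(!is.unsorted(rev(some$score)))
  }
})
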