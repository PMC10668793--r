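toy_anchors <- function() {
  # 6 anchors on a coarse stride-8 grid
  cbind(cx = c(20, 40, 60, 20, 40, 60),
        cy = c(20, 20, 20, 60, 60, 60),
        w = 16, h = 16)
}

test_that("dynamic matching handles the degenerate and dominant cases", {
  anchors <- toy_anchors()
  strides <- rep(8, 6)
  pred_boxes <- shssd:::cxcywh_to_corners(anchors)
  pred_scores <- matrix(0.5, 6, 1)
  # zero ground truth: everything negative
  asg <- dynamic_match(pred_boxes, pred_scores, shssd:::empty_box_set(),
                       anchors, strides)
  expect_equal(asg$label, rep(0L, 6))
  expect_length(asg$pos, 0)
  # one GT exactly on one anchor, others far: that anchor positive
  gt <- box_set(12, 12, 28, 28, label = 1L)
  asg2 <- dynamic_match(pred_boxes, pred_scores, gt, anchors, strides)
  expect_true(1L %in% asg2$pos)
  expect_equal(asg2$label[1], 1L)
})

test_that("dynamic matching equals the independent rule enumeration", {
  set.seed(5)
  for (trial in 1:20) {
    anchors <- toy_anchors()
    strides <- rep(8, 6)
    pred_boxes <- shssd:::decode_boxes(matrix(rnorm(24, 0, 0.2), 6, 4), anchors)
    pred_scores <- matrix(runif(6), 6, 1)
    g1 <- c(sort(runif(2, 5, 70)), sort(runif(2, 5, 70)))[c(1, 3, 2, 4)]
    g2 <- c(sort(runif(2, 5, 70)), sort(runif(2, 5, 70)))[c(1, 3, 2, 4)]
    gt <- box_set(c(g1[1], g2[1]), c(g1[2], g2[2]),
                  c(g1[3] + 5, g2[3] + 5), c(g1[4] + 5, g2[4] + 5))
    asg <- dynamic_match(pred_boxes, pred_scores, gt, anchors, strides)
    oracle <- oracle_dynamic_match(pred_boxes, pred_scores, gt, anchors, strides)
    expect_equal(asg$label, oracle)
    # no anchor serves two ground truths; k never exceeds candidates
    expect_true(all(table(asg$label[asg$label > 0]) >= 1))
  }
})

test_that("dynamic matching is permutation-equivariant in ground-truth order", {
  set.seed(6)
  anchors <- toy_anchors()
  strides <- rep(8, 6)
  pred_boxes <- shssd:::decode_boxes(matrix(rnorm(24, 0, 0.1), 6, 4), anchors)
  pred_scores <- matrix(runif(6), 6, 1)
  gt <- box_set(c(10, 50, 12), c(10, 50, 48), c(30, 70, 32), c(30, 70, 70))
  a1 <- dynamic_match(pred_boxes, pred_scores, gt, anchors, strides)
  perm <- c(3L, 1L, 2L)
  a2 <- dynamic_match(pred_boxes, pred_scores, gt[perm, ], anchors, strides)
  # relabel a2 back through the permutation
  relab <- a2$label
  relab[relab > 0] <- perm[relab[relab > 0]]
  expect_equal(relab, a1$label)
})

test_that("detection loss is exact on hand-computed instances", {
  anchors <- toy_anchors()
  # perfect predictions: zero regression loss
  gt <- box_set(12, 12, 28, 28, label = 1L)
  asg <- structure(list(label = c(1L, rep(0L, 5)), pos = 1L,
                        targets = rbind(c(0, 0, 0, 0))), class = "assignment")
  cls <- matrix(-4, 6, 1); cls[1, 1] <- 4
  reg <- matrix(0, 6, 4)
  ls <- detection_loss(cls, reg, asg, gt$label)
  expect_equal(ls$reg_loss, 0)
  expect_gt(ls$cls_loss, 0)
  # all-negative assignment: only background cross-entropy, no regression
  asg0 <- structure(list(label = rep(0L, 6), pos = integer(0), targets = NULL),
                    class = "assignment")
  ls0 <- detection_loss(cls, reg, asg0, gt$label, neg_ratio = 6)
  expect_equal(ls0$reg_loss, 0)
  # hand value: with neg_ratio = 6 and n_pos = 0 all six anchors are mined;
  # anchor 1 (logit 4) dominates the background cross-entropy
  p <- shssd:::sigmoid(c(4, -4))
  expect_equal(ls0$cls_loss,
               -log(1 - p[1]) - 5 * log(1 - p[2]), tolerance = 1e-10)
  # single positive anchor with known offsets: smooth-L1 by hand
  asg1 <- structure(list(label = c(1L, rep(0L, 5)), pos = 1L,
                         targets = rbind(c(0.5, -2, 0.2, 0))),
                    class = "assignment")
  reg1 <- matrix(0, 6, 4)
  ls1 <- detection_loss(cls, reg1, asg1, gt$label)
  expect_equal(ls1$reg_loss, 0.5 * 0.5^2 + (2 - 0.5) + 0.5 * 0.2^2 + 0)
  # classification term: BCE of the positive plus mined negatives
  expect_equal(ls1$cls_loss,
               -log(shssd:::sigmoid(4)) - 3 * log(1 - shssd:::sigmoid(-4)),
               tolerance = 1e-10)
})

test_that("loss gradients agree with finite differences", {
  set.seed(7)
  anchors <- toy_anchors()
  gt <- box_set(c(12, 40), c(12, 50), c(30, 70), c(30, 72))
  cls <- matrix(rnorm(6), 6, 1)
  reg <- matrix(rnorm(24, 0, 0.3), 6, 4)
  pb <- shssd:::decode_boxes(reg, anchors)
  asg <- dynamic_match(pb, shssd:::sigmoid(cls), gt, anchors, rep(8, 6))
  ls <- detection_loss(cls, reg, asg, gt$label)
  f <- function(cl, rg) {
    l <- detection_loss(cl, rg, asg, gt$label)
    l$cls_loss + l$reg_loss
  }
  eps <- 1e-6
  for (i in sample(length(cls), 4)) {
    c1 <- cls; c1[i] <- c1[i] + eps
    c2 <- cls; c2[i] <- c2[i] - eps
    expect_equal(ls$dcls[i], (f(c1, reg) - f(c2, reg)) / (2 * eps), tolerance = 1e-4)
  }
  for (i in sample(length(reg), 4)) {
    r1 <- reg; r1[i] <- r1[i] + eps
    r2 <- reg; r2[i] <- r2[i] - eps
    expect_equal(ls$dreg[i], (f(cls, r1) - f(cls, r2)) / (2 * eps), tolerance = 1e-4)
  }
})
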