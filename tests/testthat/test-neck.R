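test_that("SPP quadruples channels, preserves constants and spatial size", {
  set.seed(1)
  spp <- shssd:::nn_spp(c(5, 9, 13))
  x <- array(runif(15 * 15 * 4), c(15, 15, 4, 1))
  y <- spp$forward(x, FALSE)
  expect_equal(dim(y), c(15, 15, 16, 1))
  # max-pool of a constant is the constant: output = input replicated 4x
  cst <- array(2.5, c(15, 15, 4, 1))
  yc <- spp$forward(cst, FALSE)
  expect_true(all(yc == 2.5))
  expect_error(shssd:::nn_spp(c(4, 9, 13)), "odd")
})

test_that("SPP equals the brute-force sliding-window maximum", {
  set.seed(2)
  for (trial in 1:5) {
    x <- array(rnorm(9 * 9 * 8), c(9, 9, 8, 1))
    spp <- shssd:::nn_spp(c(3, 5, 7))
    y <- spp$forward(x, FALSE)
    expect_equal(y[, , 1:8, , drop = FALSE], x)
    for (ki in 1:3) {
      k <- c(3, 5, 7)[ki]
      expect_equal(y[, , 8 * ki + 1:8, , drop = FALSE], brute_window_max(x, k))
    }
  }
  # single-pixel peak dilates to a k x k plateau
  pk <- array(0, c(9, 9, 1, 1)); pk[5, 5, 1, 1] <- 1
  y <- shssd:::nn_spp(c(5, 5, 5))$forward(pk, FALSE)
  expect_equal(sum(y[, , 2, ] == 1), 25)
})

test_that("neck branches are computed independently", {
  set.seed(3)
  m <- sh_ssd("tiny")
  x <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  base <- shssd:::forward_shssd(m, x)
  # perturb only the stride-8 tap by replacing branch 1's input: feed the
  # branches directly
  cfg <- backbone_config("tiny")
  taps_ch <- cfg$out[match(1:3, cfg$tap)]
  t1 <- array(runif(12 * 12 * taps_ch[1]), c(12, 12, taps_ch[1], 1))
  t2 <- array(runif(6 * 6 * taps_ch[2]), c(6, 6, taps_ch[2], 1))
  t3 <- array(runif(3 * 3 * taps_ch[3]), c(3, 3, taps_ch[3], 1))
  p2a <- m$branches[[2]]$forward(t2, FALSE)
  p3a <- m$branches[[3]]$forward(t3, FALSE)
  invisible(m$branches[[1]]$forward(t1 + 5, FALSE))  # perturb branch 1 only
  p2b <- m$branches[[2]]$forward(t2, FALSE)
  p3b <- m$branches[[3]]$forward(t3, FALSE)
  expect_identical(p2a, p2b)
  expect_identical(p3a, p3b)
  # all three branch outputs share the head width and input spatial size
  p1 <- m$branches[[1]]$forward(t1, FALSE)
  expect_equal(dim(p1)[1:2], c(12, 12))
  w <- shssd:::neck_config("tiny")$width
  expect_equal(dim(p1)[3], w)
  expect_equal(dim(p2a)[3], w)
  expect_equal(dim(p3a)[3], w)
})

test_that("branch module counts follow the 10/9/8 layout", {
  m <- sh_ssd("tiny")
  n_modules <- vapply(m$branches, function(b) length(b$children), integer(1))
  # branch1: 2 DW-CBR + SPP + 2 CBR + 5 TAneck = 10
  # branch2: 2 DW-CBR + SPP + 2 CBR + 4 TAneck = 9
  # branch3: 2 DW-CBR + 2 CBR + 4 TAneck = 8 (no SPP)
  expect_equal(n_modules, c(10L, 9L, 8L))
  has_spp <- vapply(m$branches, function(b) {
    any(vapply(b$children, inherits, logical(1), "nn_spp"))
  }, logical(1))
  expect_equal(has_spp, c(TRUE, TRUE, FALSE))
})
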