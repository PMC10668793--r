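test_that("triple attention preserves shape and gates lie in (0,1)", {
  set.seed(1)
  ta <- shssd:::nn_ta()
  for (d in list(c(8, 8, 3, 1), c(9, 7, 5, 2), c(12, 12, 1, 1))) {
    x <- array(runif(prod(d)), d)
    y <- ta$forward(x, train = FALSE)
    expect_equal(dim(y), d)
  }
  gb <- shssd:::nn_gate_branch()
  x <- array(rnorm(10 * 10 * 4), c(10, 10, 4, 1))
  invisible(gb$forward(x, train = FALSE))
  expect_true(all(gb$gate > 0 & gb$gate < 1))
})

test_that("a zero-variance gate map passes through batch-norm as the 0.5 gate", {
  # when the pooled-and-convolved map is constant, batch normalization
  # outputs 0 everywhere (fresh scale 1 / shift 0), sigmoid(0) = 0.5, and
  # every branch gates x by exactly 0.5; zeroing the 7x7 kernels makes the
  # map constant regardless of padding
  set.seed(2)
  ta <- shssd:::nn_ta()
  for (br in ta$children) br$conv$w[] <- 0
  x <- array(3.7, c(9, 9, 4, 1))
  y <- ta$forward(x, train = TRUE)
  expect_equal(y, 0.5 * x, tolerance = 1e-12)
})

test_that("parameter counting matches closed-form layer arithmetic", {
  conv <- shssd:::nn_conv(3, 16, 3)
  expect_equal(count_parameters(conv), 432)           # 3*16*9, no bias
  cbr <- shssd:::nn_cbr(3, 16, 3)
  expect_equal(count_parameters(cbr), 432 + 32)       # BN adds 2C
  # TA block: 3 branches x (7x7 conv 2->1 without bias + BN scale/shift)
  for (C in c(3, 16, 960)) {
    expect_equal(count_parameters(shssd:::nn_ta()), 300)
  }
  # replacing TA with identity changes a bottleneck by exactly 300
  set.seed(3)
  with_ta <- shssd:::nn_taneck(8, 16, 8, 3, 1, "ta", TRUE)
  without <- shssd:::nn_taneck(8, 16, 8, 3, 1, "none", TRUE)
  expect_equal(count_parameters(with_ta) - count_parameters(without), 300)
})

test_that("TAneck respects stride, residual and ablation contracts", {
  set.seed(4)
  # stride 2 halves spatial dims
  tn <- shssd:::nn_taneck(4, 8, 6, 3, 2, "ta", FALSE)
  y <- tn$forward(array(runif(16 * 16 * 4), c(16, 16, 4, 1)), FALSE)
  expect_equal(dim(y), c(8, 8, 6, 1))
  # residual identity when the projection BN is zeroed
  tn2 <- shssd:::nn_taneck(4, 8, 4, 3, 1, "ta", TRUE)
  bn_proj <- tn2$project$children[[2]]
  bn_proj$gamma[] <- 0
  bn_proj$beta[] <- 0
  x <- array(runif(10 * 10 * 4), c(10, 10, 4, 1))
  expect_equal(tn2$forward(x, TRUE), x)
  # invalid residual configuration fails at build time
  expect_error(shssd:::nn_taneck(4, 8, 6, 3, 1, "ta", TRUE), "residual")
  expect_error(shssd:::nn_taneck(4, 8, 4, 3, 2, "ta", TRUE), "residual")
})

test_that("backbone taps come out at strides 8/16/32 with configured widths", {
  set.seed(5)
  m <- sh_ssd("tiny")
  x <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  maps <- shssd:::forward_shssd(m, x)
  dims <- lapply(maps, function(l) dim(l$cls))
  expect_equal(dims[[1]][1:2], c(12, 12))   # 96 / 8
  expect_equal(dims[[2]][1:2], c(6, 6))     # 96 / 16
  expect_equal(dims[[3]][1:2], c(3, 3))     # 96 / 32
  expect_error(shssd:::forward_shssd(m, array(0, c(100, 100, 3, 1))),
               "divisible by 32")
  # deterministic in inference mode
  m2 <- sh_ssd("tiny")
  maps2 <- shssd:::forward_shssd(m, x)
  expect_identical(maps[[1]]$cls, maps2[[1]]$cls)
})

test_that("full-size model produces three scales on a 64x64 probe", {
  set.seed(6)
  m <- sh_ssd("full")
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  maps <- shssd:::forward_shssd(m, x)
  expect_equal(vapply(maps, function(l) dim(l$cls)[1], numeric(1)), c(8, 4, 2))
  expect_equal(dim(maps[[1]]$cls)[3], 3)    # A * K = 3 * 1
  expect_equal(dim(maps[[1]]$reg)[3], 12)   # A * 4
})

test_that("composite blocks backpropagate exact gradients", {
  set.seed(7)
  m <- shssd:::nn_seq(
    shssd:::nn_cbr(3, 6, 3, 2),
    shssd:::nn_taneck(6, 12, 6, 3, 1, "ta", TRUE),
    shssd:::nn_spp(c(3, 5, 7)),
    shssd:::nn_conv(24, 2, 1, bias = TRUE))
  x <- array(runif(14 * 14 * 3 * 2), c(14, 14, 3, 2))
  y <- m$forward(x, TRUE)
  R <- array(rnorm(length(y)), dim(y))
  f <- function(xx) sum(m$forward(xx, TRUE) * R)
  invisible(m$forward(x, TRUE))
  shssd:::nn_zero_grad(m)
  dx <- m$backward(R)
  eps <- 1e-5
  for (i in sample(length(x), 10)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    expect_equal(dx[i], (f(x1) - f(x2)) / (2 * eps), tolerance = 1e-4)
  }
  for (p in shssd:::nn_params(m)[c(1, 4, 9)]) {
    w <- p$env[[p$name]]
    g <- p$env[[paste0("g", p$name)]]
    i <- sample(length(w), 1)
    w1 <- w; w1[i] <- w1[i] + eps; p$env[[p$name]] <- w1; f1 <- f(x)
    w1[i] <- w[i] - eps; p$env[[p$name]] <- w1; f2 <- f(x)
    p$env[[p$name]] <- w
    expect_equal(g[i], (f1 - f2) / (2 * eps), tolerance = 1e-4)
  }
})
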