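# Composite blocks of the detector: CBR, DW-CBR, triple attention (TA),
# squeeze-excite (SE, for the plain-backbone ablation), TAneck bottleneck,
# and spatial pyramid pooling.

# conv -> BN -> ReLU6 (activation fused into the normalization kernel)
nn_cbr <- function(cin, cout, k, stride = 1L) {
  nn_seq(nn_conv(cin, cout, k, stride), nn_bn(cout, relu6 = TRUE))
}

# depthwise conv -> BN -> ReLU6 (channel count unchanged)
nn_dw_cbr <- function(c, k, stride = 1L) {
  nn_seq(nn_dwconv(c, k, stride), nn_bn(c, relu6 = TRUE))
}

# ---- axis reductions over dim 3 of an [H,W,C,N] array ------------------

reduce_max3 <- function(x) {
  d <- dim(x)
  y <- x[, , 1L, , drop = FALSE]
  idx <- array(1L, dim(y))
  if (d[3] > 1L) for (c in 2:d[3]) {
    xc <- x[, , c, , drop = FALSE]
    upd <- xc > y
    y[upd] <- xc[upd]
    idx[upd] <- c
  }
  list(y = y, idx = idx)
}

reduce_mean3 <- function(x) {
  d <- dim(x)
  y <- x[, , 1L, , drop = FALSE]
  if (d[3] > 1L) for (c in 2:d[3]) y <- y + x[, , c, , drop = FALSE]
  y / d[3]
}

reduce_sum3 <- function(x) reduce_mean3(x) * dim(x)[3]

bcast3 <- function(g, C) g[, , rep(1L, C), , drop = FALSE]

# concatenate a list of [H,W,Ci,N] arrays along dim 3
concat3 <- function(xs) {
  Cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  d <- dim(xs[[1]])
  y <- array(0, c(d[1], d[2], sum(Cs), d[4]))
  off <- 0L
  for (x in xs) {
    y[, , off + seq_len(dim(x)[3]), ] <- x
    off <- off + dim(x)[3]
  }
  y
}

# One attention branch acting on dim 3 of its (possibly permuted) input:
# stack(max, mean) over dim 3 -> 7x7 conv (2->1, no bias) -> BN -> sigmoid
# gate -> elementwise multiply.
nn_gate_branch <- function() {
  m <- new_module("nn_gate_branch")
  m$conv <- nn_conv(2L, 1L, 7L)
  m$bn <- nn_bn(1L)
  m$sig <- nn_sigmoid()
  m$children <- list(m$conv, m$bn, m$sig)
  m$forward <- function(x, train = FALSE) {
    m$x <- x
    red <- cpp_reduce3(x)
    m$mx_idx <- red$idx
    pooled <- concat3(list(red$max, red$mean))
    g <- m$sig$forward(m$bn$forward(m$conv$forward(pooled, train), train), train)
    m$gate <- g
    cpp_bcast_mul(x, g)
  }
  m$backward <- function(dy) {
    # gate gradient needs the conv/bn/sigmoid chain first
    d <- dim(m$x)
    dg0 <- cpp_gate_dg(dy, m$x)
    dpooled <- m$conv$backward(m$bn$backward(m$sig$backward(dg0)))
    dmx <- dpooled[, , 1L, , drop = FALSE]
    dmn <- dpooled[, , 2L, , drop = FALSE]
    out <- cpp_gate_bw(dy, m$x, m$gate, m$mx_idx, dmx, dmn)
    out$dx
  }
  m
}

# Triple attention: three gate branches, each reducing a different axis
# (channel, height, width) via permutation, outputs averaged. Exactly 300
# trainable parameters regardless of input channels.
nn_ta <- function() {
  m <- new_module("nn_ta")
  m$b_c <- nn_gate_branch()  # pools over channels
  m$b_h <- nn_gate_branch()  # pools over height (permuted HWCN -> CWHN)
  m$b_w <- nn_gate_branch()  # pools over width  (permuted HWCN -> HCWN)
  m$children <- list(m$b_c, m$b_h, m$b_w)
  ph <- c(3L, 2L, 1L, 4L)    # self-inverse permutations
  pw <- c(1L, 3L, 2L, 4L)
  m$forward <- function(x, train = FALSE) {
    y1 <- m$b_c$forward(x, train)
    y2 <- aperm(m$b_h$forward(aperm(x, ph), train), ph)
    y3 <- aperm(m$b_w$forward(aperm(x, pw), train), pw)
    (y1 + y2 + y3) / 3
  }
  m$backward <- function(dy) {
    dy3 <- dy / 3
    dx <- m$b_c$backward(dy3)
    dx <- dx + aperm(m$b_h$backward(aperm(dy3, ph)), ph)
    dx + aperm(m$b_w$backward(aperm(dy3, pw)), pw)
  }
  m
}

# Squeeze-and-excitation (reduction 4, ReLU + sigmoid, biased 1x1 convs);
# used only by the plain-MobileNetV3 ablation variant.
nn_se <- function(c, reduction = 4L) {
  m <- new_module("nn_se")
  r <- max(1L, c %/% reduction)
  m$fc1 <- nn_conv(c, r, 1L, bias = TRUE)
  m$fc2 <- nn_conv(r, c, 1L, bias = TRUE)
  m$relu <- nn_relu6()
  m$sig <- nn_sigmoid()
  m$children <- list(m$fc1, m$relu, m$fc2, m$sig)
  m$forward <- function(x, train = FALSE) {
    d <- dim(x)
    m$x <- x; m$d <- d
    # global average pool to [1,1,C,N]
    pooled <- array(colSums(matrix(x, d[1] * d[2], d[3] * d[4])) / (d[1] * d[2]),
                    c(1L, 1L, d[3], d[4]))
    g <- m$sig$forward(m$fc2$forward(m$relu$forward(m$fc1$forward(pooled, train), train), train), train)
    m$gate <- g
    x * array(rep(as.vector(g), each = d[1] * d[2]), d)
  }
  m$backward <- function(dy) {
    d <- m$d
    gfull <- array(rep(as.vector(m$gate), each = d[1] * d[2]), d)
    dx <- dy * gfull
    dg <- array(colSums(matrix(dy * m$x, d[1] * d[2], d[3] * d[4])), c(1L, 1L, d[3], d[4]))
    dpool <- m$fc1$backward(m$relu$backward(m$fc2$backward(m$sig$backward(dg))))
    dx + array(rep(as.vector(dpool) / (d[1] * d[2]), each = d[1] * d[2]), d)
  }
  m
}

# Inverted bottleneck: 1x1 expand CBR -> depthwise k x k (stride s) CBR ->
# optional attention (TA or SE) -> 1x1 project CBR; residual when configured
# and shape-congruent (stride 1, cin == cout).
nn_taneck <- function(cin, cexp, cout, k, stride = 1L,
                      attention = c("ta", "se", "none"), residual = FALSE) {
  attention <- match.arg(attention)
  if (residual && (stride != 1L || cin != cout)) {
    stop("residual connection requires stride 1 and matching channel shapes")
  }
  if (!k %in% c(3L, 5L)) stop("depthwise kernel must be 3 or 5")
  m <- new_module("nn_taneck")
  m$expand <- nn_cbr(cin, cexp, 1L)
  m$dw <- nn_dw_cbr(cexp, k, stride)
  m$att <- switch(attention, ta = nn_ta(), se = nn_se(cexp), none = NULL)
  m$project <- nn_cbr(cexp, cout, 1L)
  m$residual <- residual
  m$children <- Filter(Negate(is.null), list(m$expand, m$dw, m$att, m$project))
  m$forward <- function(x, train = FALSE) {
    h <- m$dw$forward(m$expand$forward(x, train), train)
    if (!is.null(m$att)) h <- m$att$forward(h, train)
    y <- m$project$forward(h, train)
    if (m$residual) y + x else y
  }
  m$backward <- function(dy) {
    dh <- m$project$backward(dy)
    if (!is.null(m$att)) dh <- m$att$backward(dh)
    dx <- m$expand$backward(m$dw$backward(dh))
    if (m$residual) dx + dy else dx
  }
  m
}

# Spatial pyramid pooling: concat(x, maxpool_k1(x), maxpool_k2(x),
# maxpool_k3(x)) along channels; stride-1 pools, size preserved.
nn_spp <- function(kernels = c(5L, 9L, 13L)) {
  if (any(kernels %% 2L == 0L)) stop("SPP kernels must be odd")
  m <- new_module("nn_spp")
  m$kernels <- as.integer(kernels)
  m$forward <- function(x, train = FALSE) {
    d <- dim(x)
    m$d <- d
    pools <- lapply(m$kernels, function(k) cpp_maxpool_fw2(x, k))
    m$args <- lapply(pools, `[[`, "argmax")
    concat3(c(list(x), lapply(pools, `[[`, "y")))
  }
  m$backward <- function(dy) {
    d <- m$d
    C <- d[3]
    dyk <- function(i) {
      sl <- dy[, , (i - 1L) * C + seq_len(C), , drop = FALSE]
      dim(sl) <- d
      sl
    }
    dx <- dyk(1L)
    for (i in seq_along(m$kernels)) {
      dx <- dx + cpp_maxpool_bw(dyk(i + 1L), m$args[[i]])
    }
    dx
  }
  m
}
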