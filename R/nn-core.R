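#' @useDynLib shssd, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif qchisq
NULL

# ---------------------------------------------------------------------------
# Minimal define-by-module neural-network core.
#
# Every module is an environment with:
#   $forward(x, train)  -> y, caching whatever backward needs
#   $backward(dy)       -> dx, accumulating parameter gradients in g<name>
#   $param_names        -> character vector of parameter fields (leaf modules)
#   $children           -> list of submodules (composite modules)
# Tensors are column-major R arrays [H, W, C, N].
# ---------------------------------------------------------------------------

new_module <- function(class) {
  e <- new.env(parent = emptyenv())
  e$param_names <- character(0)
  e$children <- list()
  class(e) <- c(class, "nn_module")
  e
}

#' Enumerate the trainable parameters of a network component
#'
#' Walks the module tree and returns one entry per parameter array, each a
#' list with the owning environment and the field name, so optimizers can
#' update weights in place.
#'
#' @param mod a module (or model) built by the package.
#' @return list of `list(env, name)` handles.
#' @keywords internal
nn_params <- function(mod) {
  out <- list()
  for (nm in mod$param_names) out[[length(out) + 1L]] <- list(env = mod, name = nm)
  for (ch in mod$children) out <- c(out, nn_params(ch))
  out
}

nn_zero_grad <- function(mod) {
  for (p in nn_params(mod)) p$env[[paste0("g", p$name)]] <- NULL
  invisible(mod)
}

acc_grad <- function(env, name, g) {
  gn <- paste0("g", name)
  cur <- env[[gn]]
  env[[gn]] <- if (is.null(cur)) g else cur + g
}

# He-normal conv init; draws from the caller's RNG stream.
init_conv_weight <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))), c(k, k, cin, cout))
}

# --- dense convolution --------------------------------------------------

nn_conv <- function(cin, cout, k, stride = 1L, pad = k %/% 2L, bias = FALSE) {
  m <- new_module("nn_conv")
  m$cin <- cin; m$cout <- cout; m$k <- k; m$stride <- stride; m$pad <- pad
  m$w <- init_conv_weight(k, cin, cout)
  m$param_names <- "w"
  if (bias) {
    m$b <- numeric(cout)
    m$param_names <- c("w", "b")
  }
  m$forward <- function(x, train = FALSE) {
    m$x <- x
    y <- cpp_conv2d_fw(x, m$w, m$stride, m$pad)
    if (!is.null(m$b)) {
      d <- dim(y)
      y <- y + rep(m$b, each = d[1] * d[2])  # recycles over N
    }
    y
  }
  m$backward <- function(dy) {
    g <- cpp_conv2d_bw(m$x, m$w, dy, m$stride, m$pad)
    acc_grad(m, "w", g$dw)
    if (!is.null(m$b)) {
      d <- dim(dy)
      per_cn <- colSums(matrix(dy, d[1] * d[2], d[3] * d[4]))
      acc_grad(m, "b", rowSums(matrix(per_cn, d[3], d[4])))
    }
    g$dx
  }
  m
}

# --- depthwise convolution ----------------------------------------------

nn_dwconv <- function(c, k, stride = 1L, pad = k %/% 2L) {
  m <- new_module("nn_dwconv")
  m$c <- c; m$k <- k; m$stride <- stride; m$pad <- pad
  m$w <- array(rnorm(k * k * c, sd = sqrt(2 / (k * k))), c(k, k, c))
  m$param_names <- "w"
  m$forward <- function(x, train = FALSE) {
    m$x <- x
    cpp_dwconv2d_fw(x, m$w, m$stride, m$pad)
  }
  m$backward <- function(dy) {
    g <- cpp_dwconv2d_bw(m$x, m$w, dy, m$stride, m$pad)
    acc_grad(m, "w", g$dw)
    g$dx
  }
  m
}

# --- batch normalization -------------------------------------------------

# batch normalization, optionally fused with a ReLU6 activation
nn_bn <- function(c, eps = 1e-5, momentum = 0.1, relu6 = FALSE) {
  m <- new_module("nn_bn")
  m$c <- c; m$eps <- eps; m$momentum <- momentum; m$relu6 <- relu6
  m$gamma <- rep(1, c); m$beta <- rep(0, c)
  m$run_mean <- rep(0, c); m$run_var <- rep(1, c)
  m$param_names <- c("gamma", "beta")
  m$forward <- function(x, train = FALSE) {
    if (train) {
      st <- cpp_bn_stats(x)
      mu <- st$mean; va <- st$var
      m$run_mean <- (1 - m$momentum) * m$run_mean + m$momentum * mu
      m$run_var <- (1 - m$momentum) * m$run_var +
        m$momentum * va * st$n / max(1, st$n - 1)
    } else {
      mu <- m$run_mean; va <- m$run_var
    }
    istd <- 1 / sqrt(va + m$eps)
    out <- cpp_bn_fw(x, mu, istd, m$gamma, m$beta, m$relu6)
    m$xhat <- out$xhat; m$istd <- istd; m$train_mode <- train
    m$y_relu <- if (m$relu6) out$y else NULL
    out$y
  }
  m$backward <- function(dy) {
    g <- cpp_bn_bw(dy, m$xhat, m$istd, m$gamma, isTRUE(m$train_mode), m$y_relu)
    acc_grad(m, "gamma", g$dgamma)
    acc_grad(m, "beta", g$dbeta)
    g$dx
  }
  m
}

# --- activations ---------------------------------------------------------

nn_relu6 <- function() {
  m <- new_module("nn_relu6")
  m$forward <- function(x, train = FALSE) {
    m$y <- cpp_relu6_fw(x)
    m$y
  }
  m$backward <- function(dy) cpp_relu6_bw(dy, m$y)
  m
}

nn_sigmoid <- function() {
  m <- new_module("nn_sigmoid")
  m$forward <- function(x, train = FALSE) {
    m$y <- 1 / (1 + exp(-x))
    m$y
  }
  m$backward <- function(dy) dy * m$y * (1 - m$y)
  m
}

# --- containers ----------------------------------------------------------

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  m <- new_module("nn_seq")
  m$children <- mods
  m$forward <- function(x, train = FALSE) {
    for (ch in m$children) x <- ch$forward(x, train)
    x
  }
  m$backward <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$backward(dy)
    dy
  }
  m
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars in a network component or full model:
#' convolution kernels, conv biases, and batch-norm scale/shift pairs
#' (running statistics are not trainable and are excluded).
#'
#' @param x a model built by [sh_ssd()] or any internal module.
#' @return integer scalar.
#' @export
#' @examples
#' m <- sh_ssd("tiny")
#' count_parameters(m)
count_parameters <- function(x) {
  if (inherits(x, "sh_ssd")) {
    return(sum(vapply(x$modules, count_parameters, numeric(1))))
  }
  sum(vapply(nn_params(x), function(p) length(p$env[[p$name]]), numeric(1)))
}
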