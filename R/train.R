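# Adam optimizer and the training loop wiring forward pass, dynamic
# matching, detection loss and backward pass together.

adam_state <- function(params) {
  lapply(params, function(p) {
    w <- p$env[[p$name]]
    list(m = array(0, dim(w) %||% length(w)), v = array(0, dim(w) %||% length(w)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$env[[paste0("g", p$name)]]
    if (is.null(g)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mh <- st$m / (1 - beta1^t)
    vh <- st$v / (1 - beta2^t)
    p$env[[p$name]] <- p$env[[p$name]] - lr * mh / (sqrt(vh) + eps)
    state[[i]] <- st
  }
  state
}

# per-anchor row ranges of each pyramid level in the flattened layout
level_offsets <- function(anchors) {
  ends <- cumsum(anchors$counts)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

# scatter flat per-anchor gradients back into [H,W,A*K,N] map gradients
unflatten_grads <- function(maps, dcls, dreg, rows_by_level, A, K, n) {
  lapply(seq_along(maps), function(l) {
    d <- dim(maps[[l]]$cls)
    HW <- d[1] * d[2]
    rows <- rows_by_level[[l]]
    gc <- array(0, c(d[1], d[2], d[3], 1L))
    dr <- dim(maps[[l]]$reg)
    gr <- array(0, c(dr[1], dr[2], dr[3], 1L))
    for (a in seq_len(A)) {
      sub <- rows[(a - 1L) * HW + seq_len(HW)]
      for (k in seq_len(K)) gc[, , (a - 1L) * K + k, 1L] <- dcls[sub, k]
      for (j in 1:4) gr[, , (a - 1L) * 4L + j, 1L] <- dreg[sub, j]
    }
    list(cls = gc, reg = gr)
  })
}

#' Train an SH-SSD detector
#'
#' Minimizes the detection loss (mined binary cross-entropy +
#' smooth-L1) with Adam, using dynamic sample matching recomputed from the
#' current predictions at every step. The published schedule (learning
#' rate 5e-4, batch 32, decay every 100 epochs over 300 epochs) is the
#' default; CPU-scale experiments pass smaller values.
#'
#' @param model an [sh_ssd()] model (modified in place and returned).
#' @param samples list of training samples, each
#'   `list(image = [H,W,3] array 0..255, boxes = [n,4] matrix, labels =
#'   integer class ids)`.
#' @param steps number of optimizer steps.
#' @param batch_size images per step.
#' @param lr initial learning rate.
#' @param lr_decay_every decay interval in steps (0 = no decay).
#' @param lr_decay_factor multiplicative decay.
#' @param neg_ratio mined negatives per positive in the classification
#'   term (see [detection_loss()]); short CPU-scale runs benefit from a
#'   larger ratio than the 3:1 default so false positives are suppressed
#'   quickly.
#' @param match_args extra arguments for [dynamic_match()] (for example
#'   `list(k_max = 2)` to tighten the per-ground-truth positive budget on
#'   short schedules).
#' @param ema_decay exponential-moving-average decay for the weights
#'   (0 disables). With EMA on, the averaged weights are written back into
#'   the model at the end of training, which smooths the noisy endgame of
#'   short runs.
#' @param verbose print loss every `verbose` steps (0 = silent).
#' @return the model, invisibly, with a `history` attribute
#'   (data.frame of per-step losses).
#' @export
train_shssd <- function(model, samples, steps = 300L, batch_size = 8L,
                        lr = 5e-4, lr_decay_every = 0L,
                        lr_decay_factor = 0.1, neg_ratio = 3,
                        ema_decay = 0, match_args = list(), verbose = 0L) {
  params <- unlist(lapply(model$modules, nn_params), recursive = FALSE)
  state <- adam_state(params)
  ema <- if (ema_decay > 0) lapply(params, function(p) p$env[[p$name]]) else NULL
  A <- model$anchors_per_cell
  K <- model$num_classes
  d1 <- dim(samples[[1]]$image)
  anchors <- anchor_grid(model, d1[1:2])
  strides_per_anchor <- rep(model$strides, anchors$counts)
  rows_by_level <- level_offsets(anchors)
  hist <- data.frame(step = integer(0), cls = numeric(0), reg = numeric(0))
  for (t in seq_len(steps)) {
    idx <- sample.int(length(samples), min(batch_size, length(samples)))
    x <- array(0, c(d1[1], d1[2], 3L, length(idx)))
    for (b in seq_along(idx)) x[, , , b] <- samples[[idx[b]]]$image / 255
    maps <- forward_shssd(model, x, train = TRUE)
    for (m in model$modules) nn_zero_grad(m)
    grads <- NULL
    cls_tot <- reg_tot <- 0
    for (b in seq_along(idx)) {
      flat <- lapply(maps, flatten_level, A = A, K = K, n = b)
      cls <- do.call(rbind, lapply(flat, `[[`, "cls"))
      reg <- do.call(rbind, lapply(flat, `[[`, "reg"))
      sm <- samples[[idx[b]]]
      gt <- if (nrow(sm$boxes)) {
        box_set(sm$boxes[, 1], sm$boxes[, 2], sm$boxes[, 3], sm$boxes[, 4],
                label = sm$labels)
      } else empty_box_set()
      pred_boxes <- decode_boxes(reg, anchors$all)
      asg <- do.call(dynamic_match,
                     c(list(pred_boxes, sigmoid(cls), gt, anchors$all,
                            strides_per_anchor), match_args))
      ls <- detection_loss(cls, reg, asg, gt$label, neg_ratio = neg_ratio)
      cls_tot <- cls_tot + ls$cls_loss
      reg_tot <- reg_tot + ls$reg_loss
      g <- unflatten_grads(maps, ls$dcls, ls$dreg, rows_by_level, A, K, b)
      if (is.null(grads)) {
        grads <- lapply(g, function(l) {
          list(cls = array(0, c(dim(l$cls)[1:3], length(idx))),
               reg = array(0, c(dim(l$reg)[1:3], length(idx))))
        })
      }
      for (l in seq_along(g)) {
        grads[[l]]$cls[, , , b] <- g[[l]]$cls
        grads[[l]]$reg[, , , b] <- g[[l]]$reg
      }
    }
    nb <- length(idx)
    grads <- lapply(grads, function(l) list(cls = l$cls / nb, reg = l$reg / nb))
    backward_shssd(model, grads)
    cur_lr <- lr
    if (lr_decay_every > 0L) {
      cur_lr <- lr * lr_decay_factor^((t - 1L) %/% lr_decay_every)
    }
    state <- adam_step(params, state, cur_lr, t)
    if (!is.null(ema)) {
      d <- min(ema_decay, (t + 1) / (t + 10))   # warmup
      for (i in seq_along(params)) {
        ema[[i]] <- d * ema[[i]] + (1 - d) * params[[i]]$env[[params[[i]]$name]]
      }
    }
    hist <- rbind(hist, data.frame(step = t, cls = cls_tot / nb, reg = reg_tot / nb))
    if (verbose > 0L && t %% verbose == 0L) {
      message(sprintf("step %d: cls %.4f reg %.4f (lr %.2g)",
                      t, cls_tot / nb, reg_tot / nb, cur_lr))
    }
  }
  if (!is.null(ema)) {
    for (i in seq_along(params)) params[[i]]$env[[params[[i]]$name]] <- ema[[i]]
  }
  attr(model, "history") <- hist
  invisible(model)
}

#' Recalibrate batch-norm running statistics
#'
#' After a short training run the exponential running averages in the
#' normalization layers can lag the activations the network was actually
#' trained with, which degrades inference-mode predictions. This pass
#' recomputes every layer's running mean/variance as the plain average of
#' the batch statistics over the given images ("precise BN").
#'
#' @param model an [sh_ssd()] model.
#' @param samples training samples (as for [train_shssd()]).
#' @param passes how many averaging passes over the samples.
#' @return the model, invisibly, with updated running statistics.
#' @export
recalibrate_bn <- function(model, samples, passes = 1L) {
  bns <- unlist(lapply(model$modules, collect_bn), recursive = FALSE)
  saved <- lapply(bns, `[[`, "momentum")
  n_seen <- 0L
  d1 <- dim(samples[[1]]$image)
  for (p in seq_len(passes)) {
    for (s in samples) {
      n_seen <- n_seen + 1L
      for (b in bns) b$momentum <- 1 / n_seen   # cumulative average
      x <- array(s$image / 255, c(d1[1], d1[2], 3L, 1L))
      invisible(forward_shssd(model, x, train = TRUE))
    }
  }
  for (i in seq_along(bns)) bns[[i]]$momentum <- saved[[i]]
  invisible(model)
}
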