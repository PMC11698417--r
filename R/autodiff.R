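# Minimal reverse-mode autodiff tape over dense arrays, sized for the small
# encoder-decoder networks in this package.  Tensors are environments holding
# `val` (an (H, W, C, N) array or a (C, N) matrix) and `grad`; forward ops
# append nodes to a tape whose recorded order is the topological order used
# by `tape_backward()`.  Parameters are off-tape nodes whose gradients
# accumulate across the backward sweep.

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

nd <- function(tape, val, parents = list(), bwd = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$bwd <- bwd
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- n
  }
  n
}

param_node <- function(val) nd(NULL, val)

accumulate_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

tape_backward <- function(tape, loss, seed_grad = 1) {
  loss$grad <- seed_grad
  for (i in rev(seq_len(tape$n))) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad) || is.null(n$bwd)) next
    gs <- n$bwd(n$grad)
    for (j in seq_along(n$parents)) {
      if (!is.null(gs[[j]])) accumulate_grad(n$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- broadcasting helpers on (H, W, C, N) arrays ------------------------

expand_channel <- function(m, H, W) {
  # m: (C, N) matrix -> (H, W, C, N) array, constant over pixels
  array(rep(as.numeric(m), each = H * W),
        dim = c(H, W, nrow(m), ncol(m)))
}

collapse_channel <- function(a) {
  # sum an (H, W, C, N) array over pixels -> (C, N) matrix
  d <- dim(a)
  matrix(colSums(matrix(a, d[1] * d[2])), d[3], d[4])
}

expand_spatial <- function(m, C) {
  # m: (H, W, 1, N) -> (H, W, C, N)
  m[, , rep(1L, C), , drop = FALSE]
}

collapse_spatial <- function(a) {
  # sum over channels -> (H, W, 1, N)
  d <- dim(a)
  out <- array(0, c(d[1], d[2], 1L, d[4]))
  m <- array(a, c(d[1] * d[2], d[3], d[4]))
  for (n in seq_len(d[4])) {
    out[, , 1L, n] <- rowSums(matrix(m[, , n], ncol = d[3]))
  }
  out
}

# ---- elementwise ops ----------------------------------------------------

op_relu <- function(tape, x) {
  if (!is.null(dim(x$val)) && length(dim(x$val)) == 4) {
    y <- .relu_fw(x$val)
    return(nd(tape, y, list(x), function(g) list(.relu_bw(y, g))))
  }
  y <- x$val * (x$val > 0)
  nd(tape, y, list(x), function(g) list(g * (y > 0)))
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$val))
  nd(tape, y, list(x), function(g) list(g * y * (1 - y)))
}

op_tanh <- function(tape, x) {
  y <- tanh(x$val)
  nd(tape, y, list(x), function(g) list(g * (1 - y * y)))
}

op_add <- function(tape, x, y) {
  nd(tape, x$val + y$val, list(x, y), function(g) list(g, g))
}

# ---- convolution / pooling / resampling --------------------------------

op_conv <- function(tape, x, w, b) {
  pad <- (dim(w$val)[1] - 1L) %/% 2L
  y <- .conv2d_fw(x$val, w$val, b$val, pad)
  nd(tape, y, list(x, w, b), function(g) {
    r <- .conv2d_bw(x$val, w$val, g, pad)
    list(r$gx, r$gw, r$gb)
  })
}

op_maxpool <- function(tape, x) {
  r <- .maxpool2_fw(x$val)
  xd <- dim(x$val)
  nd(tape, r$y, list(x), function(g) list(.maxpool2_bw(g, r$idx, xd)))
}

op_upsample <- function(tape, x) {
  xd <- dim(x$val)
  nd(tape, .upsample2_fw(x$val), list(x),
     function(g) list(.upsample2_bw(g, xd)))
}

op_concat_c <- function(tape, xs) {
  d <- dim(xs[[1]]$val)
  cs <- vapply(xs, function(x) dim(x$val)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    ci <- dim(x$val)[3]
    out[, , at + seq_len(ci), ] <- x$val
    at <- at + ci
  }
  nd(tape, out, xs, function(g) {
    res <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      ci <- cs[i]
      res[[i]] <- g[, , at + seq_len(ci), , drop = FALSE]
      at <- at + ci
    }
    res
  })
}

# ---- batch normalization ------------------------------------------------

op_batchnorm <- function(tape, x, gamma, beta, state, training) {
  if (training) {
    st <- .chan_stats(x$val)
    mu <- st$mean
    v <- pmax(st$meansq - mu^2, 0)
    state$rm <- (1 - state$momentum) * state$rm + state$momentum * mu
    state$rv <- (1 - state$momentum) * state$rv + state$momentum * v
  } else {
    mu <- state$rm
    v <- state$rv
  }
  istd <- 1 / sqrt(v + state$eps)
  xhat <- .chan_affine(x$val, istd, -mu * istd)
  y <- .chan_affine(xhat, gamma$val, beta$val)
  nd(tape, y, list(x, gamma, beta), function(g) {
    r <- .bn_bw(xhat, g, gamma$val, istd, training)
    list(r$dx, r$dgamma, r$dbeta)
  })
}

new_bn_state <- function(C, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$rm <- numeric(C)
  e$rv <- rep(1, C)
  e$momentum <- momentum
  e$eps <- eps
  e
}

# ---- channel attention primitives --------------------------------------

op_gmaxmean <- function(tape, x) {
  # Eq-15-style channel descriptor: global max + global mean, -> (C, N)
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- matrix(x$val, H * W)
  mx <- apply(m, 2, max)
  amx <- max.col(t(m), ties.method = "first")  # first index of the max
  mn <- colMeans(m)
  z <- matrix(mx + mn, C, N)
  nd(tape, z, list(x), function(g) {
    gx <- array(rep(as.numeric(g) / (H * W), each = H * W), dim = d)
    gm <- matrix(gx, H * W)
    gv <- as.numeric(g)
    for (q in seq_len(C * N)) gm[amx[q], q] <- gm[amx[q], q] + gv[q]
    list(array(gm, dim = d))
  })
}

op_matmul <- function(tape, w, z) {
  # w: (out, in) parameter, z: (in, N) -> (out, N)
  nd(tape, w$val %*% z$val, list(w, z), function(g) {
    list(g %*% t(z$val), t(w$val) %*% g)
  })
}

op_addbias_mat <- function(tape, z, b) {
  nd(tape, z$val + b$val, list(z, b), function(g) list(g, rowSums(g)))
}

op_mul_channel <- function(tape, x, alpha) {
  # alpha: (C, N) node broadcast over pixels
  nd(tape, .chan_mul(x$val, alpha$val), list(x, alpha), function(g) {
    list(.chan_mul(g, alpha$val), .chan_dot(g, x$val))
  })
}

op_mul_spatial <- function(tape, x, m) {
  # m: (H, W, 1, N) node broadcast over channels
  d <- dim(x$val)
  m_e <- expand_spatial(m$val, d[3])
  nd(tape, x$val * m_e, list(x, m), function(g) {
    list(g * m_e, collapse_spatial(g * x$val))
  })
}

op_softmax_c <- function(tape, x) {
  d <- dim(x$val)
  K <- d[3]
  mx <- x$val[, , 1, , drop = FALSE]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, x$val[, , k, , drop = FALSE])
  ex <- exp(x$val - expand_spatial(mx, K))
  s <- collapse_spatial(ex)
  y <- ex / expand_spatial(s, K)
  nd(tape, y, list(x), function(g) {
    dot <- collapse_spatial(g * y)
    list(y * (g - expand_spatial(dot, K)))
  })
}

# ---- loss ops (scalar-valued nodes) ------------------------------------

op_weighted_ce <- function(tape, probs, onehot, weights, eps) {
  d <- dim(probs$val)
  N <- d[4]
  w4 <- array(weights, c(d[1], d[2], 1L, N))
  w_e <- expand_spatial(w4, d[3])
  lp <- log(probs$val + eps)
  val <- -sum(w_e * onehot * lp) / (N * d[1] * d[2])
  nd(tape, val, list(probs), function(g) {
    list(-g * w_e * onehot / (probs$val + eps) / (N * d[1] * d[2]))
  })
}

op_dice_loss <- function(tape, probs, onehot, eps) {
  d <- dim(probs$val)
  inter <- collapse_channel(probs$val * onehot)        # (K, N)
  tots <- collapse_channel(probs$val) + collapse_channel(onehot)
  val <- sum(1 - 2 * inter / (tots + eps))
  nd(tape, val, list(probs), function(g) {
    # d/dp [ -2*inter/(tots+eps) ] = -(2*y*(tots+eps) - 2*inter) / (tots+eps)^2
    t_e <- expand_channel(tots + eps, d[1], d[2])
    i_e <- expand_channel(inter, d[1], d[2])
    list(g * (-(2 * onehot * t_e - 2 * i_e) / (t_e * t_e)))
  })
}

op_weighted_mse <- function(tape, pred, target, weights) {
  d <- dim(pred$val)
  N <- d[4]
  w4 <- array(weights, c(d[1], d[2], 1L, N))
  w_e <- expand_spatial(w4, d[3])
  diff <- pred$val - target
  val <- sum(w_e * diff * diff) / (N * d[1] * d[2])
  nd(tape, val, list(pred), function(g) {
    list(g * 2 * w_e * diff / (N * d[1] * d[2]))
  })
}

op_scale_add <- function(tape, xs, coef) {
  # scalar nodes: sum(coef_i * x_i)
  val <- 0
  for (i in seq_along(xs)) val <- val + coef[i] * xs[[i]]$val
  nd(tape, val, xs, function(g) as.list(g * coef))
}

# ---- Adam optimizer -----------------------------------------------------

new_adam <- function(params, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$val * 0)  # keeps each param's shape
  st$v <- st$m
  st$t <- 0L
  st$beta1 <- 0.9
  st$beta2 <- 0.999
  st$eps <- 1e-8
  st$weight_decay <- weight_decay
  st
}

adam_step <- function(st, params, lr) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (st$weight_decay > 0) g <- g + st$weight_decay * p$val
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    p$val <- p$val - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
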