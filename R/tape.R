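# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Nodes are environments holding a value, an accumulated gradient and a
# backward closure.  Because the graph is built strictly feed-forward,
# creation order is a topological order and backward() is a single reverse
# sweep.  Parameters live outside the tape in `param` environments; ops that
# consume parameters accumulate directly into `p$grad`, so one backward pass
# can serve several loss heads and optimizer steps read-and-zero the grads.
#
# Feature-map nodes hold (H, W, C, N) arrays; vector nodes hold (d, N)
# matrices; loss nodes hold scalars.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

accum_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

tp_const <- function(tape, value) tp_node(tape, value)

# Block gradient flow: value passes, backward stops here.
tp_stopgrad <- function(tape, x) tp_node(tape, x$value)

tape_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- parameters -----------------------------------------------------------

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0   # same shape and attributes as the value
  p$m <- p$grad
  p$v <- p$grad
  p
}

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# ---- array ops ------------------------------------------------------------

tp_conv <- function(tape, x, Wp, bp, stride = 1L, pad = 1L) {
  xv <- x$value
  v <- conv2d_fwd_cpp(xv, Wp$value, bp$value, stride, pad)
  tp_node(tape, v, function(nd) {
    r <- conv2d_bwd_cpp(xv, Wp$value, nd$grad, stride, pad)
    Wp$grad <- Wp$grad + r$dw
    bp$grad <- bp$grad + r$db
    accum_grad(x, r$dx)
  })
}

tp_lrelu <- function(tape, x, alpha = 0.2) {
  xv <- x$value
  if (is.null(dim(xv)) || length(dim(xv)) != 4) {
    v <- pmax(xv, 0) + alpha * pmin(xv, 0)
    return(tp_node(tape, v, function(nd) {
      accum_grad(x, nd$grad * (alpha + (1 - alpha) * (xv > 0)))
    }))
  }
  tp_node(tape, lrelu_fwd_cpp(xv, alpha), function(nd) {
    accum_grad(x, lrelu_bwd_cpp(xv, nd$grad, alpha))
  })
}

tp_tanh <- function(tape, x) {
  v <- tanh(x$value)
  tp_node(tape, v, function(nd) accum_grad(x, nd$grad * (1 - v^2)))
}

tp_add <- function(tape, a, b) {
  tp_node(tape, a$value + b$value, function(nd) {
    accum_grad(a, nd$grad)
    accum_grad(b, nd$grad)
  })
}

# multiply by a fixed scalar
tp_scale <- function(tape, x, k) {
  tp_node(tape, x$value * k, function(nd) accum_grad(x, nd$grad * k))
}

# add a fixed array (e.g. the content perturbation eta)
tp_add_const <- function(tape, x, k) {
  tp_node(tape, x$value + k, function(nd) accum_grad(x, nd$grad))
}

# Instance normalization without affine terms: each (channel, sample) map is
# standardized over its spatial extent.
tp_instnorm <- function(tape, x, eps = 1e-5) {
  f <- instnorm_fwd_cpp(x$value, eps)
  tp_node(tape, f$y, function(nd) {
    accum_grad(x, instnorm_bwd_cpp(f$y, f$isd, nd$grad))
  })
}

# Per-(channel, sample) affine modulation from style: y = x * (1 + gain) + bias
# with gain, bias nodes of shape (C, N).
tp_chanaffine <- function(tape, x, gain, bias) {
  gv <- gain$value
  v <- chanaffine_fwd_cpp(x$value, gv, bias$value)
  tp_node(tape, v, function(nd) {
    r <- chanaffine_bwd_cpp(x$value, gv, nd$grad)
    accum_grad(x, r$dx)
    accum_grad(gain, r$dgain)
    accum_grad(bias, r$dbias)
  })
}

# Fully-connected layer on (d_in, N) matrices.
tp_linear <- function(tape, x, Wp, bp) {
  xv <- x$value
  v <- Wp$value %*% xv + bp$value
  tp_node(tape, v, function(nd) {
    Wp$grad <- Wp$grad + nd$grad %*% t(xv)
    bp$grad <- bp$grad + rowSums(nd$grad)
    accum_grad(x, t(Wp$value) %*% nd$grad)
  })
}

# Global average pooling (H, W, C, N) -> (C, N).
tp_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  v <- matrix(colMeans(matrix(x$value, hw, d[3] * d[4])), d[3], d[4])
  tp_node(tape, v, function(nd) {
    accum_grad(x, expand_cn_cpp(nd$grad / hw, d[1], d[2]))
  })
}

# Nearest-neighbour 2x upsampling; backward is 2x2 block summation.
tp_upsample2 <- function(tape, x) {
  d <- dim(x$value)
  tp_node(tape, upsample2_fwd_cpp(x$value), function(nd) {
    accum_grad(x, upsample2_bwd_cpp(nd$grad, d[1], d[2]))
  })
}

# Forward finite difference along spatial axis 1 or 2 with edge replication.
tp_fdiff <- function(tape, x, axis) {
  d <- dim(x$value)
  n <- d[axis]
  idx <- c(seq_len(n - 1L) + 1L, n)
  v <- if (axis == 1) x$value[idx, , , , drop = FALSE] - x$value
       else x$value[, idx, , , drop = FALSE] - x$value
  tp_node(tape, v, function(nd) {
    g <- nd$grad
    dx <- -g
    if (axis == 1) {
      dx[2:n, , , ] <- dx[2:n, , , , drop = FALSE] + g[1:(n - 1), , , , drop = FALSE]
      dx[n, , , ] <- dx[n, , , , drop = FALSE] + g[n, , , , drop = FALSE]
    } else {
      dx[, 2:n, , ] <- dx[, 2:n, , , drop = FALSE] + g[, 1:(n - 1), , , drop = FALSE]
      dx[, n, , ] <- dx[, n, , , drop = FALSE] + g[, n, , , drop = FALSE]
    }
    accum_grad(x, dx)
  })
}

# ---- scalar loss ops ------------------------------------------------------

tp_l1 <- function(tape, a, b) {
  dv <- a$value - b$value
  n <- length(dv)
  tp_node(tape, mean(abs(dv)), function(nd) {
    s <- nd$grad * sign(dv) / n
    accum_grad(a, s)
    accum_grad(b, -s)
  })
}

# 0.5 * mean(x^2): the per-element closed form of KL(N(x, I) || N(0, I)).
tp_half_mean_sq <- function(tape, x) {
  xv <- x$value
  n <- length(xv)
  tp_node(tape, 0.5 * mean(xv^2), function(nd) {
    accum_grad(x, nd$grad * xv / n)
  })
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

# mean log D from logits: mean(-softplus(-l)); ascends toward "real".
tp_mean_logsig <- function(tape, l) {
  lv <- l$value
  n <- length(lv)
  tp_node(tape, mean(-softplus(-lv)), function(nd) {
    accum_grad(l, nd$grad * sigmoid(-lv) / n)
  })
}

# mean log(1 - D) from logits: mean(-softplus(l)).
tp_mean_log1msig <- function(tape, l) {
  lv <- l$value
  n <- length(lv)
  tp_node(tape, mean(-softplus(lv)), function(nd) {
    accum_grad(l, -nd$grad * sigmoid(lv) / n)
  })
}

# Clip a scalar node from above (gradient is zero beyond the ceiling).
tp_clip_max <- function(tape, x, ceiling) {
  clipped <- x$value > ceiling
  tp_node(tape, min(x$value, ceiling), function(nd) {
    if (!clipped) accum_grad(x, nd$grad)
  })
}

# Weighted sum of scalar nodes.
tp_wsum <- function(tape, nodes, weights) {
  v <- sum(vapply(nodes, function(n) n$value, numeric(1)) * weights)
  tp_node(tape, v, function(nd) {
    for (k in seq_along(nodes)) accum_grad(nodes[[k]], nd$grad * weights[k])
  })
}
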