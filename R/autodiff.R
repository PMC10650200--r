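# Minimal reverse-mode automatic differentiation on dense arrays.
#
# A tape records nodes in creation order; each node is an environment holding
# `value`, an accumulated `grad`, its `parents`, and a `backward` closure that
# distributes the node's gradient to its parents. Feature batches are numeric
# arrays with dim (H, W, C, N). Convolutions go through im2col (C++) plus
# BLAS matrix products; the column matrix is recomputed in the backward pass
# rather than cached, trading FLOPs for memory.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

nd_new <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

nd_leaf <- function(tape, value) nd_new(tape, value)

nd_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Back-propagate from a scalar node. Nodes are visited in reverse creation
# order, which is a valid topological order for a tape built by evaluation.
tape_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# ---- array helpers -------------------------------------------------------

# (H,W,C,N) -> matrix (H*W*N) x C
.hwcn_to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
}

# matrix (H*W*N) x C -> (H,W,C,N)
.mat_to_hwcn <- function(m, H, W, N) {
  aperm(array(m, c(H, W, N, ncol(m))), c(1L, 2L, 4L, 3L))
}

# ---- primitive ops -------------------------------------------------------

# 2-D convolution, stride 1, same padding. w: (k,k,Cin,Cout), b: (Cout).
op_conv <- function(tape, x, w, b = NULL) {
  xv <- x$value
  wv <- w$value
  d <- dim(xv)
  k <- dim(wv)[1]
  cout <- dim(wv)[4]
  cols <- cpp_im2col(xv, k)
  wm <- matrix(wv, k * k * d[3], cout)
  y2 <- cols %*% wm
  if (!is.null(b)) for (j in seq_len(cout)) y2[, j] <- y2[, j] + b$value[j]
  yv <- .mat_to_hwcn(y2, d[1], d[2], d[4])
  nd_new(tape, yv, c(list(x, w), if (!is.null(b)) list(b)), backward = function(g) {
    dy2 <- .hwcn_to_mat(g)
    if (!is.null(b)) nd_accum(b, colSums(dy2))
    cols2 <- cpp_im2col(xv, k)
    dw <- crossprod(cols2, dy2)
    dim(dw) <- dim(wv)
    nd_accum(w, dw)
    dcols <- dy2 %*% t(wm)
    nd_accum(x, cpp_col2im(dcols, d[1], d[2], d[3], d[4], k))
  })
}

# Transposed convolution, kernel 2x2, stride 2 (non-overlapping upsampling).
op_conv_transpose2 <- function(tape, x, w, b = NULL) {
  xv <- x$value
  wv <- w$value
  d <- dim(xv)
  cout <- dim(wv)[4]
  H2 <- 2L * d[1]
  W2 <- 2L * d[2]
  m <- .hwcn_to_mat(xv)
  yv <- array(0, c(H2, W2, cout, d[4]))
  for (a in 1:2) for (bb in 1:2) {
    yab <- m %*% matrix(wv[a, bb, , ], d[3], cout)
    yv[seq(a, H2, 2L), seq(bb, W2, 2L), , ] <- .mat_to_hwcn(yab, d[1], d[2], d[4])
  }
  if (!is.null(b)) for (j in seq_len(cout)) yv[, , j, ] <- yv[, , j, ] + b$value[j]
  nd_new(tape, yv, c(list(x, w), if (!is.null(b)) list(b)), backward = function(g) {
    if (!is.null(b)) nd_accum(b, apply(g, 3, sum))
    dm <- matrix(0, nrow(m), d[3])
    dw <- array(0, dim(wv))
    for (a in 1:2) for (bb in 1:2) {
      gab <- .hwcn_to_mat(g[seq(a, H2, 2L), seq(bb, W2, 2L), , , drop = FALSE])
      dw[a, bb, , ] <- crossprod(m, gab)
      dm <- dm + gab %*% t(matrix(wv[a, bb, , ], d[3], cout))
    }
    nd_accum(w, dw)
    nd_accum(x, .mat_to_hwcn(dm, d[1], d[2], d[4]))
  })
}

# Nearest-neighbour 2x upsampling (parameter-free).
op_upsample_nearest <- function(tape, x) {
  xv <- x$value
  d <- dim(xv)
  yv <- xv[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
  nd_new(tape, yv, list(x), backward = function(g) {
    o1 <- seq(1L, 2L * d[1], 2L)
    o2 <- seq(1L, 2L * d[2], 2L)
    dx <- g[o1, o2, , , drop = FALSE] + g[o1 + 1L, o2, , , drop = FALSE] +
      g[o1, o2 + 1L, , , drop = FALSE] + g[o1 + 1L, o2 + 1L, , , drop = FALSE]
    nd_accum(x, dx)
  })
}

op_maxpool <- function(tape, x) {
  res <- cpp_maxpool(x$value)
  xd <- dim(x$value)
  nd_new(tape, res$y, list(x), backward = function(g) {
    nd_accum(x, cpp_maxpool_bw(g, res$idx, xd))
  })
}

op_relu <- function(tape, x) {
  xv <- x$value
  yv <- xv
  yv[yv < 0] <- 0
  nd_new(tape, yv, list(x), backward = function(g) {
    nd_accum(x, g * (xv > 0))
  })
}

op_sigmoid <- function(tape, x) {
  yv <- 1 / (1 + exp(-x$value))
  nd_new(tape, yv, list(x), backward = function(g) {
    nd_accum(x, g * yv * (1 - yv))
  })
}

# Channel concatenation of two (H,W,C,N) batches.
op_concat_ch <- function(tape, a, b) {
  av <- a$value
  bv <- b$value
  da <- dim(av)
  db <- dim(bv)
  yv <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  yv[, , seq_len(da[3]), ] <- av
  yv[, , da[3] + seq_len(db[3]), ] <- bv
  nd_new(tape, yv, list(a, b), backward = function(g) {
    nd_accum(a, g[, , seq_len(da[3]), , drop = FALSE])
    nd_accum(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# Elementwise mean of two same-shape maps: the hyperactive fusion primitive.
op_fuse <- function(tape, a, b) {
  nd_new(tape, (a$value + b$value) / 2, list(a, b), backward = function(g) {
    nd_accum(a, g / 2)
    nd_accum(b, g / 2)
  })
}

# Batch normalization over (H,W,N) per channel. `state` is an environment
# carrying running_mean/running_var (updated in training mode only).
op_batchnorm <- function(tape, x, gamma, beta, state, training, momentum = 0.1,
                         eps = 1e-5) {
  xv <- x$value
  d <- dim(xv)
  m <- d[1] * d[2] * d[4]
  xm <- .hwcn_to_mat(xv)
  if (training) {
    mu <- colMeans(xm)
    ctr <- sweep(xm, 2L, mu)
    va <- colMeans(ctr^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va * m / max(m - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
    ctr <- sweep(xm, 2L, mu)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(ctr, 2L, istd, `*`)
  ym <- sweep(sweep(xhat, 2L, gamma$value, `*`), 2L, beta$value, `+`)
  yv <- .mat_to_hwcn(ym, d[1], d[2], d[4])
  nd_new(tape, yv, list(x, gamma, beta), backward = function(g) {
    gm <- .hwcn_to_mat(g)
    nd_accum(beta, colSums(gm))
    nd_accum(gamma, colSums(gm * xhat))
    dxhat <- sweep(gm, 2L, gamma$value, `*`)
    if (training) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dxm <- sweep(sweep(dxhat, 2L, s1 / m) - sweep(xhat, 2L, s2 / m, `*`),
                   2L, istd, `*`)
    } else {
      dxm <- sweep(dxhat, 2L, istd, `*`)
    }
    nd_accum(x, .mat_to_hwcn(dxm, d[1], d[2], d[4]))
  })
}

# ---- scalar loss ops -----------------------------------------------------

# Mean binary cross-entropy of soft predictions against a {0,1} target array.
op_bce <- function(tape, yhat, y, eps = 1e-7) {
  yc <- pmin(pmax(yhat$value, eps), 1 - eps)
  n <- length(yc)
  val <- -sum(y * log(yc) + (1 - y) * log(1 - yc)) / n
  nd_new(tape, val, list(yhat), backward = function(g) {
    nd_accum(yhat, g * (yc - y) / (yc * (1 - yc)) / n)
  })
}

# 1 - soft Dice; the squared-denominator form with additive smoothing.
op_dice_loss <- function(tape, yhat, y, smooth = 1e-6) {
  hv <- yhat$value
  num <- 2 * sum(y * hv) + smooth
  den <- sum(y^2) + sum(hv^2) + smooth
  nd_new(tape, 1 - num / den, list(yhat), backward = function(g) {
    ddice <- (2 * y * den - num * 2 * hv) / den^2
    nd_accum(yhat, -g * ddice)
  })
}

# w1 * a + w2 * b for scalar loss nodes.
op_wsum <- function(tape, a, b, w1 = 1, w2 = 1) {
  nd_new(tape, w1 * a$value + w2 * b$value, list(a, b), backward = function(g) {
    nd_accum(a, g * w1)
    nd_accum(b, g * w2)
  })
}
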