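# Shared fixtures and independent oracles, built in code at test time.

# In-memory synthetic dataset: stacked standardized images and masks.
make_dataset <- function(n, size, seed0, n_lesions = 2L, ...) {
  xs <- array(0, c(size, size, 3, n))
  ys <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    sp <- synthetic_spec(seed = seed0 + i * 1000003, size = size,
                         n_lesions = n_lesions, ...)
    g <- generate_sample(sp)
    xs[, , , i] <- g$image / 255
    ys[, , i] <- g$mask
  }
  list(x = xs, y = ys)
}

# Closed-form trainable-parameter count for a dual-UNet schedule; written
# from the layer formula (k^2 * Cin * Cout + Cout per biased convolution,
# bias dropped and 2*Cout scale/shift added under batchnorm), independent
# of the package's parameter containers.
oracle_param_count <- function(depth, base, bn, up) {
  conv_p <- function(cin, cout, k) k * k * cin * cout + (if (bn) 2 * cout else cout)
  one <- function(cin) {
    f <- base * 2^(0:depth)
    tot <- 0
    cprev <- cin
    for (i in 1:depth) {
      tot <- tot + conv_p(cprev, f[i], 3) + conv_p(f[i], f[i], 3)
      cprev <- f[i]
    }
    fb <- f[depth + 1]
    tot <- tot + conv_p(cprev, fb, 3) + conv_p(fb, fb, 3)
    cup <- fb
    for (i in depth:1) {
      tot <- tot + (if (up == "transposed") 4 * cup * f[i] + (if (bn) 2 * f[i] else f[i])
                    else conv_p(cup, f[i], 3))
      tot <- tot + conv_p(2 * f[i], f[i], 3) + conv_p(f[i], f[i], 3)
      cup <- f[i]
    }
    tot + (f[1] + 1)
  }
  one(3) + one(4)
}

# Brute-force per-pixel metric recomputation by explicit enumeration.
oracle_metrics <- function(y, y_hat, threshold = 0.5) {
  y <- as.numeric(y)
  hb <- as.numeric(as.numeric(y_hat) >= threshold)
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && hb[i] == 1) tp <- tp + 1
    else if (y[i] == 0 && hb[i] == 1) fp <- fp + 1
    else if (y[i] == 1 && hb[i] == 0) fn <- fn + 1
    else tn <- tn + 1
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  dice <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  list(tp = tp, fp = fp, fn = fn, tn = tn, precision = p, recall = r,
       f1 = f1, dice = dice)
}

# Term-by-term BCE summation.
oracle_bce <- function(y, y_hat, eps = 1e-7) {
  y <- as.numeric(y)
  h <- pmin(pmax(as.numeric(y_hat), eps), 1 - eps)
  s <- 0
  for (i in seq_along(y)) s <- s + y[i] * log(h[i]) + (1 - y[i]) * log(1 - h[i])
  -s / length(y)
}

# Binary dilation of a {0,1} matrix by one pixel (8-neighbourhood).
dilate1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  for (dy in -1:1) for (dx in -1:1) {
    out <- pmax(out, pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)])
  }
  out
}
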