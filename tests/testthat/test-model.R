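toy_cfg <- function(...) dhunet_config(depth = 2, base_filters = 2,
                                       use_batchnorm = FALSE,
                                       upsample_mode = "interp", ...)

test_that("fuse is the elementwise mean", {
  a <- array(c(1, 3), c(1, 1, 2, 1))
  b <- array(c(5, 7), c(1, 1, 2, 1))
  expect_equal(fuse(a, b), array(c(3, 5), c(1, 1, 2, 1)))
  x <- array(runif(8), c(2, 2, 2, 1))
  expect_equal(fuse(array(0, dim(x)), x), x / 2)
  expect_equal(fuse(x, x), x)
  expect_error(fuse(x, array(0, c(2, 2, 1, 1))), "identical shapes")
})

test_that("forward pass respects the shape and sigmoid-range contracts", {
  m <- build_dhunet(toy_cfg(), seed = 1)
  x <- array(runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  out <- dhunet_forward(m, x)
  expect_identical(dim(out$mask1), c(32L, 32L, 3L))
  expect_identical(dim(out$mask2), c(32L, 32L, 3L))
  expect_true(all(out$mask1 > 0 & out$mask1 < 1))
  expect_true(all(out$mask2 > 0 & out$mask2 < 1))
  expect_error(dhunet_forward(m, array(0, c(30, 30, 3, 1))), "divisible")

  # single image without explicit batch axis
  one <- dhunet_forward(m, x[, , , 1])
  expect_identical(dim(one$mask1), c(32L, 32L, 1L))
})

test_that("every fused map equals the mean of its two source maps", {
  for (mode in c("interp", "transposed")) {
    m <- build_dhunet(dhunet_config(depth = 3, base_filters = 4,
                                    upsample_mode = mode,
                                    use_batchnorm = FALSE), seed = 5)
    x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    out <- dhunet_forward(m, x, capture = TRUE)
    p1 <- out$pyramids$unet1
    p2 <- out$pyramids$unet2
    for (i in seq_along(p2$encoder)) {
      expect_lt(max(abs(p2$encoder[[i]] -
                          (p1$encoder[[i]] + p2$encoder_pre[[i]]) / 2)), 1e-6)
      expect_lt(max(abs(p2$decoder[[i]] -
                          (p1$decoder[[i]] + p2$decoder_pre[[i]]) / 2)), 1e-6)
    }
    expect_lt(max(abs(p2$bottleneck -
                        (p1$bottleneck + p2$bottleneck_pre) / 2)), 1e-6)
  }
})

test_that("encoder levels halve the spatial size down to the bottleneck", {
  m <- build_dhunet(dhunet_config(depth = 3, base_filters = 2,
                                  use_batchnorm = FALSE), seed = 2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  out <- dhunet_forward(m, x, capture = TRUE)
  for (i in 1:3) {
    expect_identical(dim(out$pyramids$unet1$encoder[[i]])[1:2],
                     as.integer(c(64 / 2^(i - 1), 64 / 2^(i - 1))))
  }
  expect_identical(dim(out$pyramids$unet1$bottleneck)[1:2], c(8L, 8L))
})

test_that("parameter counts match the closed-form schedule oracle", {
  # a single biased 3x3 convolution mapping 3 -> 1 channels
  expect_equal(3 * 3 * 3 * 1 + 1, 28)
  grid <- expand.grid(depth = 2:3, base = c(4, 8),
                      bn = c(FALSE, TRUE), up = c("interp", "transposed"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- dhunet_config(depth = g$depth, base_filters = g$base,
                         use_batchnorm = g$bn, upsample_mode = g$up)
    m <- build_dhunet(cfg, seed = 1)
    expect_equal(count_parameters(m),
                 oracle_param_count(g$depth, g$base, g$bn, g$up))
  }
  # frozen default schedule
  expect_equal(count_parameters(build_dhunet(dhunet_config(), seed = 1)),
               oracle_param_count(4, 8, TRUE, "interp"))
})

test_that("building and forwarding are deterministic under a fixed seed", {
  m1 <- build_dhunet(toy_cfg(), seed = 9)
  m2 <- build_dhunet(toy_cfg(), seed = 9)
  expect_identical(m1$params, m2$params)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  expect_identical(dhunet_forward(m1, x), dhunet_forward(m2, x))
  m3 <- build_dhunet(toy_cfg(), seed = 10)
  expect_false(identical(m1$params, m3$params))
})

test_that("analytic gradients match finite differences", {
  set.seed(4)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2))
  for (variant in list(list(up = "interp", bn = FALSE, strat = "dice"),
                       list(up = "transposed", bn = TRUE, strat = "bce"))) {
    cfg <- dhunet_config(depth = 2, base_filters = 2,
                         upsample_mode = variant$up,
                         use_batchnorm = variant$bn)
    m <- build_dhunet(cfg, seed = 3)
    tc <- train_config(variant$strat)
    bg <- dhunet:::.batch_grads(m, x, y, tc)
    for (nm in sample(names(m$params), 5)) {
      i <- sample(length(m$params[[nm]]), 1)
      eps <- 1e-5
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (dhunet:::.batch_grads(mp, x, y, tc)$loss -
                dhunet:::.batch_grads(mm, x, y, tc)$loss) / (2 * eps)
      ana <- bg$grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-3 * max(abs(num), abs(ana), 1))
    }
  }
})

test_that("all parameters of both UNets receive gradient (no dead branches)", {
  set.seed(6)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2))
  for (variant in list(c("interp", FALSE), c("transposed", TRUE))) {
    cfg <- dhunet_config(depth = 2, base_filters = 2,
                         upsample_mode = variant[1],
                         use_batchnorm = as.logical(variant[2]))
    m <- build_dhunet(cfg, seed = 3)
    bg <- dhunet:::.batch_grads(m, x, y, train_config("bce"))
    expect_true(all(names(m$params) %in% names(bg$grads)))
    mx <- vapply(bg$grads, function(g) max(abs(g)), numeric(1))
    expect_true(all(mx > 0))
  }
})

test_that("config validation enforces the shared-schedule invariants", {
  expect_error(dhunet_config(depth = 1), "at least 2")
  expect_error(dhunet_config(base_filters = 0), "positive")
  expect_error(dhunet_config(kernel_size = 4), "odd")
})
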