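#' DHuNeT architecture configuration
#'
#' Describes the shared schedule of both stacked UNets. The two UNets must
#' agree level-by-level because hyperactive transfer averages same-shaped
#' feature maps. The default schedule (depth 4, 8 base filters, nearest-
#' neighbour upsampling followed by a 3x3 convolution, batch normalization
#' after every convolution) was frozen by a constraint search over standard
#' dual-UNet schedules targeting the published trainable-parameter budget of
#' 1,081,942; no standard schedule matches exactly, and the closest,
#' adopted here, has 1,082,218 parameters (within 0.03%). See
#' `scripts/search_config.R` in the source repository.
#'
#' @param depth Number of encoder levels (spatial size halves at each).
#' @param base_filters Channel count of the first level; level `i` has
#'   `base_filters * filter_growth^(i-1)` channels and the bottleneck twice
#'   the deepest level's.
#' @param filter_growth Per-level channel multiplier.
#' @param kernel_size Convolution window (odd).
#' @param use_batchnorm Insert batch normalization after every convolution.
#' @param upsample_mode `"interp"` for nearest-neighbour upsampling followed
#'   by a `kernel_size` convolution, or `"transposed"` for a 2x2 stride-2
#'   transposed convolution.
#' @return An object of class `dhunet_config`.
#' @export
dhunet_config <- function(depth = 4L, base_filters = 8L, filter_growth = 2L,
                          kernel_size = 3L, use_batchnorm = TRUE,
                          upsample_mode = c("interp", "transposed")) {
  upsample_mode <- match.arg(upsample_mode)
  depth <- as.integer(depth)
  base_filters <- as.integer(base_filters)
  if (depth < 2L) stop("`depth` must be at least 2", call. = FALSE)
  if (base_filters < 1L) stop("`base_filters` must be positive", call. = FALSE)
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd", call. = FALSE)
  structure(list(
    depth = depth, base_filters = base_filters,
    filter_growth = as.integer(filter_growth),
    kernel_size = as.integer(kernel_size), convs_per_block = 2L,
    use_batchnorm = isTRUE(use_batchnorm), upsample_mode = upsample_mode,
    in_channels_unet1 = 3L, in_channels_unet2 = 4L, out_channels = 1L,
    head_activation = "sigmoid"
  ), class = "dhunet_config")
}

#' @export
print.dhunet_config <- function(x, ...) {
  cat("DHuNeT configuration\n")
  cat(sprintf("  depth %d, base filters %d (growth %d), kernel %dx%d\n",
              x$depth, x$base_filters, x$filter_growth, x$kernel_size,
              x$kernel_size))
  cat(sprintf("  upsampling: %s; batchnorm: %s\n", x$upsample_mode,
              x$use_batchnorm))
  invisible(x)
}

# Per-level channel schedule; index depth+1 is the bottleneck.
.filters <- function(config) {
  config$base_filters * config$filter_growth^(0:config$depth)
}

.he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Declare one convolution's weight/bias (+ optional batchnorm pair) under
# `name` into the param list being built. A convolution followed by
# batchnorm carries no bias: the normalization's mean subtraction would
# cancel it, leaving a dead parameter.
.add_conv <- function(acc, name, k, cin, cout, bn) {
  acc$params[[paste0(name, ".w")]] <- .he_uniform(c(k, k, cin, cout), k * k * cin)
  if (!bn) acc$params[[paste0(name, ".b")]] <- numeric(cout)
  if (bn) {
    acc$params[[paste0(name, ".g")]] <- rep(1, cout)
    acc$params[[paste0(name, ".be")]] <- numeric(cout)
    st <- new.env(parent = emptyenv())
    st$running_mean <- numeric(cout)
    st$running_var <- rep(1, cout)
    acc$bn_state[[name]] <- st
  }
  acc
}

# Parameter layout of one UNet; shared by both (they differ only in the
# input channel count).
.unet_param_plan <- function(config, cin) {
  f <- .filters(config)
  d <- config$depth
  plan <- list()
  cprev <- cin
  for (i in seq_len(d)) {
    plan[[length(plan) + 1L]] <- list(name = sprintf("enc%d.c1", i),
                                      k = config$kernel_size, cin = cprev, cout = f[i])
    plan[[length(plan) + 1L]] <- list(name = sprintf("enc%d.c2", i),
                                      k = config$kernel_size, cin = f[i], cout = f[i])
    cprev <- f[i]
  }
  fb <- f[d + 1L]
  plan[[length(plan) + 1L]] <- list(name = "bott.c1", k = config$kernel_size,
                                    cin = cprev, cout = fb)
  plan[[length(plan) + 1L]] <- list(name = "bott.c2", k = config$kernel_size,
                                    cin = fb, cout = fb)
  cup <- fb
  for (i in rev(seq_len(d))) {
    upk <- if (config$upsample_mode == "transposed") 2L else config$kernel_size
    plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d.up", i), k = upk,
                                      cin = cup, cout = f[i])
    plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d.c1", i),
                                      k = config$kernel_size, cin = 2L * f[i], cout = f[i])
    plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d.c2", i),
                                      k = config$kernel_size, cin = f[i], cout = f[i])
    cup <- f[i]
  }
  plan[[length(plan) + 1L]] <- list(name = "head", k = 1L, cin = f[1],
                                    cout = config$out_channels, head = TRUE)
  plan
}

#' Build a DHuNeT model
#'
#' Instantiates both UNets with seeded He-uniform initial weights. UNet-1
#' consumes the 3-channel standardized image; UNet-2 consumes the image
#' concatenated with UNet-1's soft mask (4 channels) and fuses UNet-1's
#' per-level encoder, bottleneck, and decoder features into its own by
#' elementwise averaging.
#'
#' @param config A [dhunet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `dhunet_model`.
#' @export
build_dhunet <- function(config = dhunet_config(), seed = 42L) {
  stopifnot(inherits(config, "dhunet_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  acc <- list(params = list(), bn_state = list())
  for (u in 1:2) {
    cin <- if (u == 1L) config$in_channels_unet1 else config$in_channels_unet2
    for (p in .unet_param_plan(config, cin)) {
      bn <- config$use_batchnorm && is.null(p$head)
      acc <- .add_conv(acc, sprintf("u%d.%s", u, p$name), p$k, p$cin, p$cout, bn)
    }
  }
  structure(list(config = config, params = acc$params, bn_state = acc$bn_state,
                 seed = as.integer(seed)),
            class = "dhunet_model")
}

#' Count trainable parameters
#'
#' Sum of all trainable scalars (convolution weights and biases, plus batch
#' normalization scale/shift when enabled) across both UNets.
#'
#' @param model A `dhunet_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "dhunet_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.dhunet_model <- function(x, ...) {
  cat(sprintf("DHuNeT model: depth %d, base %d, %s upsampling, %s parameters\n",
              x$config$depth, x$config$base_filters, x$config$upsample_mode,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Elementwise feature fusion
#'
#' The hyperactive transfer primitive: the arithmetic mean of two
#' same-shaped feature maps, `(a + b) / 2`.
#'
#' @param a,b Numeric arrays of identical shape.
#' @return Array of the same shape.
#' @export
fuse <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop("`a` and `b` must have identical shapes", call. = FALSE)
  }
  (a + b) / 2
}

# One conv (+bn) + ReLU step on the tape.
.conv_act <- function(tape, x, pn, name, model, training, relu = TRUE) {
  y <- op_conv(tape, x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]])
  if (!is.null(pn[[paste0(name, ".g")]])) {
    y <- op_batchnorm(tape, y, pn[[paste0(name, ".g")]], pn[[paste0(name, ".be")]],
                      model$bn_state[[name]], training)
  }
  if (relu) op_relu(tape, y) else y
}

.block <- function(tape, x, prefix, pn, model, training) {
  x <- .conv_act(tape, x, pn, paste0(prefix, ".c1"), model, training)
  .conv_act(tape, x, pn, paste0(prefix, ".c2"), model, training)
}

.upsample <- function(tape, x, prefix, pn, model, training) {
  if (model$config$upsample_mode == "transposed") {
    y <- op_conv_transpose2(tape, x, pn[[paste0(prefix, ".up.w")]],
                            pn[[paste0(prefix, ".up.b")]])
    if (!is.null(pn[[paste0(prefix, ".up.g")]])) {
      y <- op_batchnorm(tape, y, pn[[paste0(prefix, ".up.g")]],
                        pn[[paste0(prefix, ".up.be")]],
                        model$bn_state[[paste0(prefix, ".up")]], training)
    }
    op_relu(tape, y)
  } else {
    y <- op_upsample_nearest(tape, x)
    .conv_act(tape, y, pn, paste0(prefix, ".up"), model, training)
  }
}

# Build the full two-UNet graph on a tape. Returns head nodes, parameter
# nodes (for gradient collection), and per-level feature nodes.
.dhunet_graph <- function(tape, model, x_node, training = FALSE) {
  cfg <- model$config
  d <- cfg$depth
  pn <- lapply(model$params, function(p) nd_leaf(tape, p))

  run_unet <- function(u, input, donor = NULL) {
    pre <- sprintf("u%d.", u)
    enc <- vector("list", d)
    enc_pre <- vector("list", d)
    dec <- vector("list", d)
    dec_pre <- vector("list", d)
    x <- input
    for (i in seq_len(d)) {
      c1 <- .block(tape, x, sprintf("%senc%d", pre, i), pn, model, training)
      enc_pre[[i]] <- c1
      enc[[i]] <- if (is.null(donor)) c1 else op_fuse(tape, donor$enc[[i]], c1)
      x <- op_maxpool(tape, enc[[i]])
    }
    bott_pre <- .block(tape, x, paste0(pre, "bott"), pn, model, training)
    bott <- if (is.null(donor)) bott_pre else op_fuse(tape, donor$bottleneck, bott_pre)
    x <- bott
    for (i in rev(seq_len(d))) {
      up <- .upsample(tape, x, sprintf("%sdec%d", pre, i), pn, model, training)
      z <- op_concat_ch(tape, up, enc[[i]])
      c2 <- .block(tape, z, sprintf("%sdec%d", pre, i), pn, model, training)
      dec_pre[[i]] <- c2
      dec[[i]] <- if (is.null(donor)) c2 else op_fuse(tape, donor$dec[[i]], c2)
      x <- dec[[i]]
    }
    logits <- .conv_act(tape, x, pn, paste0(pre, "head"), model, training, relu = FALSE)
    mask <- op_sigmoid(tape, logits)
    list(mask = mask, enc = enc, enc_pre = enc_pre, bottleneck = bott,
         bottleneck_pre = bott_pre, dec = dec, dec_pre = dec_pre)
  }

  u1 <- run_unet(1L, x_node)
  x2 <- op_concat_ch(tape, x_node, u1$mask)
  u2 <- run_unet(2L, x2, donor = u1)
  list(mask1 = u1$mask, mask2 = u2$mask, pn = pn, unet1 = u1, unet2 = u2)
}

.check_batch <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 4L || d[3] != model$config$in_channels_unet1) {
    stop("batch must be H x W x 3 x N", call. = FALSE)
  }
  div <- 2L^model$config$depth
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    stop(sprintf("spatial size must be divisible by 2^depth = %d", div),
         call. = FALSE)
  }
  x
}

#' Forward pass through both UNets
#'
#' @param model A `dhunet_model`.
#' @param batch Standardized images in `[0,1]`, array `H x W x 3 x N` (or a
#'   single `H x W x 3` image).
#' @param capture If `TRUE`, also return both feature pyramids (per-level
#'   encoder/decoder maps and bottlenecks, for UNet-2 both before and after
#'   fusion) for inspection.
#' @return List with `mask1` and `mask2` (soft masks, `H x W x N`) and, when
#'   requested, `pyramids`.
#' @export
dhunet_forward <- function(model, batch, capture = FALSE) {
  stopifnot(inherits(model, "dhunet_model"))
  x <- .check_batch(model, batch)
  tape <- tape_new()
  g <- .dhunet_graph(tape, model, nd_leaf(tape, x), training = FALSE)
  squeeze <- function(m) array(m, dim(m)[c(1L, 2L, 4L)])
  out <- list(mask1 = squeeze(g$mask1$value), mask2 = squeeze(g$mask2$value))
  if (capture) {
    vals <- function(l) lapply(l, function(nd) nd$value)
    out$pyramids <- list(
      unet1 = list(encoder = vals(g$unet1$enc), bottleneck = g$unet1$bottleneck$value,
                   decoder = vals(g$unet1$dec)),
      unet2 = list(encoder = vals(g$unet2$enc), encoder_pre = vals(g$unet2$enc_pre),
                   bottleneck = g$unet2$bottleneck$value,
                   bottleneck_pre = g$unet2$bottleneck_pre$value,
                   decoder = vals(g$unet2$dec), decoder_pre = vals(g$unet2$dec_pre))
    )
  }
  out
}
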