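#' Specification for one synthetic wound image
#'
#' Describes a reproducible wound-like image/mask pair: a skin-toned noisy
#' background carrying 1-3 irregular reddish lesions whose exact supports
#' form the binary mask, optionally framed by all-black border bands (the
#' acquisition artifact the preprocessing crop removes). The same spec
#' always renders the same bytes.
#'
#' Lesion outlines are ellipses whose radius is modulated by a low-order
#' periodic perturbation (a sum of four sinusoids with random phases), so
#' lesions are irregular but simply connected and the mask is exact by
#' construction.
#'
#' @param seed Integer RNG seed.
#' @param size Pixels per side of the (pre-border) image; at least 32.
#' @param n_lesions Number of lesions, 0-3 (0 is the degenerate empty case).
#' @param lesion_radius_frac Length-2 range of the base lesion radius as a
#'   fraction of `size`.
#' @param boundary_jitter Relative amplitude of the radial outline
#'   perturbation; `0` gives smooth ellipses, must stay below 0.9 so the
#'   outline cannot self-intersect.
#' @param skin_tone Background RGB triple in `[0,255]`.
#' @param noise_sd Gaussian texture noise standard deviation (8-bit units).
#' @param border_widths Four non-negative integers (left, right, top,
#'   bottom) of all-black bands appended around the image.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, size = 128L, n_lesions = 2L,
                           lesion_radius_frac = c(0.08, 0.25),
                           boundary_jitter = 0.3,
                           skin_tone = c(224, 172, 138), noise_sd = 6,
                           border_widths = c(0L, 0L, 0L, 0L)) {
  size <- as.integer(size)
  if (is.na(size) || size < 32L) stop("`size` must be at least 32", call. = FALSE)
  if (n_lesions < 0L || n_lesions > 3L) {
    stop("`n_lesions` must be between 0 and 3", call. = FALSE)
  }
  if (length(lesion_radius_frac) != 2L || any(lesion_radius_frac <= 0) ||
      diff(lesion_radius_frac) < 0) {
    stop("`lesion_radius_frac` must be an increasing positive range", call. = FALSE)
  }
  if (boundary_jitter < 0 || boundary_jitter >= 0.9) {
    stop("`boundary_jitter` must lie in [0, 0.9)", call. = FALSE)
  }
  if (length(skin_tone) != 3L || any(skin_tone < 0 | skin_tone > 255)) {
    stop("`skin_tone` must be an RGB triple in [0,255]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  border_widths <- as.integer(border_widths)
  if (length(border_widths) != 4L || anyNA(border_widths) || any(border_widths < 0L)) {
    stop("`border_widths` must be four non-negative integers", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), size = size,
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_frac = as.numeric(lesion_radius_frac),
                 boundary_jitter = as.numeric(boundary_jitter),
                 skin_tone = as.numeric(skin_tone),
                 noise_sd = as.numeric(noise_sd),
                 border_widths = border_widths),
            class = "synthetic_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Lesion parameters in fractional (size-free) units: ellipse centre, axes,
# orientation, the low-order radial perturbation, and a reddish base colour.
# Drawn before any size-dependent randomness so that a given seed renders
# the same fractional geometry at every raster scale.
.lesion_params <- function(radius_range, jitter) {
  cx <- stats::runif(1, 0.25, 0.75)
  cy <- stats::runif(1, 0.25, 0.75)
  r0 <- stats::runif(1, radius_range[1], radius_range[2])
  amp <- stats::runif(4)
  list(cx = cx, cy = cy,
       a = r0 * stats::runif(1, 0.75, 1.25),
       b = r0 * stats::runif(1, 0.75, 1.25),
       theta = stats::runif(1, 0, pi),
       amp = amp / sum(amp), jitter = jitter,
       phase = stats::runif(4, 0, 2 * pi),
       color = c(stats::runif(1, 150, 200), stats::runif(1, 30, 80),
                 stats::runif(1, 35, 90)))
}

# Rasterize one lesion support: inside the ellipse whose radius at polar
# angle phi is scaled by 1 + jitter * sum_k a_k sin(k phi + phase_k).
.lesion_support <- function(size, par) {
  xs <- matrix(rep(seq_len(size) - 0.5, each = size), size) - par$cx * size
  ys <- matrix(rep(seq_len(size) - 0.5, times = size), size) - par$cy * size
  dist <- sqrt(xs^2 + ys^2)
  phi <- atan2(ys, xs)
  u <- cos(phi - par$theta)
  v <- sin(phi - par$theta)
  a <- par$a * size
  b <- par$b * size
  re <- a * b / sqrt((b * u)^2 + (a * v)^2)
  rho <- 1 + par$jitter * Reduce(`+`, lapply(1:4, function(k) {
    par$amp[k] * sin(k * phi + par$phase[k])
  }))
  dist <= re * rho
}

#' Generate one synthetic wound image/mask pair
#'
#' Deterministic rendering of the pair described by a [synthetic_spec()].
#' Lesion pixels are drawn from a reddish hue distribution clearly separated
#' from the skin tone; the mask is exactly the union of the rendered lesion
#' supports. Border bands, when requested, are appended around the image
#' (dimensions grow) and are zero in both image and mask.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `image` (H x W x 3 numeric array of 8-bit values),
#'   `mask` (H x W binary matrix), and `interior` (the [crop_box()] of the
#'   pre-border content, for round-trip checks).
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    s <- spec$size
    lesions <- lapply(seq_len(spec$n_lesions), function(l) {
      .lesion_params(spec$lesion_radius_frac, spec$boundary_jitter)
    })
    image <- array(0, c(s, s, 3))
    for (ch in 1:3) {
      image[, , ch] <- spec$skin_tone[ch] + stats::rnorm(s * s, 0, spec$noise_sd)
    }
    mask <- matrix(0L, s, s)
    for (par in lesions) {
      inside <- .lesion_support(s, par)
      for (ch in 1:3) {
        plane <- image[, , ch]
        plane[inside] <- par$color[ch] + stats::rnorm(sum(inside), 0, spec$noise_sd)
        image[, , ch] <- plane
      }
      mask[inside] <- 1L
    }
    image <- round(pmin(pmax(image, 0), 255))
    out <- add_black_border(image, mask, spec$border_widths)
    out
  })
}

#' Append all-black border bands around an image/mask pair
#'
#' Emulates the photographic black framing bands that the preprocessing
#' pipeline is designed to remove. Output dimensions grow by the band
#' widths; the bands are zero in every channel and in the mask; the
#' interior is the unmodified input.
#'
#' @param image H x W x 3 numeric array of 8-bit values.
#' @param mask H x W binary matrix.
#' @param widths Four non-negative integers: left, right, top, bottom.
#' @return List with `image`, `mask`, and `interior` (a [crop_box()]
#'   locating the original content inside the padded frame).
#' @export
add_black_border <- function(image, mask, widths = c(0L, 0L, 0L, 0L)) {
  widths <- as.integer(widths)
  if (length(widths) != 4L || anyNA(widths) || any(widths < 0L)) {
    stop("`widths` must be four non-negative integers", call. = FALSE)
  }
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("`image` must be H x W x 3", call. = FALSE)
  if (!identical(dim(mask), d[1:2])) {
    stop("`mask` dimensions must match `image`", call. = FALSE)
  }
  if (d[1] == 0L || d[2] == 0L) stop("interior must be non-empty", call. = FALSE)
  l <- widths[1]; r <- widths[2]; t <- widths[3]; b <- widths[4]
  H <- d[1] + t + b
  W <- d[2] + l + r
  img <- array(0, c(H, W, 3L))
  msk <- matrix(0L, H, W)
  img[t + seq_len(d[1]), l + seq_len(d[2]), ] <- image
  msk[t + seq_len(d[1]), l + seq_len(d[2])] <- mask
  list(image = img, mask = msk,
       interior = crop_box(l, t, l + d[2], t + d[1]))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` image/mask PNG pairs plus a TSV manifest
#' (`image<TAB>mask<TAB>split`). Per-sample seeds are derived from the
#' template seed and the sample index (counter-based), so regeneration is
#' byte-identical and order-independent.
#'
#' @param spec_template A [synthetic_spec()]; everything except the seed is
#'   shared by all samples.
#' @param n Number of samples (>= 1).
#' @param out_dir Output directory (created if missing).
#' @param test_frac Fraction of samples tagged `test` (the trailing ones);
#'   the rest are tagged `train`.
#' @return Path of the written manifest, invisibly.
#' @export
generate_dataset <- function(spec_template, n, out_dir, test_frac = 0.2) {
  stopifnot(inherits(spec_template, "synthetic_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (test_frac < 0 || test_frac >= 1) stop("`test_frac` must be in [0,1)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create `out_dir`", call. = FALSE)
  n_train <- n - floor(n * test_frac)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec_template
    sp$seed <- as.integer((spec_template$seed + i * 1000003) %% 2147483647)
    smp <- generate_sample(sp)
    ipath <- file.path(out_dir, sprintf("image_%04d.png", i))
    mpath <- file.path(out_dir, sprintf("mask_%04d.png", i))
    png::writePNG(smp$image / 255, ipath)
    png::writePNG(smp$mask + 0, mpath)
    rows[[i]] <- data.frame(image = ipath, mask = mpath,
                            split = if (i <= n_train) "train" else "test",
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.tsv")
  write_manifest(manifest, mpath)
  invisible(mpath)
}
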