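#' Blur configuration for the grayscale step
#'
#' The region-of-interest extractor first converts the photograph to
#' grayscale and blurs it. The default is a median filter (robust to
#' speckle); a Gaussian mode is available, whose kernel is the normalized
#' discretization of the 2-D Gaussian `A * exp(-(x-mu_x)^2 / (2 sigma_x^2)
#' - (y-mu_y)^2 / (2 sigma_y^2))` on the kernel support (amplitude and
#' centre fixed by the normalized-kernel convention).
#'
#' @param mode `"median"` or `"gaussian"`.
#' @param kernel Odd window side length.
#' @param sigma_x,sigma_y Gaussian standard deviations (gaussian mode only).
#' @return Object of class `blur_config`.
#' @export
blur_config <- function(mode = c("median", "gaussian"), kernel = 5L,
                        sigma_x = 1, sigma_y = 1) {
  mode <- match.arg(mode)
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 1L || kernel %% 2L == 0L) {
    stop("`kernel` must be an odd positive integer", call. = FALSE)
  }
  if (mode == "gaussian" && (sigma_x <= 0 || sigma_y <= 0)) {
    stop("Gaussian sigmas must be positive", call. = FALSE)
  }
  structure(list(mode = mode, kernel = kernel,
                 sigma_x = as.numeric(sigma_x), sigma_y = as.numeric(sigma_y)),
            class = "blur_config")
}

#' Normalized discrete Gaussian kernel
#'
#' Discretizes the 2-D Gaussian on a `kernel x kernel` support centred at
#' the window middle and normalizes it to unit sum.
#'
#' @inheritParams blur_config
#' @return `kernel x kernel` matrix summing to 1.
#' @export
gaussian_kernel <- function(kernel, sigma_x = 1, sigma_y = sigma_x) {
  r <- (kernel - 1) / 2
  x <- matrix(rep(-r:r, each = kernel), kernel)
  y <- matrix(rep(-r:r, times = kernel), kernel)
  k <- exp(-x^2 / (2 * sigma_x^2) - y^2 / (2 * sigma_y^2))
  k / sum(k)
}

# 2-D correlation with replicate (clamp-to-edge) padding.
.filter2_replicate <- function(mat, kern) {
  k <- nrow(kern)
  r <- (k - 1) / 2
  H <- nrow(mat)
  W <- ncol(mat)
  ridx <- pmin(pmax(seq_len(H + 2 * r) - r, 1L), H)
  cidx <- pmin(pmax(seq_len(W + 2 * r) - r, 1L), W)
  pad <- mat[ridx, cidx, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out <- out + kern[i, j] * pad[(i - 1) + seq_len(H), (j - 1) + seq_len(W)]
    }
  }
  out
}

.check_image8 <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("`image` must be H x W x 3", call. = FALSE)
  if (min(image) < 0 || max(image) > 255) {
    stop("`image` must hold 8-bit values in [0,255]", call. = FALSE)
  }
}

#' Grayscale conversion with blur
#'
#' ITU-R 601 luminance (`0.299 R + 0.587 G + 0.114 B`) followed by the
#' configured blur filter.
#'
#' @param image H x W x 3 numeric array of 8-bit values.
#' @param cfg A [blur_config()].
#' @return H x W matrix of 8-bit grayscale values.
#' @export
blur_gray <- function(image, cfg = blur_config()) {
  stopifnot(inherits(cfg, "blur_config"))
  .check_image8(image)
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  out <- if (cfg$mode == "median") {
    cpp_median_blur(gray, cfg$kernel)
  } else {
    .filter2_replicate(gray, gaussian_kernel(cfg$kernel, cfg$sigma_x, cfg$sigma_y))
  }
  round(pmin(pmax(out, 0), 255))
}

#' Threshold a grayscale raster to a binary image
#'
#' Pixels strictly greater than `threshold` map to 255, others to 0.
#'
#' @param gray H x W matrix of 8-bit values.
#' @param threshold Integer in `[0, 255]`.
#' @return H x W matrix with values in `{0, 255}`.
#' @export
binarize <- function(gray, threshold = 10L) {
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must lie in [0,255]", call. = FALSE)
  }
  (gray > threshold) * 255L
}

# Moore-neighbour boundary tracing of one labelled component. Returns an
# n x 2 matrix of 0-based (x, y) pixel-centre coordinates in image
# coordinates (y down). The walk starts at the first foreground pixel in
# raster order with a west backtrack and stops when a (pixel, backtrack)
# state repeats, which closes the outer boundary cycle.
.trace_boundary <- function(lab, id) {
  fg <- lab == id
  H <- nrow(fg)
  W <- ncol(fg)
  hits <- which(t(fg))          # t() => raster order: row by row
  p0 <- hits[1] - 1L
  sy <- p0 %/% W
  sx <- p0 %% W
  # clockwise neighbourhood starting west (dx, dy), y pointing down
  dx <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  inside <- function(x, y) x >= 0L && x < W && y >= 0L && y < H && fg[y + 1L, x + 1L]
  px <- sx; py <- sy
  bdir <- 1L  # direction index pointing at the backtrack neighbour
  pts_x <- integer(0)
  pts_y <- integer(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  repeat {
    key <- paste(px, py, bdir)
    if (!is.null(seen[[key]])) break
    seen[[key]] <- TRUE
    pts_x <- c(pts_x, px)
    pts_y <- c(pts_y, py)
    found <- FALSE
    for (s in 0:7) {
      d <- ((bdir - 1L + s) %% 8L) + 1L
      qx <- px + dx[d]; qy <- py + dy[d]
      if (inside(qx, qy)) {
        prev <- ((d - 2L) %% 8L) + 1L  # free neighbour checked just before q
        bx <- px + dx[prev]; by <- py + dy[prev]
        bdir <- which(dx == (bx - qx) & dy == (by - qy))[1]
        px <- qx; py <- qy
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
  }
  cbind(pts_x, pts_y)
}

.shoelace <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Ramer-Douglas-Peucker simplification of an open chain.
.rdp <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len == 0) {
    sqrt(rowSums(sweep(pts, 2, a)^2))
  } else {
    abs((pts[, 1] - a[1]) * ab[2] - (pts[, 2] - a[2]) * ab[1]) / len
  }
  i <- which.max(d)
  if (d[i] <= eps) {
    rbind(a, b)
  } else {
    left <- .rdp(pts[1:i, , drop = FALSE], eps)
    right <- .rdp(pts[i:n, , drop = FALSE], eps)
    rbind(left[-nrow(left), , drop = FALSE], right)
  }
}

.simplify_closed <- function(pts, eps) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  # split at the vertex farthest from the first point
  d <- rowSums(sweep(pts, 2, pts[1, ])^2)
  k <- which.max(d)
  c1 <- .rdp(pts[1:k, , drop = FALSE], eps)
  c2 <- .rdp(rbind(pts[k:n, , drop = FALSE], pts[1, , drop = FALSE]), eps)
  out <- rbind(c1[-nrow(c1), , drop = FALSE], c2[-nrow(c2), , drop = FALSE])
  unname(out)
}

#' Extract the largest contour of a binary raster
#'
#' Labels 8-connected foreground regions, traces each region's outer
#' boundary, and returns the contour enclosing the largest area (shoelace
#' formula on the boundary polygon). The contour is simplified with
#' Ramer-Douglas-Peucker (tolerance 1% of the perimeter) and annotated with
#' the vertex farthest from the contour centroid (the "far" point) and the
#' maximal x and y vertex coordinates.
#'
#' @param binary H x W matrix with values in `{0, 255}`.
#' @return `NULL` when no foreground exists; otherwise an object of class
#'   `wound_contour` with fields `points` (n x 2, 0-based x = column,
#'   y = row), `area`, `approx`, `centroid`, `far_point`, `max_x`, `max_y`.
#' @export
extract_largest_contour <- function(binary) {
  if (!all(binary %in% c(0, 255))) {
    stop("`binary` must contain only 0 and 255", call. = FALSE)
  }
  bin <- matrix(as.integer(binary), nrow(binary))
  lab <- cpp_label_components(bin)
  nlab <- max(lab)
  if (nlab == 0L) return(NULL)
  best <- NULL
  best_area <- -1
  for (id in seq_len(nlab)) {
    pts <- .trace_boundary(lab, id)
    area <- .shoelace(pts)
    # tie-break (and the degenerate thin-region case) by pixel count
    if (area > best_area ||
        (area == best_area && sum(lab == id) > attr(best, "npix"))) {
      best <- pts
      best_area <- area
      attr(best, "npix") <- sum(lab == id)
    }
  }
  pts <- best
  per <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2)))
  approx <- .simplify_closed(pts, eps = 0.01 * per)
  centroid <- unname(colMeans(pts))
  dfar <- rowSums(sweep(approx, 2, centroid)^2)
  structure(list(points = unname(pts), area = best_area, approx = approx,
                 centroid = centroid,
                 far_point = approx[which.max(dfar), ],
                 max_x = max(pts[, 1]), max_y = max(pts[, 2])),
            class = "wound_contour")
}

#' Axis-aligned crop window
#'
#' Half-open pixel interval `[x0, x1) x [y0, y1)` in 0-based coordinates
#' (x = column, y = row).
#'
#' @param x0,y0,x1,y1 Box corners; `x1 > x0`, `y1 > y0`.
#' @return Object of class `crop_box`.
#' @export
crop_box <- function(x0, y0, x1, y1) {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  if (x1 <= x0 || y1 <= y0) stop("degenerate crop box", call. = FALSE)
  if (x0 < 0L || y0 < 0L) stop("crop box out of bounds", call. = FALSE)
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "crop_box")
}

#' Bounding crop box of a contour
#'
#' The axis-aligned bounding box of the contour vertices, clamped to the
#' raster bounds.
#'
#' @param contour A `wound_contour`.
#' @param height,width Raster dimensions.
#' @return A [crop_box()].
#' @export
compute_crop_box <- function(contour, height, width) {
  stopifnot(inherits(contour, "wound_contour"))
  p <- contour$points
  crop_box(max(min(p[, 1]), 0), max(min(p[, 2]), 0),
           min(max(p[, 1]) + 1L, width), min(max(p[, 2]) + 1L, height))
}

#' Crop an image/mask pair with the same window
#'
#' @param image H x W x 3 array.
#' @param mask H x W matrix.
#' @param box A [crop_box()].
#' @return List with cropped `image` and `mask`, bit-identical to the
#'   source window.
#' @export
apply_crop <- function(image, mask, box) {
  stopifnot(inherits(box, "crop_box"))
  d <- dim(image)
  if (!identical(dim(mask), d[1:2])) {
    stop(sprintf("image (%dx%d) and mask (%dx%d) sizes differ",
                 d[1], d[2], dim(mask)[1], dim(mask)[2]), call. = FALSE)
  }
  if (box$x1 > d[2] || box$y1 > d[1]) stop("crop box out of bounds", call. = FALSE)
  rows <- (box$y0 + 1L):box$y1
  cols <- (box$x0 + 1L):box$x1
  list(image = image[rows, cols, , drop = FALSE],
       mask = mask[rows, cols, drop = FALSE])
}

# Bilinear (images) / nearest-neighbour (masks) resize of a matrix.
.resize_mat <- function(mat, th, tw, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(mat); W <- ncol(mat)
  cy <- (seq_len(th) - 0.5) * H / th - 0.5
  cx <- (seq_len(tw) - 0.5) * W / tw - 0.5
  if (method == "nearest") {
    r <- pmin(pmax(round(cy), 0), H - 1) + 1L
    c <- pmin(pmax(round(cx), 0), W - 1) + 1L
    return(mat[r, c, drop = FALSE])
  }
  y0 <- pmin(pmax(floor(cy), 0), H - 1)
  x0 <- pmin(pmax(floor(cx), 0), W - 1)
  y1 <- pmin(y0 + 1, H - 1)
  x1 <- pmin(x0 + 1, W - 1)
  fy <- pmin(pmax(cy - y0, 0), 1)
  fx <- pmin(pmax(cx - x0, 0), 1)
  m00 <- mat[y0 + 1L, x0 + 1L, drop = FALSE]
  m01 <- mat[y0 + 1L, x1 + 1L, drop = FALSE]
  m10 <- mat[y1 + 1L, x0 + 1L, drop = FALSE]
  m11 <- mat[y1 + 1L, x1 + 1L, drop = FALSE]
  wy <- matrix(fy, th, tw)
  wx <- matrix(fx, th, tw, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx +
    m10 * wy * (1 - wx) + m11 * wy * wx
}

#' Resize and normalize a cropped pair to the network input size
#'
#' The image is resized with bilinear interpolation and scaled to `[0,1]`;
#' the mask is resized with nearest-neighbour interpolation and
#' re-binarized at 0.5.
#'
#' @param image H x W x 3 array of 8-bit values.
#' @param mask H x W binary matrix.
#' @param target_size Output side length (default 128).
#' @param provenance Optional list recorded in the result (source paths,
#'   crop box).
#' @return Object of class `preprocessed_sample` with `image`
#'   (`target_size^2 x 3` values in `[0,1]`), `mask` (binary), and
#'   `provenance`.
#' @export
standardize <- function(image, mask, target_size = 128L, provenance = list()) {
  target_size <- as.integer(target_size)
  if (is.na(target_size) || target_size < 8L) {
    stop("`target_size` must be at least 8", call. = FALSE)
  }
  d <- dim(image)
  if (d[1] == 0L || d[2] == 0L) stop("empty input", call. = FALSE)
  out <- array(0, c(target_size, target_size, 3L))
  for (ch in 1:3) {
    out[, , ch] <- .resize_mat(image[, , ch], target_size, target_size,
                               "bilinear") / 255
  }
  m <- .resize_mat(mask, target_size, target_size, "nearest")
  m <- (m >= 0.5) * 1L
  structure(list(image = out, mask = m, provenance = provenance),
            class = "preprocessed_sample")
}

#' Region-of-interest preprocessing configuration
#'
#' @param blur A [blur_config()].
#' @param threshold Binarization threshold in `[0,255]`; the default 10
#'   separates content from near-black framing bands.
#' @param target_size Network input side length.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(blur = blur_config(), threshold = 10L,
                              target_size = 128L) {
  stopifnot(inherits(blur, "blur_config"))
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must lie in [0,255]", call. = FALSE)
  }
  structure(list(blur = blur, threshold = as.integer(threshold),
                 target_size = as.integer(target_size)),
            class = "preprocess_config")
}

#' Full region-of-interest preprocessing of one sample
#'
#' The composition blur+gray -> threshold -> largest contour -> bounding
#' crop -> identical crop of image and mask -> resize/normalize. When no
#' contour is found (e.g. an all-black frame), the identity crop is used so
#' no sample is silently discarded.
#'
#' @param image H x W x 3 array of 8-bit values.
#' @param mask H x W binary matrix.
#' @param cfg A [preprocess_config()].
#' @param provenance Optional list (e.g. source paths) carried through.
#' @return A `preprocessed_sample`; its `provenance$crop_box` records the
#'   window used.
#' @export
preprocess_sample <- function(image, mask, cfg = preprocess_config(),
                              provenance = list()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  d <- dim(image)
  gray <- blur_gray(image, cfg$blur)
  bin <- binarize(gray, cfg$threshold)
  contour <- extract_largest_contour(bin)
  box <- if (is.null(contour)) {
    crop_box(0L, 0L, d[2], d[1])
  } else {
    compute_crop_box(contour, d[1], d[2])
  }
  cropped <- apply_crop(image, mask, box)
  provenance$crop_box <- box
  standardize(cropped$image, cropped$mask, cfg$target_size, provenance)
}
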