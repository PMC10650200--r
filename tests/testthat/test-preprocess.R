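const_image <- function(v, h = 16, w = 16) array(v, c(h, w, 3))

test_that("blurring a constant image leaves it unchanged in both modes", {
  img <- const_image(128)
  expect_true(all(blur_gray(img, blur_config("median", 5)) == 128))
  expect_true(all(blur_gray(img, blur_config("gaussian", 5, 1, 1)) == 128))
})

test_that("median blur rejects an isolated impulse", {
  img <- const_image(0, 5, 5)
  img[3, 3, ] <- 255
  out <- blur_gray(img, blur_config("median", 3))
  expect_true(all(out == 0))
})

test_that("gaussian kernel matches direct discretization of the density", {
  k <- 5L; s <- 1
  # independent direct summation over the 5x5 support
  raw <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    x <- j - 3; y <- i - 3
    raw[i, j] <- exp(-x^2 / (2 * s^2) - y^2 / (2 * s^2))
  }
  raw <- raw / sum(raw)
  got <- gaussian_kernel(k, s, s)
  expect_equal(got[3, 3], raw[3, 3], tolerance = 1e-12)
  expect_equal(got, raw, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(got), 1, tolerance = 1e-12)
})

test_that("binarize follows the strict-inequality convention", {
  expect_equal(binarize(matrix(c(200, 127, 128, 0), 2), 127),
               matrix(c(255, 0, 255, 0), 2))
  pos <- matrix(1:9, 3)
  expect_true(all(binarize(pos, 0) == 255))
  expect_error(binarize(pos, 300), "\\[0,255\\]")
})

test_that("largest contour of rectangles has the expected geometry", {
  bin <- matrix(0, 100, 100)
  bin[6:15, 6:25] <- 255  # 10 rows x 20 cols at (x,y) = (5,5)
  ct <- extract_largest_contour(bin)
  expect_s3_class(ct, "wound_contour")
  expect_equal(ct$max_x, 24)
  expect_equal(ct$max_y, 14)
  # shoelace over pixel centres of a w x h rectangle is (w-1)(h-1)
  expect_equal(ct$area, 19 * 9)
  box <- compute_crop_box(ct, 100, 100)
  expect_identical(unclass(box)[c("x0", "y0", "x1", "y1")],
                   list(x0 = 5L, y0 = 5L, x1 = 25L, y1 = 15L))

  # larger of two squares wins
  two <- matrix(0, 60, 60)
  two[5:8, 5:8] <- 255     # 4x4
  two[20:27, 30:37] <- 255 # 8x8
  ct2 <- extract_largest_contour(two)
  expect_equal(ct2$max_x, 36)
  expect_equal(ct2$max_y, 26)

  expect_null(extract_largest_contour(matrix(0, 10, 10)))
})

test_that("contour annotations are coherent", {
  bin <- matrix(0, 40, 40)
  bin[11:30, 6:35] <- 255
  ct <- extract_largest_contour(bin)
  expect_gte(nrow(ct$points), 3)
  expect_true(all(ct$points[, 1] >= 0 & ct$points[, 1] < 40))
  expect_lte(nrow(ct$approx), nrow(ct$points))
  # far point is a vertex of the simplified contour at maximal distance
  d <- sqrt(rowSums(sweep(ct$approx, 2, ct$centroid)^2))
  expect_equal(sqrt(sum((ct$far_point - ct$centroid)^2)), max(d))
})

test_that("apply_crop uses half-open windows identically on image and mask", {
  img <- array(seq_len(100 * 100 * 3), c(100, 100, 3))
  msk <- matrix(rbinom(100 * 100, 1, 0.3), 100)
  box <- crop_box(5, 5, 25, 15)
  out <- apply_crop(img, msk, box)
  expect_identical(dim(out$image), c(10L, 20L, 3L))
  expect_identical(out$image, img[6:15, 6:25, , drop = FALSE])
  expect_identical(out$mask, msk[6:15, 6:25, drop = FALSE])

  idb <- crop_box(0, 0, 100, 100)
  id <- apply_crop(img, msk, idb)
  expect_identical(id$image, img)
  expect_error(apply_crop(img, msk[1:50, ], box), "differ")
  expect_error(crop_box(5, 5, 5, 15), "degenerate")
})

test_that("standardize normalizes, re-binarizes, and preserves area", {
  img <- array(round(runif(64 * 64 * 3, 0, 255)), c(64, 64, 3))
  msk <- matrix(1L, 64, 64)
  out <- standardize(img, msk, 64)
  expect_equal(out$image, img / 255, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(out$mask == 1))

  # centred disk, 256 -> 128: foreground fraction preserved within 0.02
  xs <- matrix(rep(1:256, each = 256), 256)
  ys <- matrix(rep(1:256, times = 256), 256)
  disk <- ((xs - 128.5)^2 + (ys - 128.5)^2 <= 60^2) * 1L
  out2 <- standardize(array(128, c(256, 256, 3)), disk, 128)
  expect_lt(abs(mean(out2$mask) - mean(disk)), 0.02)
  expect_true(all(out2$mask %in% c(0L, 1L)))
  expect_error(standardize(img, msk, 4), "at least 8")
})

test_that("preprocessing recovers the interior of a black-bordered sample", {
  sp <- synthetic_spec(seed = 19, size = 128, border_widths = c(20, 20, 0, 0))
  s <- generate_sample(sp)
  pre <- preprocess_sample(s$image, s$mask, preprocess_config())
  box <- pre$provenance$crop_box
  expect_identical(box$x1 - box$x0, 128L)  # bands removed exactly
  expect_identical(unclass(box)[c("x0", "y0", "x1", "y1")],
                   unclass(s$interior)[c("x0", "y0", "x1", "y1")])
  expect_identical(dim(pre$image), c(128L, 128L, 3L))
})

test_that("borderless samples keep nearly the whole frame", {
  s <- generate_sample(synthetic_spec(seed = 23, size = 128))
  pre <- preprocess_sample(s$image, s$mask, preprocess_config())
  box <- pre$provenance$crop_box
  area <- (box$x1 - box$x0) * (box$y1 - box$y0)
  expect_gte(area / (128 * 128), 0.95)
})

test_that("an all-black image takes the identity-crop fallback without error", {
  img <- array(0, c(64, 64, 3))
  msk <- matrix(0L, 64, 64)
  pre <- preprocess_sample(img, msk, preprocess_config(target_size = 32))
  expect_identical(dim(pre$image), c(32L, 32L, 3L))
  expect_true(all(pre$mask == 0))
  box <- pre$provenance$crop_box
  expect_identical(c(box$x0, box$y0, box$x1, box$y1), c(0L, 0L, 64L, 64L))
})

test_that("preprocessing is idempotent and respects the output domain", {
  s <- generate_sample(synthetic_spec(seed = 31, size = 96,
                                      border_widths = c(5, 0, 9, 3)))
  cfg <- preprocess_config(target_size = 64)
  pre <- preprocess_sample(s$image, s$mask, cfg)
  expect_true(all(pre$image >= 0 & pre$image <= 1))
  expect_true(all(pre$mask %in% c(0L, 1L)))

  pre2 <- preprocess_sample(round(pre$image * 255), pre$mask, cfg)
  expect_identical(unname(pre2$mask), unname(pre$mask))
  expect_lt(max(abs(pre2$image - pre$image)), 2 / 255 + 1e-12)

  # no all-zero band of width >= 2 survives
  rowmax <- apply(pre$image, 1, max)
  colmax <- apply(pre$image, 2, max)
  expect_lt(max(rle(rowmax == 0)$lengths[rle(rowmax == 0)$values], 0), 2)
  expect_lt(max(rle(colmax == 0)$lengths[rle(colmax == 0)$values], 0), 2)
})

test_that("blur and preprocess configs validate their fields", {
  expect_error(blur_config("median", 4), "odd")
  expect_error(blur_config("gaussian", 5, -1), "positive")
  expect_error(preprocess_config(threshold = 256), "\\[0,255\\]")
})
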