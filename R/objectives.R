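#' Training objectives and segmentation metrics
#'
#' Pixel-wise binary cross-entropy, the soft Dice index (squared-denominator
#' form) and its complement used as a loss, confusion counts at a
#' binarization threshold, and the precision/recall/F1/Dice report.
#'
#' @name objectives
NULL

.check_pair <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop(sprintf("mask pair length mismatch: %d vs %d", length(y), length(y_hat)),
         call. = FALSE)
  }
  if (any(y != 0 & y != 1)) stop("ground truth must be binary {0,1}", call. = FALSE)
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of a binary mask under soft predictions,
#' with predictions clipped to `[eps, 1 - eps]` for numerical safety.
#'
#' @param y Ground-truth mask values in `{0,1}` (any shape; flattened).
#' @param y_hat Predicted probabilities in `[0,1]`, same length.
#' @param eps Clipping constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, y_hat, eps = 1e-7) {
  .check_pair(y, y_hat)
  yc <- pmin(pmax(as.numeric(y_hat), eps), 1 - eps)
  y <- as.numeric(y)
  -mean(y * log(yc) + (1 - y) * log(1 - yc))
}

#' Soft Dice index
#'
#' `(2 * sum(y * y_hat) + smooth) / (sum(y^2) + sum(y_hat^2) + smooth)`.
#' With both masks empty the smoothing term makes the index 1 (perfect
#' agreement on "nothing to segment").
#'
#' @inheritParams bce_loss
#' @param smooth Additive smoothing constant.
#' @return Scalar in `(0, 1]`.
#' @export
dice_index <- function(y, y_hat, smooth = 1e-6) {
  if (length(y) != length(y_hat)) {
    stop(sprintf("mask pair length mismatch: %d vs %d", length(y), length(y_hat)),
         call. = FALSE)
  }
  y <- as.numeric(y)
  y_hat <- as.numeric(y_hat)
  (2 * sum(y * y_hat) + smooth) / (sum(y^2) + sum(y_hat^2) + smooth)
}

#' Dice loss
#'
#' The training form of the Dice objective: `1 - dice_index(y, y_hat)`.
#'
#' @inheritParams dice_index
#' @return Scalar in `[0, 1)`.
#' @export
dice_loss <- function(y, y_hat, smooth = 1e-6) 1 - dice_index(y, y_hat, smooth)

#' Pixel-wise confusion counts
#'
#' Binarizes soft predictions at `threshold` (values `>= threshold` become
#' foreground) and tallies TP/FP/FN/TN against the ground truth.
#'
#' @inheritParams bce_loss
#' @param threshold Binarization threshold in `(0, 1)`.
#' @return List of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(y, y_hat, threshold = 0.5) {
  .check_pair(y, y_hat)
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0,1)", call. = FALSE)
  }
  yb <- as.numeric(y) == 1
  hb <- as.numeric(y_hat) >= threshold
  structure(list(tp = sum(yb & hb), fp = sum(!yb & hb),
                 fn = sum(yb & !hb), tn = sum(!yb & !hb)),
            class = "confusion_counts")
}

.safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Segmentation metrics report
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1, and
#' the Dice index of the binarized prediction. Degenerate 0/0 ratios are
#' reported as 0 (and Dice of two empty masks as 1, via smoothing).
#'
#' @param counts A `confusion_counts` object.
#' @param y,y_hat Optional mask pair used for the Dice entry; when omitted,
#'   Dice is derived from the counts via `2TP / (2TP + FP + FN)` (the exact
#'   binary-mask identity).
#' @param threshold Binarization threshold used for `y_hat`.
#' @param head Which UNet head produced the prediction (1 or 2).
#' @param aggregation Label recorded in the report (`"global"` pixel pooling
#'   or `"per-image-mean"`).
#' @return Object of class `metrics_report`.
#' @export
segmentation_metrics <- function(counts, y = NULL, y_hat = NULL,
                                 threshold = 0.5, head = NA_integer_,
                                 aggregation = "global") {
  stopifnot(inherits(counts, "confusion_counts"))
  p <- .safe_div(counts$tp, counts$tp + counts$fp)
  r <- .safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- .safe_div(2 * p * r, p + r)
  dice <- if (!is.null(y) && !is.null(y_hat)) {
    dice_index(as.numeric(y), as.numeric(as.numeric(y_hat) >= threshold))
  } else if (counts$tp + counts$fp + counts$fn == 0) {
    1
  } else {
    .safe_div(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)
  }
  structure(list(precision = p, recall = r, f1 = f1, dice = dice,
                 counts = counts, head = head, aggregation = aggregation),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("head %s (%s): precision %.4f  recall %.4f  F1 %.4f  Dice %.4f\n",
              x$head, x$aggregation, x$precision, x$recall, x$f1, x$dice))
  invisible(x)
}
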