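#' Training configuration
#'
#' Two strategies are supported, mirroring the two published training
#' scenarios: minimizing pixel-wise binary cross-entropy, or maximizing the
#' Dice index by minimizing `1 - Dice`. Both mask heads are supervised
#' (deep supervision) with configurable weights. Defaults follow the
#' published hyperparameters: learning rate 0.005, batch size 32, Adam.
#'
#' @param strategy `"bce"` or `"dice"`.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param head_loss_weights Length-2 non-negative weights of the two head
#'   losses (not both zero).
#' @param seed RNG seed controlling shuffling.
#' @param threshold Binarization threshold used for validation metrics.
#' @param checkpoint_dir Optional directory; when set, the best
#'   validation-Dice (head 2) model is saved there as `best.rds`.
#' @param verbose Emit one log line per epoch (loss per head, validation
#'   Dice) via `message()`.
#' @return Object of class `train_config`.
#' @export
train_config <- function(strategy = c("bce", "dice"), learning_rate = 0.005,
                         batch_size = 32L, epochs = 50L,
                         head_loss_weights = c(1, 1), seed = 1L,
                         threshold = 0.5, checkpoint_dir = NULL,
                         verbose = FALSE) {
  strategy <- match.arg(strategy)
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be at least 1", call. = FALSE)
  if (epochs < 0L) stop("`epochs` must be non-negative", call. = FALSE)
  if (length(head_loss_weights) != 2L || any(head_loss_weights < 0) ||
      sum(head_loss_weights) == 0) {
    stop("`head_loss_weights` must be two non-negative weights, not both zero",
         call. = FALSE)
  }
  structure(list(strategy = strategy, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 head_loss_weights = as.numeric(head_loss_weights),
                 seed = as.integer(seed), threshold = threshold,
                 checkpoint_dir = checkpoint_dir, verbose = isTRUE(verbose)),
            class = "train_config")
}

# Adam optimizer state and update (Kingma & Ba defaults).
.adam_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Coerce a dataset argument: either a list(x = HxWx3xN, y = HxWxN) or a
# manifest path / data.frame (optionally restricted to one split).
.as_dataset <- function(data, split = NULL) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$x)) return(data)
  load_dataset(data, split = split)
}

# One loss-and-gradient evaluation on a batch. Returns scalar losses and
# the gradient list keyed like model$params.
.batch_grads <- function(model, xb, yb, cfg) {
  tape <- tape_new()
  g <- .dhunet_graph(tape, model, nd_leaf(tape, xb), training = TRUE)
  yarr <- array(yb, dim(g$mask1$value))
  lossf <- if (cfg$strategy == "bce") op_bce else op_dice_loss
  l1 <- lossf(tape, g$mask1, yarr)
  l2 <- lossf(tape, g$mask2, yarr)
  total <- op_wsum(tape, l1, l2, cfg$head_loss_weights[1], cfg$head_loss_weights[2])
  tape_backward(tape, total)
  grads <- lapply(g$pn, function(nd) nd$grad)
  list(loss = total$value, loss1 = l1$value, loss2 = l2$value, grads = grads)
}

#' Train a DHuNeT model
#'
#' Minimizes the weighted sum of both heads' losses (BCE or `1 - Dice`
#' according to the strategy) with Adam, shuffling every epoch with a
#' seeded RNG. When validation data is supplied, the epoch with the best head-2
#' Dice is tracked and its weights are restored in the returned model.
#'
#' @param model A `dhunet_model`.
#' @param train_data,val_data Either a list with `x` (`H x W x 3 x N`) and
#'   `y` (`H x W x N`) or a manifest path/data.frame (split `"train"` /
#'   `"test"` respectively); `val_data` may be `NULL`.
#' @param cfg A [train_config()].
#' @return List with `model` (trained; best-validation weights when
#'   validation data was given), `history` (per-epoch data frame), and
#'   `best_epoch`.
#' @export
dhunet_train <- function(model, train_data, val_data = NULL,
                         cfg = train_config()) {
  stopifnot(inherits(model, "dhunet_model"), inherits(cfg, "train_config"))
  train_data <- .as_dataset(train_data, "train")
  if (!is.null(val_data)) val_data <- .as_dataset(val_data, "test")
  n <- dim(train_data$x)[4]
  if (is.null(n) || n < 1L) stop("empty training set", call. = FALSE)
  if (cfg$epochs == 0L) {
    return(list(model = model, history = data.frame(), best_epoch = NA_integer_))
  }
  opt <- .adam_new(model$params)
  best_dice <- -Inf
  best_params <- NULL
  best_epoch <- NA_integer_
  hist <- vector("list", cfg$epochs)
  .with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- ep_l1 <- ep_l2 <- 0
      for (s in starts) {
        take <- idx[s:min(s + cfg$batch_size - 1L, n)]
        xb <- train_data$x[, , , take, drop = FALSE]
        yb <- train_data$y[, , take, drop = FALSE]
        res <- .batch_grads(model, xb, yb, cfg)
        if (!is.finite(res$loss)) {
          stop(sprintf("non-finite loss (%g) at epoch %d; lower the learning rate",
                       res$loss, epoch), call. = FALSE)
        }
        upd <- .adam_step(model$params, res$grads, opt, cfg$learning_rate)
        model$params <- upd$params
        opt <- upd$state
        w <- length(take) / n
        ep_loss <- ep_loss + res$loss * w
        ep_l1 <- ep_l1 + res$loss1 * w
        ep_l2 <- ep_l2 + res$loss2 * w
      }
      rec <- data.frame(epoch = epoch, loss = ep_loss, loss_head1 = ep_l1,
                        loss_head2 = ep_l2, val_dice_head1 = NA_real_,
                        val_dice_head2 = NA_real_)
      if (!is.null(val_data)) {
        ev <- dhunet_evaluate(model, val_data, threshold = cfg$threshold)
        rec$val_dice_head1 <- ev$head1$global$dice
        rec$val_dice_head2 <- ev$head2$global$dice
        if (rec$val_dice_head2 > best_dice) {
          best_dice <- rec$val_dice_head2
          best_params <- model$params
          best_epoch <- epoch
          if (!is.null(cfg$checkpoint_dir)) {
            dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
            save_dhunet(model, file.path(cfg$checkpoint_dir, "best.rds"))
          }
        }
      }
      if (cfg$verbose) {
        message(sprintf(
          "epoch %d/%d  loss %.4f (head1 %.4f, head2 %.4f)%s",
          epoch, cfg$epochs, ep_loss, ep_l1, ep_l2,
          if (is.null(val_data)) "" else
            sprintf("  val Dice h1 %.4f h2 %.4f", rec$val_dice_head1,
                    rec$val_dice_head2)))
      }
      hist[[epoch]] <- rec
    }
  })
  if (!is.null(best_params)) model$params <- best_params
  list(model = model, history = do.call(rbind, hist), best_epoch = best_epoch)
}

#' Evaluate both heads of a model
#'
#' Computes precision, recall, F1, and Dice for each mask head under both
#' aggregations: `global` pools confusion counts over every pixel of the
#' set (micro); `per_image_mean` averages per-image metric values (macro).
#'
#' @param model A `dhunet_model`.
#' @param data Dataset list or manifest (see [dhunet_train()]).
#' @param threshold Binarization threshold in `(0,1)`.
#' @param batch_size Forward-pass batch size.
#' @return List with `head1` and `head2`, each holding `global` and
#'   `per_image_mean` [segmentation_metrics()] reports.
#' @export
dhunet_evaluate <- function(model, data, threshold = 0.5, batch_size = 16L) {
  stopifnot(inherits(model, "dhunet_model"))
  data <- .as_dataset(data)
  n <- dim(data$x)[4]
  if (is.null(n) || n < 1L) stop("empty evaluation set", call. = FALSE)
  preds <- vector("list", 2)
  for (s in seq(1L, n, by = batch_size)) {
    take <- s:min(s + batch_size - 1L, n)
    out <- dhunet_forward(model, data$x[, , , take, drop = FALSE])
    preds[[1]] <- c(preds[[1]], list(out$mask1))
    preds[[2]] <- c(preds[[2]], list(out$mask2))
  }
  report_head <- function(h) {
    soft <- array(unlist(preds[[h]]), c(dim(data$x)[1:2], n))
    cc <- confusion_counts(data$y, soft, threshold)
    global <- segmentation_metrics(cc, data$y, soft, threshold, head = h,
                                   aggregation = "global")
    per <- vapply(seq_len(n), function(i) {
      ci <- confusion_counts(data$y[, , i], soft[, , i], threshold)
      m <- segmentation_metrics(ci, data$y[, , i], soft[, , i], threshold,
                                head = h, aggregation = "per-image-mean")
      c(m$precision, m$recall, m$f1, m$dice)
    }, numeric(4))
    macro <- segmentation_metrics(cc, head = h, aggregation = "per-image-mean")
    macro$precision <- mean(per[1, ])
    macro$recall <- mean(per[2, ])
    macro$f1 <- mean(per[3, ])
    macro$dice <- mean(per[4, ])
    list(global = global, per_image_mean = macro)
  }
  list(head1 = report_head(1L), head2 = report_head(2L))
}

#' Segment one image and write prediction artifacts
#'
#' Writes, for each head: the soft mask, the binarized mask, and the
#' masked-region overlay (image pixels kept where the binary mask is 1,
#' zero elsewhere) — the three-row presentation used for qualitative
#' inspection of segmentation results.
#'
#' @param model A `dhunet_model`.
#' @param image_path PNG image to segment.
#' @param out_dir Output directory (created if missing).
#' @param cfg A [preprocess_config()]; its `target_size` must match the
#'   model input size.
#' @param threshold Binarization threshold.
#' @return Named character vector of written paths, invisibly.
#' @export
dhunet_predict <- function(model, image_path, out_dir,
                           cfg = preprocess_config(), threshold = 0.5) {
  stopifnot(inherits(model, "dhunet_model"))
  if (!file.exists(image_path)) {
    stop(sprintf("cannot read '%s'", image_path), call. = FALSE)
  }
  img <- .read_image8(image_path)
  pre <- preprocess_sample(img, matrix(0L, dim(img)[1], dim(img)[2]), cfg,
                           provenance = list(source = image_path))
  out <- dhunet_forward(model, array(pre$image, c(dim(pre$image), 1L)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- tools::file_path_sans_ext(basename(image_path))
  paths <- character(0)
  for (h in 1:2) {
    soft <- out[[paste0("mask", h)]][, , 1]
    bin <- (soft >= threshold) * 1
    overlay <- pre$image * array(bin, c(dim(bin), 3L))
    p <- c(soft = file.path(out_dir, sprintf("%s_head%d_soft.png", stem, h)),
           mask = file.path(out_dir, sprintf("%s_head%d_mask.png", stem, h)),
           overlay = file.path(out_dir, sprintf("%s_head%d_overlay.png", stem, h)))
    png::writePNG(soft, p[["soft"]])
    png::writePNG(bin, p[["mask"]])
    png::writePNG(overlay, p[["overlay"]])
    names(p) <- paste0("head", h, "_", names(p))
    paths <- c(paths, p)
  }
  invisible(paths)
}
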