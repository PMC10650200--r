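# Raster and manifest I/O. Masks on disk are single-channel {0,255} PNGs;
# in memory they are {0,1} matrices. Images on disk are 8-bit RGB PNGs; in
# memory 8-bit values held in numeric arrays.

.read_image8 <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing file '%s'", path), call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  round(x * 255)
}

.read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing file '%s'", path), call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x >= 0.5) * 1L
}

#' Load one image/mask pair
#'
#' Reads an 8-bit RGB image (grayscale is promoted to three channels) and a
#' mask stored with the `{0,255}` convention, returned as `{0,1}`.
#'
#' @param image_path,mask_path PNG file paths.
#' @return List with `image` (H x W x 3, 8-bit values) and `mask`
#'   (H x W, `{0,1}`).
#' @export
load_sample <- function(image_path, mask_path) {
  image <- .read_image8(image_path)
  mask <- .read_mask(mask_path)
  if (!identical(dim(image)[1:2], dim(mask))) {
    stop(sprintf("image %s (%dx%d) and mask %s (%dx%d) sizes differ",
                 image_path, dim(image)[1], dim(image)[2],
                 mask_path, dim(mask)[1], dim(mask)[2]), call. = FALSE)
  }
  list(image = image, mask = mask)
}

#' Read a dataset manifest
#'
#' A manifest is a UTF-8 TSV with header `image<TAB>mask<TAB>split`. All
#' referenced files must exist; splits must be `train`, `val`, or `test`.
#'
#' @param path Manifest path.
#' @return Data frame with columns `image`, `mask`, `split`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing manifest '%s'", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("image", "mask", "split")
  if (!all(req %in% names(df))) {
    stop("manifest must have columns image, mask, split", call. = FALSE)
  }
  if (!all(df$split %in% c("train", "val", "test"))) {
    stop("manifest splits must be train/val/test", call. = FALSE)
  }
  missing <- c(df$image[!file.exists(df$image)], df$mask[!file.exists(df$mask)])
  if (length(missing)) {
    stop(sprintf("manifest references missing files: %s",
                 paste(utils::head(missing, 3), collapse = ", ")), call. = FALSE)
  }
  df[req]
}

#' Write a dataset manifest
#'
#' @param manifest Data frame with columns `image`, `mask`, `split`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[c("image", "mask", "split")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a dataset into memory as training arrays
#'
#' Loads every manifest row (optionally one split), optionally pushes each
#' pair through [preprocess_sample()], and stacks the results. Without
#' preprocessing, images are scaled to `[0,1]` directly and all samples
#' must share one size.
#'
#' @param manifest Manifest path or data frame.
#' @param split Optional split filter (`"train"`, `"val"`, `"test"`).
#' @param preprocess Optional [preprocess_config()].
#' @return List with `x` (`H x W x 3 x N`), `y` (`H x W x N`), and `paths`.
#' @export
load_dataset <- function(manifest, split = NULL, preprocess = NULL) {
  df <- if (is.data.frame(manifest)) manifest else load_manifest(manifest)
  if (!is.null(split)) df <- df[df$split == split, , drop = FALSE]
  if (nrow(df) == 0L) stop("no samples selected from manifest", call. = FALSE)
  xs <- vector("list", nrow(df))
  ys <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    smp <- load_sample(df$image[i], df$mask[i])
    if (!is.null(preprocess)) {
      pre <- preprocess_sample(smp$image, smp$mask, preprocess)
      xs[[i]] <- pre$image
      ys[[i]] <- pre$mask
    } else {
      xs[[i]] <- smp$image / 255
      ys[[i]] <- smp$mask
    }
  }
  d <- dim(xs[[1]])
  if (!all(vapply(xs, function(x) identical(dim(x), d), logical(1)))) {
    stop("samples have differing sizes; supply a `preprocess` config", call. = FALSE)
  }
  list(x = array(unlist(xs), c(d, nrow(df))),
       y = array(unlist(ys), c(d[1:2], nrow(df))),
       paths = df)
}

#' Write a metrics report table
#'
#' TSV with header `strategy	head	recall	precision	f1	dice	aggregation`,
#' one row per report, values rendered with four decimals in a fixed column
#' order. A path ending in `.json` writes the same rows as a JSON array
#' (with full-precision values and the confusion counts included).
#'
#' @param reports A single [segmentation_metrics()] report or a list of
#'   them.
#' @param path Output TSV (or JSON) path.
#' @param strategy Strategy label(s) recorded per row.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, strategy = "bce") {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  if (!length(reports)) stop("no reports to write", call. = FALSE)
  strategy <- rep_len(strategy, length(reports))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- lapply(seq_along(reports), function(i) {
      r <- reports[[i]]
      list(strategy = strategy[i], head = r$head, recall = r$recall,
           precision = r$precision, f1 = r$f1, dice = r$dice,
           aggregation = r$aggregation, counts = unclass(r$counts))
    })
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(strategy = strategy[i], head = r$head,
               recall = sprintf("%.4f", r$recall),
               precision = sprintf("%.4f", r$precision),
               f1 = sprintf("%.4f", r$f1),
               dice = sprintf("%.4f", r$dice),
               aggregation = r$aggregation, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model
#'
#' `save_dhunet()` serializes the model with R's native serialization and
#' writes a plain-text sidecar (`<path>.params.txt`) holding the trainable
#' parameter count for external cross-checking.
#'
#' @param model A `dhunet_model`.
#' @param path Destination `.rds` path.
#' @return `path` (save) or the restored model (load).
#' @export
save_dhunet <- function(model, path) {
  stopifnot(inherits(model, "dhunet_model"))
  bn <- lapply(model$bn_state, function(e) as.list(e))
  obj <- list(config = unclass(model$config), params = model$params,
              bn_state = bn, seed = model$seed)
  saveRDS(obj, path)
  writeLines(sprintf("trainable_parameters\t%d", count_parameters(model)),
             paste0(path, ".params.txt"))
  invisible(path)
}

#' @rdname save_dhunet
#' @export
load_dhunet <- function(path) {
  obj <- readRDS(path)
  bn <- lapply(obj$bn_state, function(l) list2env(l, parent = emptyenv()))
  structure(list(config = structure(obj$config, class = "dhunet_config"),
                 params = obj$params, bn_state = bn, seed = obj$seed),
            class = "dhunet_model")
}

#' Read a DHuNeT architecture configuration from a YAML file
#'
#' Keys mirror the arguments of [dhunet_config()].
#'
#' @param path YAML file path.
#' @return A [dhunet_config()].
#' @export
load_dhunet_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(dhunet_config)))
  do.call(dhunet_config, vals[keep])
}
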