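# File I/O: PNG images and masks, TIFF TSDF stacks, YAML configs,
# checkpoints.

#' Read a grayscale image
#'
#' 8- or 16-bit PNG (or TIFF); multi-channel images are averaged to one
#' channel.  Values are returned in `[0, 1]`.
#'
#' @param path File path.
#' @return `H x W` numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  a <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                      c(1, 2), mean)
  a
}

#' Write a grayscale image as PNG
#'
#' @param image `H x W` matrix in `[0, 1]`.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read an integer label mask
#'
#' Single-channel 8-bit PNG whose pixel value is the class index.
#'
#' @param path File path.
#' @param K Optional class count; values `>= K` raise an error.
#' @return `H x W` integer matrix.
#' @export
read_mask <- function(path, K = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
  if (!is.null(K) && any(m >= K)) {
    stop("mask ", path, " contains class values >= K = ", K)
  }
  m
}

#' Write an integer label mask as 8-bit PNG
#'
#' The round trip `write_mask()` then [read_mask()] is lossless for class
#' indices up to 255.
#'
#' @param mask `H x W` integer matrix (values in `0 .. 255`).
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  if (any(mask < 0) || any(mask > 255)) stop("mask values must be in 0..255")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Export / import a TSDF stack as a multi-page TIFF
#'
#' TIFF stores unsigned intensities, so the `[-1, 1]` values are mapped to
#' `[0, 1]` on write (one 32-bit page per class) and mapped back on read.
#'
#' @param stack `H x W x K` array with values in `[-1, 1]`.
#' @param path File path.
#' @export
write_tsdf_tiff <- function(stack, path) {
  d <- dim(stack)
  pages <- lapply(seq_len(d[3]),
                  function(k) matrix((stack[, , k] + 1) / 2, d[1], d[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_tsdf_tiff
#' @export
read_tsdf_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) out[, , k] <- 2 * pages[[k]] - 1
  out
}

#' Export a weight map as a PNG heatmap
#'
#' @param weights `H x W` matrix in `(0, 1]`.
#' @param path Output path.
#' @export
write_weight_png <- function(weights, path) {
  write_image(weights, path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys produce a warning naming the accepted ones; missing keys take
#' the package defaults.
#'
#' @param path YAML file.
#' @return List with `train` ([train_config()]), `loss` ([loss_config()]),
#'   `spec` ([model_spec()]) and `prune` settings.
#' @export
read_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  accepted <- list(
    train = names(formals(train_config)),
    loss = names(formals(loss_config)),
    spec = names(formals(model_spec)),
    prune = c("r_p", "n_iters", "finetune_epochs", "min_kept"))
  for (sec in names(raw)) {
    if (!sec %in% names(accepted)) {
      warning("unknown config section '", sec, "'; accepted: ",
              paste(names(accepted), collapse = ", "))
      next
    }
    bad <- setdiff(names(raw[[sec]]), accepted[[sec]])
    if (length(bad)) {
      warning("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "),
              "; accepted: ", paste(accepted[[sec]], collapse = ", "))
      raw[[sec]] <- raw[[sec]][intersect(names(raw[[sec]]), accepted[[sec]])]
    }
  }
  loss <- do.call(loss_config, raw$loss %||% list())
  train_args <- raw$train %||% list()
  train_args$loss <- loss
  prune <- utils::modifyList(list(r_p = 0.2, n_iters = 5,
                                  finetune_epochs = 20, min_kept = 4),
                             raw$prune %||% list())
  list(train = do.call(train_config, train_args), loss = loss,
       spec = do.call(model_spec, raw$spec %||% list()), prune = prune)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the spec, kept-kernel bookkeeping, parameter
#' values and batch-norm state, with a format version stamp.
#'
#' @param model A `layerseg_model`.
#' @param path Checkpoint path.
#' @return `save_checkpoint()` returns the path; `load_checkpoint()` the
#'   rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(version = 1L, spec = model$spec,
              kept_n = as.list(model$kept_n),
              params = lapply(model$params, function(p) p$val),
              bn = lapply(model$bn, function(s) list(rm = s$rm, rv = s$rv)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version) || obj$version != 1L) {
    stop("unsupported checkpoint version")
  }
  model <- build_model(obj$spec, kept = obj$kept_n)
  for (nm in names(obj$params)) model$params[[nm]]$val <- obj$params[[nm]]
  for (nm in names(obj$bn)) {
    model$bn[[nm]]$rm <- obj$bn[[nm]]$rm
    model$bn[[nm]]$rv <- obj$bn[[nm]]$rv
  }
  model
}
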