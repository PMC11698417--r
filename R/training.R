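# End-to-end training: joint augmentation, cosine learning-rate annealing,
# Adam, cached full-image TSDF targets, and k-fold cross-validation.

#' Training configuration
#'
#' Defaults are the full-scale training recipe (Adam, cosine annealing from 5e-4 to
#' 5e-6, weight decay 1e-5, batch size 8, crops, flips and photometric
#' jitter each with probability 0.5); scale parameters (epochs, crop) are
#' meant to be overridden for desk-scale experiments.
#'
#' @param epochs Training epochs.
#' @param batch_size Images per gradient step.
#' @param lr_start,lr_end Cosine-annealed learning-rate endpoints.
#' @param weight_decay L2 penalty added to the Adam gradient.
#' @param crop Training crop size in pixels: `c(height, width)` or a single
#'   number; `NULL` trains on full images.
#' @param flip_p,brightness_p,contrast_p Augmentation probabilities
#'   (`flip_p` sets both flips).
#' @param vflip_p Vertical-flip probability; defaults to `flip_p`.  Layered
#'   data carries a strong depth prior, so desk-scale runs may want to keep
#'   horizontal flips only.
#' @param jitter Relative strength of brightness/contrast jitter.
#' @param folds Folds for [cross_validate()].
#' @param seed Seed for shuffling, augmentation and initialization.
#' @param loss A [loss_config()].
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, batch_size = 8, lr_start = 5e-4,
                         lr_end = 5e-6, weight_decay = 1e-5, crop = 256,
                         flip_p = 0.5, vflip_p = flip_p, brightness_p = 0.5,
                         contrast_p = 0.5, jitter = 0.2, folds = 5, seed = 1,
                         loss = loss_config()) {
  if (lr_end > lr_start) stop("lr_end must be <= lr_start")
  probs <- c(flip_p, vflip_p, brightness_p, contrast_p)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  structure(list(epochs = epochs, batch_size = batch_size,
                 lr_start = lr_start, lr_end = lr_end,
                 weight_decay = weight_decay, crop = crop, flip_p = flip_p,
                 vflip_p = vflip_p, brightness_p = brightness_p,
                 contrast_p = contrast_p, jitter = jitter, folds = folds,
                 seed = seed, loss = loss),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr_end + 0.5 * (lr_start - lr_end) * (1 + cos(pi * t / total))`.
#'
#' @param step Current step (0-based).
#' @param total_steps Total steps (>= 1).
#' @param lr_start,lr_end Endpoints.
#' @return The learning rate at `step`.
#' @export
cosine_lr <- function(step, total_steps, lr_start = 5e-4, lr_end = 5e-6) {
  if (total_steps < 1) stop("total_steps must be >= 1")
  lr_end + 0.5 * (lr_start - lr_end) * (1 + cos(pi * step / total_steps))
}

#' Jointly augment an image/mask (/TSDF) sample
#'
#' Random crop and horizontal/vertical flips are applied jointly to the
#' image, the mask and (when present) the cached TSDF stack; brightness and
#' contrast jitter touch the image only, so the mask's label set can only
#' shrink (cropping) and never gains new classes.
#'
#' @param sample `list(image, mask[, tsdf])`.
#' @param config A [train_config()].
#' @return The augmented sample.
#' @export
augment <- function(sample, config) {
  img <- sample$image; mask <- sample$mask; tsdf <- sample$tsdf
  H <- nrow(img); W <- ncol(img)
  crop <- config$crop
  if (!is.null(crop)) {
    ch <- if (length(crop) == 2) crop[1] else crop
    cw <- if (length(crop) == 2) crop[2] else crop
    if (ch > H || cw > W) stop("crop larger than image (", ch, "x", cw,
                               " vs ", H, "x", W, ")")
    r0 <- sample.int(H - ch + 1L, 1)
    c0 <- sample.int(W - cw + 1L, 1)
    rows <- r0:(r0 + ch - 1L); cols <- c0:(c0 + cw - 1L)
    img <- img[rows, cols]; mask <- mask[rows, cols]
    if (!is.null(tsdf)) tsdf <- tsdf[rows, cols, , drop = FALSE]
  }
  if (stats::runif(1) < config$flip_p) {  # horizontal
    img <- img[, rev(seq_len(ncol(img)))]
    mask <- mask[, rev(seq_len(ncol(mask)))]
    if (!is.null(tsdf)) tsdf <- tsdf[, rev(seq_len(ncol(tsdf))), , drop = FALSE]
  }
  if (stats::runif(1) < (config$vflip_p %||% config$flip_p)) {  # vertical
    img <- img[rev(seq_len(nrow(img))), ]
    mask <- mask[rev(seq_len(nrow(mask))), ]
    if (!is.null(tsdf)) tsdf <- tsdf[rev(seq_len(nrow(tsdf))), , , drop = FALSE]
  }
  if (stats::runif(1) < config$brightness_p) {
    img <- img + stats::runif(1, -config$jitter, config$jitter)
  }
  if (stats::runif(1) < config$contrast_p) {
    img <- mean(img) + (img - mean(img)) *
      stats::runif(1, 1 - config$jitter, 1 + config$jitter)
  }
  img <- pmin(pmax(img, 0), 1)
  out <- list(image = img, mask = mask)
  if (!is.null(tsdf)) out$tsdf <- tsdf
  out
}

cache_tsdf <- function(dataset, K, tau) {
  # full-image targets cached once; crops slice the cached stack so the
  # normalization stays defined on the whole image
  lapply(dataset, function(s) {
    if (is.null(s$tsdf)) s$tsdf <- tsdf_stack(s$mask, K, tau)
    s
  })
}

#' Train the dual-branch model
#'
#' Minimizes the composite loss with Adam under a cosine learning-rate
#' schedule.  TSDF targets are precomputed per image and cropped with the
#' augmentation; the adaptive weight is recomputed every step from the
#' configured source without gradient flow.
#'
#' @param model A `layerseg_model` (modified in place and returned).
#' @param dataset List of samples `list(image, mask)`.
#' @param config A [train_config()].
#' @param val_data Optional held-out samples; when given, validation mean
#'   Dice is logged per epoch.
#' @return List with `model` and `log` (one row per epoch: loss components,
#'   learning rate, optional `val_dice`).
#' @export
train_model <- function(model, dataset, config = train_config(),
                        val_data = NULL) {
  if (length(dataset) == 0) stop("empty dataset")
  K <- model$spec$n_classes
  lc <- config$loss
  dataset <- cache_tsdf(dataset, K, lc$tau)
  set.seed(config$seed)
  params <- model$params
  opt <- new_adam(params, weight_decay = config$weight_decay)
  n <- length(dataset)
  bs <- min(config$batch_size, n)
  steps_per_epoch <- ceiling(n / bs)
  total_steps <- config$epochs * steps_per_epoch
  step <- 0L
  log_rows <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    comp <- c(total = 0, ce = 0, dice = 0, bou = 0)
    nb <- 0L
    for (s0 in seq(1, n, by = bs)) {
      idx <- ord[s0:min(s0 + bs - 1L, n)]
      batch <- lapply(dataset[idx], augment, config = config)
      hb <- nrow(batch[[1]]$image); wb <- ncol(batch[[1]]$image)
      nbatch <- length(batch)
      x <- array(0, c(hb, wb, 1L, nbatch))
      mask <- array(0L, c(hb, wb, nbatch))
      target <- array(0, c(hb, wb, K, nbatch))
      for (i in seq_len(nbatch)) {
        x[, , 1L, i] <- batch[[i]]$image
        mask[, , i] <- batch[[i]]$mask
        target[, , , i] <- batch[[i]]$tsdf
      }
      tape <- new_tape()
      fw <- model_forward(model, x, training = TRUE, tape = tape)
      onehot <- onehot_mask(mask, K)
      weights <- array(1, c(hb, wb, nbatch))
      if (lc$use_adaptive_weight) {
        src <- if (lc$weight_source == "predicted") fw$tsdf else target
        for (i in seq_len(nbatch)) {
          weights[, , i] <- tsdf_weight_map(array(src[, , , i],
                                                  c(hb, wb, K)))
        }
      }
      l_ce <- op_weighted_ce(tape, fw$nodes$seg, onehot, weights, lc$epsilon)
      l_di <- op_dice_loss(tape, fw$nodes$seg, onehot, lc$epsilon)
      l_bo <- op_weighted_mse(tape, fw$nodes$tsdf, target, weights)
      total <- op_scale_add(tape, list(l_ce, l_di, l_bo),
                            c(1, 1, lc$lambda_bou))
      zero_grads(params)
      tape_backward(tape, total)
      lr <- cosine_lr(step, total_steps, config$lr_start, config$lr_end)
      adam_step(opt, params, lr)
      step <- step + 1L
      comp <- comp + c(total$val, l_ce$val, l_di$val, l_bo$val)
      nb <- nb + 1L
    }
    row <- data.frame(epoch = ep, loss = comp[1] / nb, ce = comp[2] / nb,
                      dice_loss = comp[3] / nb, bou = comp[4] / nb,
                      lr = cosine_lr(step - 1L, total_steps,
                                     config$lr_start, config$lr_end))
    if (!is.null(val_data)) {
      row$val_dice <- evaluate_model(model, val_data)$mean_dice
    }
    log_rows[[ep]] <- row
  }
  list(model = model, log = do.call(rbind, log_rows))
}

#' Predict a label mask (and TSDF) for one image
#'
#' Images whose size is not divisible by 16 are reflection-padded and the
#' outputs cropped back.
#'
#' @param model A `layerseg_model`.
#' @param image `H x W` matrix in `[0, 1]`.
#' @return List with `mask` (`H x W` integer, argmax class), `probs`
#'   (`H x W x K`) and `tsdf` (`H x W x K`).
#' @export
predict_model <- function(model, image) {
  H <- nrow(image); W <- ncol(image)
  ph <- (16 - H %% 16) %% 16
  pw <- (16 - W %% 16) %% 16
  padded <- image
  if (ph > 0) padded <- rbind(padded, padded[H - seq_len(ph) + 1L, , drop = FALSE])
  if (pw > 0) padded <- cbind(padded, padded[, W - seq_len(pw) + 1L, drop = FALSE])
  fw <- model_forward(model, padded, training = FALSE)
  K <- model$spec$n_classes
  probs <- array(fw$seg, dim(fw$seg)[1:3])[seq_len(H), seq_len(W), , drop = FALSE]
  tsd <- array(fw$tsdf, dim(fw$tsdf)[1:3])[seq_len(H), seq_len(W), , drop = FALSE]
  m <- matrix(probs, H * W, K)
  mask <- matrix(max.col(m, ties.method = "first") - 1L, H, W)
  list(mask = mask, probs = probs, tsdf = tsd)
}

#' Evaluate a model on a set of samples
#'
#' Full-size (uncropped) inference per image; Dice/IoU averaged over images
#' with background excluded from the means.
#'
#' @param model A `layerseg_model`.
#' @param samples List of `list(image, mask)`.
#' @return List with `mean_dice`, `mean_iou`, `topology_violation_rate`
#'   (fraction of image columns breaking the layer order), and the
#'   `per_image` data frame.
#' @export
evaluate_model <- function(model, samples) {
  K <- model$spec$n_classes
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    pr <- predict_model(model, s$image)
    rep_ <- dice_iou(pr$mask, s$mask, K)
    data.frame(image = i, dice = rep_$mean_dice, iou = rep_$mean_iou,
               topo = column_topology_violations(pr$mask))
  })
  per_image <- do.call(rbind, rows)
  list(mean_dice = mean(per_image$dice), mean_iou = mean(per_image$iou),
       topology_violation_rate = mean(per_image$topo),
       per_image = per_image)
}

#' K-fold cross-validation
#'
#' Deterministic fold assignment from the config seed; trains one model per
#' fold and returns the fold with the highest validation mean Dice as the
#' selected model.
#'
#' @param dataset List of samples.
#' @param config A [train_config()].
#' @param spec A [model_spec()] used to build each fold's model.
#' @return List with `models`, `fold_dice`, `folds` (assignment vector),
#'   `best_fold` and `model` (the selected one).
#' @export
cross_validate <- function(dataset, config = train_config(),
                           spec = model_spec()) {
  n <- length(dataset)
  if (n < config$folds) stop("need at least as many images as folds")
  set.seed(config$seed)
  folds <- sample(rep(seq_len(config$folds), length.out = n))
  models <- vector("list", config$folds)
  fold_dice <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    tr <- dataset[folds != f]
    va <- dataset[folds == f]
    m <- build_model(spec, seed = config$seed + f)
    fit <- train_model(m, tr, config)
    models[[f]] <- fit$model
    fold_dice[f] <- evaluate_model(fit$model, va)$mean_dice
  }
  best <- which.max(fold_dice)
  list(models = models, fold_dice = fold_dice, folds = folds,
       best_fold = best, model = models[[best]])
}
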