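# Desk-scale end-to-end experiment: train a small-channel model on easy
# synthetic layered images, measure held-out recovery, then prune once and
# fine-tune.  Used by the acceptance checks and the reproduction script.

#' Desk-scale parameter-recovery experiment
#'
#' Generates an easy synthetic dataset (high contrast, low noise, K classes),
#' trains a small-channel dual-branch model, evaluates held-out mean
#' foreground Dice and column-topology violations, then performs one
#' structured-prune iteration (attention-scored, with weight transfer)
#' followed by a short fine-tune and re-evaluates.
#'
#' The training configuration is the package's desk-scale default: batch 2,
#' cosine learning rate 3e-3 to 3e-5, full-height 128 x 48 crops, horizontal
#' flips only, no photometric jitter, adaptive weights from the predicted
#' TSDF.  See the methods vignette for the rationale behind these choices.
#'
#' @param seed Master seed for data, initialization and training.
#' @param n_train,n_test Dataset sizes.
#' @param K Number of classes (background + K-1 layers).
#' @param width,height Image size.
#' @param channels Model channel plan.
#' @param epochs Training epochs.
#' @param prune_ratio Fraction of kernels removed in the prune step
#'   (`NULL` or 0 skips pruning).
#' @param finetune_epochs Fine-tuning epochs after the prune.
#' @param n_importance Training images used for importance accumulation.
#' @return List with `dice`, `iou`, `topology_violation_rate`,
#'   `params_before`, and, when pruning ran, `pruned_dice`, `pruned_topo`,
#'   `params_after`; plus `model`, `pruned_model` and the training `log`.
#' @export
run_recovery_experiment <- function(seed, n_train = 64, n_test = 8, K = 5,
                                    width = 256, height = 128,
                                    channels = c(8, 16, 32, 32, 32),
                                    epochs = 12, prune_ratio = 0.2,
                                    finetune_epochs = 2,
                                    n_importance = 16) {
  train <- synth_samples(n_train, width = width, height = height, K = K,
                         seed = seed * 19L + 3L, easy = TRUE)
  test <- synth_samples(n_test, width = width, height = height, K = K,
                        seed = seed * 19L + 7L, easy = TRUE)
  spec <- model_spec(channels = channels, n_classes = K)
  cfg <- train_config(epochs = epochs, batch_size = 2, lr_start = 3e-3,
                      lr_end = 3e-5, crop = c(height, 48), flip_p = 0.5,
                      vflip_p = 0, brightness_p = 0, contrast_p = 0,
                      seed = seed)
  model <- build_model(spec, seed = seed)
  fit <- train_model(model, train, cfg)
  ev <- evaluate_model(fit$model, test)
  out <- list(dice = ev$mean_dice, iou = ev$mean_iou,
              topology_violation_rate = ev$topology_violation_rate,
              params_before = count_parameters(fit$model),
              model = fit$model, log = fit$log)
  if (!is.null(prune_ratio) && prune_ratio > 0) {
    idx <- seq_len(min(n_importance, n_train))
    batches <- lapply(split(idx, ceiling(seq_along(idx) / 4)), function(ii) {
      arr <- array(0, c(height, width, 1L, length(ii)))
      for (j in seq_along(ii)) arr[, , 1L, j] <- train[[ii[j]]]$image
      arr
    })
    tab <- accumulate_importance(fit$model, batches)
    plan <- plan_prune(tab, prune_ratio)
    pruned <- apply_prune(fit$model, plan)
    if (finetune_epochs > 0) {
      cfg_ft <- cfg
      cfg_ft$epochs <- finetune_epochs
      cfg_ft$lr_start <- 3e-4
      cfg_ft$lr_end <- 3e-5
      pruned <- train_model(pruned, train, cfg_ft)$model
    }
    evp <- evaluate_model(pruned, test)
    out$pruned_dice <- evp$mean_dice
    out$pruned_topo <- evp$topology_violation_rate
    out$params_after <- count_parameters(pruned)
    out$pruned_model <- pruned
  }
  out
}
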