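# Composite training objective: weighted cross-entropy + Dice for the
# segmentation branch, weighted MSE on the TSDF for the boundary branch.

#' Loss configuration
#'
#' @param lambda_bou Weight of the boundary-regression term (>= 0).
#' @param use_adaptive_weight If `TRUE`, both the cross-entropy and the
#'   boundary MSE are multiplied per pixel by the entropy weight; otherwise
#'   the weight is 1 everywhere.
#' @param weight_source Where the weight's TSDF comes from: `"predicted"`
#'   (the network's boundary output, detached from the gradient) or
#'   `"ground_truth"` (the label-derived stack).
#' @param epsilon Stabilizer added inside logs and Dice denominators.
#' @param tau Truncation distance used when a target TSDF must be computed
#'   from the mask.
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda_bou = 1.0, use_adaptive_weight = TRUE,
                        weight_source = c("predicted", "ground_truth"),
                        epsilon = 1e-7, tau = 5) {
  if (lambda_bou < 0) stop("lambda_bou must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(lambda_bou = lambda_bou,
                 use_adaptive_weight = isTRUE(use_adaptive_weight),
                 weight_source = match.arg(weight_source),
                 epsilon = epsilon, tau = tau),
            class = "loss_config")
}

check_loss_shapes <- function(probs, onehot, weights = NULL) {
  if (!identical(dim(probs), dim(onehot))) {
    stop("probs and onehot must share shape (H, W, K, N)")
  }
  if (!is.null(weights)) {
    d <- dim(probs)
    if (!identical(as.integer(dim(weights)[1:2]), as.integer(d[1:2]))) {
      stop("weights must be (H, W[, N]) matching probs")
    }
  }
  invisible(NULL)
}

as_batch <- function(a) {
  # promote (H, W, K) to (H, W, K, 1)
  if (length(dim(a)) == 3) dim(a) <- c(dim(a), 1L)
  a
}

#' Weighted cross-entropy loss
#'
#' `-(1/N) * sum_images sum_k (1/(H*W)) * sum_pixels w * y * log(p + eps)`.
#' Equals the unweighted cross-entropy when `w` is 1 everywhere.
#'
#' @param probs `H x W x K x N` array of class probabilities (sum to 1 over
#'   the class dimension at each pixel).
#' @param onehot One-hot ground truth of the same shape.
#' @param weights `H x W x N` (or `H x W`) positive per-pixel weights.
#' @param epsilon Log stabilizer.
#' @return Non-negative scalar.
#' @export
weighted_cross_entropy <- function(probs, onehot, weights = NULL,
                                   epsilon = 1e-7) {
  probs <- as_batch(probs); onehot <- as_batch(onehot)
  check_loss_shapes(probs, onehot, weights)
  d <- dim(probs)
  if (is.null(weights)) weights <- array(1, c(d[1], d[2], d[4]))
  w4 <- array(weights, c(d[1], d[2], 1L, d[4]))
  -sum(expand_spatial(w4, d[3]) * onehot * log(probs + epsilon)) /
    (d[4] * d[1] * d[2])
}

#' Dice loss
#'
#' Summed over classes and images:
#' `1 - 2 * sum(y*p) / (sum(y) + sum(p) + eps)` per class per image.
#'
#' @inheritParams weighted_cross_entropy
#' @return Scalar in `[0, N * K]`.
#' @export
dice_loss <- function(probs, onehot, epsilon = 1e-7) {
  probs <- as_batch(probs); onehot <- as_batch(onehot)
  check_loss_shapes(probs, onehot)
  inter <- collapse_channel(probs * onehot)
  tots <- collapse_channel(probs) + collapse_channel(onehot)
  sum(1 - 2 * inter / (tots + epsilon))
}

#' Weighted boundary-regression MSE
#'
#' `(1/N) * sum_images sum_k (1/(H*W)) * sum_pixels w * (s - d)^2` between
#' the predicted and target TSDF stacks.
#'
#' @param pred_tsdf,target_tsdf `H x W x K x N` arrays.
#' @param weights `H x W x N` (or `H x W`) per-pixel weights.
#' @return Non-negative scalar; zero iff prediction equals the target
#'   wherever the weight is positive.
#' @export
boundary_mse <- function(pred_tsdf, target_tsdf, weights = NULL) {
  pred_tsdf <- as_batch(pred_tsdf); target_tsdf <- as_batch(target_tsdf)
  check_loss_shapes(pred_tsdf, target_tsdf, weights)
  d <- dim(pred_tsdf)
  if (is.null(weights)) weights <- array(1, c(d[1], d[2], d[4]))
  w4 <- array(weights, c(d[1], d[2], 1L, d[4]))
  diff <- pred_tsdf - target_tsdf
  sum(expand_spatial(w4, d[3]) * diff * diff) / (d[4] * d[1] * d[2])
}

#' One-hot encode a label mask
#'
#' @param mask `H x W` integer matrix or `H x W x N` array (values
#'   `0 .. K-1`).
#' @param K Number of classes.
#' @return `H x W x K x N` array of 0/1.
#' @export
onehot_mask <- function(mask, K) {
  if (length(dim(mask)) == 2 || is.null(dim(mask))) {
    mask <- array(mask, c(nrow(mask), ncol(mask), 1L))
  }
  d <- dim(mask)
  out <- array(0, c(d[1], d[2], K, d[3]))
  for (k in seq_len(K) - 1L) {
    out[, , k + 1L, ] <- (mask == k) * 1
  }
  out
}

#' Total dual-branch loss
#'
#' `L = Lce + Ldice + lambda * Lbou` with the adaptive entropy weight
#' multiplying both the cross-entropy and the boundary MSE.  The weight is
#' computed outside the gradient path, from the predicted TSDF by default.
#'
#' @param seg_probs `H x W x K x N` segmentation probabilities.
#' @param pred_tsdf `H x W x K x N` predicted TSDF.
#' @param mask `H x W` matrix or `H x W x N` integer array of labels.
#' @param config A [loss_config()].
#' @param target_tsdf Optional precomputed `H x W x K x N` target stack; when
#'   `NULL` it is computed per image from `mask` with `config$tau`.
#' @return List with `total`, `ce`, `dice`, `bou`, and the `weights` used.
#' @export
total_loss <- function(seg_probs, pred_tsdf, mask, config = loss_config(),
                       target_tsdf = NULL) {
  seg_probs <- as_batch(seg_probs); pred_tsdf <- as_batch(pred_tsdf)
  d <- dim(seg_probs)
  K <- d[3]; N <- d[4]
  if (length(dim(mask)) == 2 || is.null(dim(mask))) {
    mask <- array(mask, c(d[1], d[2], 1L))
  }
  onehot <- onehot_mask(mask, K)
  if (is.null(target_tsdf)) {
    target_tsdf <- array(0, d)
    for (n in seq_len(N)) {
      target_tsdf[, , , n] <- tsdf_stack(
        matrix(mask[, , n], d[1], d[2]), K, config$tau)
    }
  }
  target_tsdf <- as_batch(target_tsdf)
  weights <- array(1, c(d[1], d[2], N))
  if (config$use_adaptive_weight) {
    src <- if (config$weight_source == "predicted") pred_tsdf else target_tsdf
    for (n in seq_len(N)) {
      weights[, , n] <- tsdf_weight_map(array(src[, , , n], d[1:3]))
    }
  }
  ce <- weighted_cross_entropy(seg_probs, onehot, weights, config$epsilon)
  dl <- dice_loss(seg_probs, onehot, config$epsilon)
  bou <- boundary_mse(pred_tsdf, target_tsdf, weights)
  list(total = ce + dl + config$lambda_bou * bou,
       ce = ce, dice = dl, bou = bou, weights = weights)
}
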