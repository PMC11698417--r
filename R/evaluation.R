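# Overlap metrics and layer-topology diagnostics.

#' Per-class Dice and IoU
#'
#' Dice `= 2|P∩T| / (|P| + |T|)` and IoU `= |P∩T| / |P∪T|` per class; a
#' class absent from both masks scores 1 by convention so small-set means
#' stay defined.  The reported means exclude the background class unless
#' `include_background` is set.
#'
#' @param pred,truth `H x W` integer label matrices with values `< K`.
#' @param K Number of classes.
#' @param include_background Include class 0 in the means.
#' @return List with `dice`, `iou` (length-`K` vectors, class `k` at index
#'   `k + 1`), `mean_dice` and `mean_iou`.
#' @export
dice_iou <- function(pred, truth, K, include_background = FALSE) {
  if (!identical(dim(pred), dim(truth))) stop("pred and truth shapes differ")
  if (any(pred >= K) || any(truth >= K)) stop("labels must be < K")
  dice <- numeric(K); iou <- numeric(K)
  for (k in seq_len(K) - 1L) {
    p <- pred == k; t_ <- truth == k
    np <- sum(p); nt <- sum(t_); ni <- sum(p & t_)
    if (np + nt == 0) {
      dice[k + 1L] <- 1; iou[k + 1L] <- 1
    } else {
      dice[k + 1L] <- 2 * ni / (np + nt)
      iou[k + 1L] <- ni / (np + nt - ni)
    }
  }
  sel <- if (include_background) seq_len(K) else seq_len(K)[-1]
  list(dice = dice, iou = iou,
       mean_dice = mean(dice[sel]), mean_iou = mean(iou[sel]))
}

#' Fraction of columns violating the layer order
#'
#' A column is valid when its top-to-bottom run-length class sequence is
#' (optional background, strictly increasing tissue indices, optional
#' trailing background) — i.e. each ordered layer is crossed at most once.
#'
#' @param mask `H x W` integer label matrix.
#' @return Fraction of violating columns in `[0, 1]`.
#' @export
column_topology_violations <- function(mask) {
  bad <- vapply(seq_len(ncol(mask)), function(cc) {
    runs <- rle(mask[, cc])$values
    if (length(runs) == 0) return(FALSE)
    if (runs[1] == 0) runs <- runs[-1]
    if (length(runs) > 0 && runs[length(runs)] == 0) runs <- runs[-length(runs)]
    if (length(runs) == 0) return(FALSE)
    any(runs == 0) || any(diff(runs) <= 0)
  }, logical(1))
  mean(bad)
}
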