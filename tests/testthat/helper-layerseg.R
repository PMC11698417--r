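# Shared fixtures: all synthetic, built in code.

tiny_spec <- function(K = 3) {
  model_spec(channels = c(4, 8, 8, 8, 8), n_classes = K, ca_reduction = 2)
}

random_mask <- function(H, W, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:(K - 1), H * W, replace = TRUE), H, W)
}

# brute-force signed distance: double loop over all boundary pixels
brute_signed_distance <- function(mask, k, tau) {
  bp <- boundary_pixels(mask, k)
  H <- nrow(mask); W <- ncol(mask)
  inside <- mask == k
  if (nrow(bp) == 0) {
    return(matrix(if (any(inside)) -tau else tau, H, W))
  }
  d <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      best <- Inf
      for (b in seq_len(nrow(bp))) {
        dist <- sqrt((r - bp[b, 1])^2 + (cc - bp[b, 2])^2)
        if (dist < best) best <- dist
      }
      d[r, cc] <- min(best, tau) * (if (inside[r, cc]) -1 else 1)
    }
  }
  d
}

# layered masks with ordered flat-ish boundaries, for structure tests
layered_mask <- function(H, W, K, seed = 1) {
  set.seed(seed)
  curves <- sort(sample(seq(2, H - 1), K - 1))
  matrix(findInterval(seq_len(H) - 1, curves), H, W)
}

make_loss_fixture <- function(H = 4, W = 5, K = 3, N = 2, seed = 1) {
  set.seed(seed)
  logits <- array(stats::rnorm(H * W * K * N), c(H, W, K, N))
  probs <- exp(logits)
  s <- apply(probs, c(1, 2, 4), sum)
  for (n in seq_len(N)) for (k in seq_len(K)) {
    probs[, , k, n] <- probs[, , k, n] / s[, , n]
  }
  mask <- array(sample(0:(K - 1), H * W * N, TRUE), c(H, W, N))
  list(probs = probs, mask = mask, onehot = onehot_mask(mask, K),
       weights = array(stats::runif(H * W * N, 0.5, 1), c(H, W, N)),
       target = array(stats::runif(H * W * K * N, -1, 1), c(H, W, K, N)))
}

numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Memoized desk-scale recovery study shared by the heavy acceptance blocks.
# Seeds 1..5 run one at a time; once three seeds have passed both the
# recovery bound (Dice >= 0.85, topology violations <= 5%) and the pruning
# bound (Dice drop <= 0.05), a majority of the five is already decided and
# the remaining seeds are skipped.
.recovery_cache <- new.env(parent = emptyenv())

recovery_runs <- function() {
  if (is.null(.recovery_cache$runs)) {
    runs <- list()
    pass8 <- 0L
    pass9 <- 0L
    for (s in 1:5) {
      r <- run_recovery_experiment(s)
      runs[[length(runs) + 1L]] <- r
      pass8 <- pass8 + (r$dice >= 0.85 && r$topology_violation_rate <= 0.05)
      pass9 <- pass9 + (r$dice - r$pruned_dice <= 0.05)
      if (pass8 >= 3L && pass9 >= 3L) break
    }
    .recovery_cache$runs <- runs
  }
  .recovery_cache$runs
}
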