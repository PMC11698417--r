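test_that("weighted cross-entropy matches its closed forms", {
  fx <- make_loss_fixture()
  # perfect one-hot prediction: ~0
  expect_lt(weighted_cross_entropy(fx$onehot, fx$onehot, fx$weights), 1e-5)
  # uniform binary prediction on a 1-pixel image: ln 2
  p <- array(0.5, c(1, 1, 2, 1))
  y <- array(c(1, 0), c(1, 1, 2, 1))
  expect_equal(weighted_cross_entropy(p, y), log(2), tolerance = 1e-6)
  # linear in the weights
  l1 <- weighted_cross_entropy(fx$probs, fx$onehot, fx$weights)
  l2 <- weighted_cross_entropy(fx$probs, fx$onehot, 2 * fx$weights)
  expect_equal(l2, 2 * l1)
  # w == 1 equals the unweighted loss
  expect_equal(weighted_cross_entropy(fx$probs, fx$onehot),
               weighted_cross_entropy(fx$probs, fx$onehot,
                                      fx$weights * 0 + 1))
  expect_error(weighted_cross_entropy(fx$probs, fx$onehot[, , 1:2, ]),
               "shape")
})

test_that("dice loss matches worked cases and bounds", {
  fx <- make_loss_fixture()
  expect_lt(dice_loss(fx$onehot, fx$onehot), 1e-5)
  # disjoint single class contributes 1
  p <- array(0, c(2, 2, 2, 1)); p[1, 1, 1, 1] <- 1; p[, , 2, ][p[, , 2, ] == 0] <- 0
  y <- array(0, c(2, 2, 2, 1)); y[2, 2, 1, 1] <- 1
  # class 1 disjoint -> 1; class 2 absent from both -> sums 0 -> 1 - 0 = 1
  expect_equal(dice_loss(p, y), 2, tolerance = 1e-5)
  # half overlap: y covers 2 pixels, p puts 0.5 on the same 2 pixels
  p2 <- array(0, c(1, 4, 1, 1)); p2[1, 1:2, 1, 1] <- 0.5
  y2 <- array(0, c(1, 4, 1, 1)); y2[1, 1:2, 1, 1] <- 1
  expect_equal(dice_loss(p2, y2), 1 / 3, tolerance = 1e-6)
  d <- dice_loss(fx$probs, fx$onehot)
  expect_gte(d, 0)
  expect_lte(d, dim(fx$probs)[3] * dim(fx$probs)[4])
})

test_that("boundary MSE matches worked cases and is linear in w", {
  fx <- make_loss_fixture()
  expect_equal(boundary_mse(fx$target, fx$target, fx$weights), 0)
  expect_equal(boundary_mse(array(0.5, c(1, 1, 1, 1)),
                            array(0, c(1, 1, 1, 1)),
                            array(1, c(1, 1, 1))), 0.25)
  l1 <- boundary_mse(fx$target * 0.5, fx$target, fx$weights)
  l2 <- boundary_mse(fx$target * 0.5, fx$target, 2 * fx$weights)
  expect_equal(l2, 2 * l1)
  expect_gte(l1, 0)
})

test_that("analytic loss gradients match central finite differences", {
  fx <- make_loss_fixture(H = 3, W = 4, K = 3, N = 2)
  tol <- 1e-4

  tape <- layerseg:::new_tape()
  pn <- layerseg:::nd(tape, fx$probs)
  l <- layerseg:::op_weighted_ce(tape, pn, fx$onehot, fx$weights, 1e-7)
  layerseg:::tape_backward(tape, l)
  g_num <- numeric_gradient(function(p)
    weighted_cross_entropy(p, fx$onehot, fx$weights), fx$probs)
  expect_lt(max(abs(pn$grad - g_num)) / max(abs(g_num)), tol)

  tape <- layerseg:::new_tape()
  pn <- layerseg:::nd(tape, fx$probs)
  l <- layerseg:::op_dice_loss(tape, pn, fx$onehot, 1e-7)
  layerseg:::tape_backward(tape, l)
  g_num <- numeric_gradient(function(p) dice_loss(p, fx$onehot), fx$probs)
  expect_lt(max(abs(pn$grad - g_num)) / max(abs(g_num)), tol)

  pred <- fx$target * 0.3
  tape <- layerseg:::new_tape()
  sn <- layerseg:::nd(tape, pred)
  l <- layerseg:::op_weighted_mse(tape, sn, fx$target, fx$weights)
  layerseg:::tape_backward(tape, l)
  g_num <- numeric_gradient(function(s)
    boundary_mse(s, fx$target, fx$weights), pred)
  expect_lt(max(abs(sn$grad - g_num)) / max(abs(g_num)), tol)
})

test_that("total loss decomposes, honours the weight switch, and vanishes at the optimum", {
  set.seed(3)
  K <- 3
  mask <- layered_mask(8, 8, K, seed = 2)
  target <- tsdf_stack(mask, K, 5)
  probs <- onehot_mask(mask, K)
  noise <- array(stats::runif(8 * 8 * K, 0.1, 0.9), c(8, 8, K, 1))
  noisy <- noise / array(rep(apply(noise, c(1, 2, 4), sum), each = 1),
                         c(8, 8, K, 1))
  for (k in seq_len(K)) noisy[, , k, 1] <- noise[, , k, 1] /
    apply(noise, c(1, 2, 4), sum)[, , 1]
  pred_tsdf <- array(stats::runif(8 * 8 * K, -1, 1), c(8, 8, K, 1))

  # lambda = 0 decouples the boundary term
  cfg0 <- loss_config(lambda_bou = 0)
  r0 <- total_loss(noisy, pred_tsdf, mask, cfg0, target)
  expect_equal(r0$total, r0$ce + r0$dice)

  # adaptive weight off reproduces the unweighted losses
  cfg_off <- loss_config(use_adaptive_weight = FALSE)
  r_off <- total_loss(noisy, pred_tsdf, mask, cfg_off, target)
  expect_true(all(r_off$weights == 1))
  expect_equal(r_off$ce, weighted_cross_entropy(noisy, onehot_mask(mask, K)))

  # weight source switch changes the weights
  r_pred <- total_loss(noisy, pred_tsdf, mask,
                       loss_config(weight_source = "predicted"), target)
  r_gt <- total_loss(noisy, pred_tsdf, mask,
                     loss_config(weight_source = "ground_truth"), target)
  expect_equal(r_gt$weights[, , 1], tsdf_weight_map(target))
  expect_false(isTRUE(all.equal(r_pred$weights, r_gt$weights)))

  # joint optimum: ~0 total
  arr_t <- array(target, c(8, 8, K, 1))
  r_opt <- total_loss(probs, arr_t, mask, loss_config(), arr_t)
  expect_lt(r_opt$total, 1e-4)
})
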