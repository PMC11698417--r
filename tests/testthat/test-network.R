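test_that("channel attention follows the squeeze/excite closed forms", {
  # zero features + zero-initialized dense layers: alpha = sigmoid(0) = 0.5
  z0 <- channel_attention(array(0, c(4, 4, 6)), zero_init = TRUE)
  expect_equal(as.vector(z0$alpha), rep(0.5, 6))
  expect_true(all(z0$output == 0))
  # constant channel value v: descriptor z = max + mean = 2v
  v <- c(0.3, -1, 2)
  x <- array(rep(v, each = 16), c(4, 4, 3))
  zc <- channel_attention(x, r = 1)
  expect_equal(as.vector(zc$z), 2 * v)
  # alpha strictly inside (0, 1)
  set.seed(2)
  zr <- channel_attention(array(stats::rnorm(4 * 4 * 8), c(4, 4, 8)))
  expect_true(all(zr$alpha > 0 & zr$alpha < 1))
})

test_that("attention gate obeys the sigmoid-gated broadcast contract", {
  set.seed(1)
  q <- array(stats::rnorm(8 * 8 * 4), c(8, 8, 4))
  g <- array(stats::rnorm(8 * 8 * 4), c(8, 8, 4))
  res <- attention_gate(q, g)
  expect_equal(dim(res$output), dim(g))
  expect_true(all(res$map > 0 & res$map < 1))
  # zeroed final conv: map = 0.5 everywhere, output = gated / 2
  res0 <- attention_gate(q, g, zero_w3 = TRUE)
  expect_equal(res0$map, matrix(0.5, 8, 8))
  expect_equal(res0$output, 0.5 * g)
  expect_error(attention_gate(q, g[1:4, , ]), "spatial")
})

test_that("fusion block gates both partners and restores the channel count", {
  set.seed(4)
  f <- array(stats::rnorm(8 * 8 * 6), c(8, 8, 6))
  s <- array(stats::rnorm(8 * 8 * 6), c(8, 8, 6))
  b <- array(stats::rnorm(8 * 8 * 6), c(8, 8, 6))
  r <- sadbifb(f, s, b, "segmentation", zero_w3 = TRUE)
  expect_equal(dim(r$output)[3], 6)
  expect_equal(r$gated_f, 0.5 * f)
  expect_equal(r$gated_other, 0.5 * b)
  expect_equal(r$n_gates, 2L)
  rb <- sadbifb(f, s, b, "boundary", zero_w3 = TRUE)
  expect_equal(rb$gated_other, 0.5 * s)
})

test_that("every decoder level of the built model carries four attention gates", {
  m <- build_model(tiny_spec(), seed = 1)
  for (l in 1:4) {
    gate_w3 <- grep(sprintf("^d%d[sb]\\.g[FSB]\\.w3\\.w$", l),
                    names(m$params), value = TRUE)
    expect_length(gate_w3, 4)
  }
})

test_that("residual attention block preserves shape and matches the hand-counted size", {
  x <- array(stats::runif(16 * 16), c(16, 16, 1))
  r <- res_att_block(x, 32, r = 4)
  expect_equal(dim(r$output), c(16, 16, 32))
  expect_true(all(is.finite(r$output)))
  # conv1 3x3x1x32+32, bn1 64, conv2 3x3x32x32+32, bn2 64,
  # CA (8x32+8 + 32x8+32), proj 1x1x1x32+32
  hand <- (288 + 32) + 64 + (9216 + 32) + 64 + (256 + 8 + 256 + 32) + (32 + 32)
  expect_equal(r$n_params, hand)
})

test_that("model forward honours the output contracts and determinism", {
  sp <- tiny_spec(K = 4)
  m <- build_model(sp, seed = 5)
  x <- array(stats::runif(64 * 64), c(64, 64, 1, 1))
  fw <- model_forward(m, x)
  expect_equal(dim(fw$seg), c(64, 64, 4, 1))
  expect_equal(dim(fw$tsdf), c(64, 64, 4, 1))
  sums <- apply(fw$seg[, , , 1], c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  expect_true(all(fw$tsdf > -1 & fw$tsdf < 1))
  # seeded rebuild reproduces outputs exactly
  m2 <- build_model(sp, seed = 5)
  expect_identical(model_forward(m2, x)$seg, fw$seg)
  # non-multiple-of-16 sizes are refused by the raw forward
  expect_error(model_forward(m, array(0, c(30, 64, 1, 1))), "divisible by 16")
  # but handled by predict_model via reflection padding
  pr <- predict_model(m, matrix(stats::runif(30 * 50), 30, 50))
  expect_equal(dim(pr$mask), c(30, 50))
})

test_that("parameter counting matches hand counts and shrinks under pruning", {
  st <- new.env(parent = emptyenv()); st$params <- list()
  layerseg:::mk_conv(st, "c", 1, 2, 3)
  expect_equal(sum(lengths(lapply(st$params, function(p) p$val))), 9)

  m <- build_model(tiny_spec(), seed = 1)
  n0 <- count_parameters(m)
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  plan <- plan_prune(accumulate_importance(m, list(x)), 0.25, min_kept = 2)
  expect_lt(count_parameters(apply_prune(m, plan)), n0)
})

test_that("every parameter receives gradient on a random batch", {
  # realistic widths: with very narrow channel-attention hidden layers a
  # dead ReLU can legitimately zero a block's CA gradients
  sp <- model_spec(n_classes = 3)
  m <- build_model(sp, seed = 1)
  set.seed(2)
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  mask <- array(random_mask(32, 32, 3), c(32, 32, 1))
  onehot <- onehot_mask(mask, 3)
  target <- array(stats::runif(32 * 32 * 3, -1, 1), c(32, 32, 3, 1))
  wts <- array(1, c(32, 32, 1))
  tape <- layerseg:::new_tape()
  fw <- model_forward(m, x, training = TRUE, tape = tape)
  l1 <- layerseg:::op_weighted_ce(tape, fw$nodes$seg, onehot, wts, 1e-7)
  l2 <- layerseg:::op_dice_loss(tape, fw$nodes$seg, onehot, 1e-7)
  l3 <- layerseg:::op_weighted_mse(tape, fw$nodes$tsdf, target, wts)
  tot <- layerseg:::op_scale_add(tape, list(l1, l2, l3), c(1, 1, 1))
  layerseg:::zero_grads(m$params)
  layerseg:::tape_backward(tape, tot)
  dead <- names(m$params)[vapply(m$params, function(p)
    is.null(p$grad) || all(p$grad == 0), logical(1))]
  expect_length(dead, 0)
})
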