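test_that("importance accumulation is additive and order invariant", {
  m <- build_model(tiny_spec(), seed = 2)
  set.seed(1)
  b1 <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  b2 <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  t1 <- accumulate_importance(m, list(b1))
  expect_equal(t1$batches_seen, 1)
  # single batch equals that batch's alpha
  model_forward(m, b1, record_alpha = TRUE)
  expect_equal(t1$scores$enc1, rowSums(m$last_alpha$enc1))
  # duplication doubles every score
  t2 <- accumulate_importance(m, list(b1, b1))
  expect_equal(t2$scores$bott, 2 * t1$scores$bott)
  # order invariance
  t12 <- accumulate_importance(m, list(b1, b2))
  t21 <- accumulate_importance(m, list(b2, b1))
  expect_equal(t12$scores, t21$scores)
  expect_true(all(unlist(t12$scores) >= 0))
  expect_error(accumulate_importance(m, list()), "nonempty")
})

test_that("a zeroed kernel has the minimal channel descriptor on nonnegative input", {
  set.seed(9)
  x <- array(stats::runif(6 * 6 * 5), c(6, 6, 5))
  x[, , 3] <- 0  # emulate a kernel whose output channel is always zero
  z <- channel_attention(x)$z
  expect_equal(which.min(z), 3)
})

test_that("prune planning removes the lowest floor(r*n) scores with index ties", {
  tab <- structure(list(scores = list(conv = c(0.1, 0.9, 0.5, 0.2)),
                        batches_seen = 1), class = "importance_table")
  expect_equal(plan_prune(tab, 0.25, min_kept = 1)$kept$conv, c(2, 3, 4))
  # r = 0: identity plan
  expect_equal(plan_prune(tab, 0)$kept$conv, 1:4)
  # floor arithmetic at n = 32, r = 0.2: 6 removed, 26 kept
  tab32 <- structure(list(scores = list(conv = stats::runif(32)),
                          batches_seen = 1), class = "importance_table")
  expect_length(plan_prune(tab32, 0.2, min_kept = 4)$kept$conv, 26)
  # ties: lower index removed first
  tabt <- structure(list(scores = list(conv = c(0.5, 0.5, 0.5, 0.9)),
                         batches_seen = 1), class = "importance_table")
  expect_equal(plan_prune(tabt, 0.5, min_kept = 1)$kept$conv, c(3, 4))
  expect_error(plan_prune(tab, 1), "r_p")
  expect_error(plan_prune(tab, -0.1), "r_p")
  # min_kept floor
  expect_length(plan_prune(tab, 0.9, min_kept = 3)$kept$conv, 3)
})

test_that("identity surgery (r = 0) reproduces the original network exactly", {
  m <- build_model(tiny_spec(), seed = 3)
  x <- array(stats::runif(32 * 48), c(32, 48, 1, 1))
  plan <- plan_prune(accumulate_importance(m, list(x)), 0)
  p0 <- apply_prune(m, plan)
  f0 <- model_forward(p0, x)
  f1 <- model_forward(m, x)
  expect_equal(f0$seg, f1$seg, tolerance = 1e-12)
  expect_equal(f0$tsdf, f1$tsdf, tolerance = 1e-12)
  expect_equal(count_parameters(p0), count_parameters(m))
})

test_that("pruned network equals the kernel-masked network (dependency closure)", {
  set.seed(11)
  for (trial in 1:3) {
    m <- build_model(tiny_spec(K = 2 + trial), seed = 20 + trial)
    x <- array(stats::runif(32 * 32 * 2), c(32, 32, 1, 2))
    tab <- accumulate_importance(m, list(x))
    # random plans, not just score-driven ones
    plan <- plan_prune(tab, stats::runif(1, 0.1, 0.4), min_kept = 2)
    pruned <- apply_prune(m, plan)
    masked <- mask_pruned_kernels(m, plan)
    fp <- model_forward(pruned, x)
    fm <- model_forward(masked, x)
    expect_lt(max(abs(fp$seg - fm$seg)), 1e-5)
    expect_lt(max(abs(fp$tsdf - fm$tsdf)), 1e-5)
    # architecture consistency: shapes unchanged, params reduced
    expect_equal(dim(fp$seg), dim(fm$seg))
    expect_lt(count_parameters(pruned), count_parameters(m))
  }
})

test_that("inconsistent plans are rejected with the offending layer named", {
  m <- build_model(tiny_spec(), seed = 3)
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  plan <- plan_prune(accumulate_importance(m, list(x)), 0.25, min_kept = 2)
  plan$kept$enc2 <- c(0L, 2L)  # out of range
  expect_error(apply_prune(m, plan), "enc2")
})

test_that("plans and importance tables round-trip through JSON", {
  m <- build_model(tiny_spec(), seed = 12)
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  tab <- accumulate_importance(m, list(x))
  plan <- plan_prune(tab, 0.25, min_kept = 2)
  ft <- tempfile(fileext = ".json"); fp <- tempfile(fileext = ".json")
  write_prune_json(tab, ft)
  write_prune_json(plan, fp)
  tab2 <- read_importance_table(ft)
  plan2 <- read_prune_plan(fp)
  expect_equal(tab2$scores, tab$scores, tolerance = 1e-12)
  expect_equal(tab2$batches_seen, tab$batches_seen)
  expect_equal(plan2$kept, plan$kept)
  expect_equal(plan2$r_p, plan$r_p)
  expect_error(read_prune_plan(ft), "not a prune_plan")
  # a restored plan drives identical surgery
  p1 <- apply_prune(m, plan)
  p2 <- apply_prune(m, plan2)
  expect_equal(model_forward(p1, x)$seg, model_forward(p2, x)$seg)
})

test_that("iterative schedule follows the geometric retention curve", {
  # widths of 16 keep floor(r * n) >= 1 in all five iterations
  sp <- model_spec(channels = rep(16, 5), n_classes = 3)
  m <- build_model(sp, seed = 6)
  data <- synth_samples(4, width = 48, height = 32, K = 3, seed = 5,
                        easy = TRUE)
  cfg <- train_config(epochs = 1, batch_size = 2, crop = NULL,
                      flip_p = 0, brightness_p = 0, contrast_p = 0, seed = 1)
  res <- iterative_prune(m, data, data, r_p = 0.2, n_iters = 5,
                         finetune_epochs = 0, config = cfg, min_kept = 2)
  expect_equal(nrow(res$history), 5)
  expect_true(all(diff(res$history$n_params) < 0))
  # kernel counts ~ n * (1 - r)^i within floor effects
  for (b in layerseg:::PRUNABLE_BLOCKS) {
    n0 <- build_model(sp)$kept_n[b]
    ni <- res$final_model$kept_n[b]
    pred <- n0
    for (i in 1:5) pred <- pred - max(0, min(floor(0.2 * pred), pred - 2))
    expect_equal(unname(ni), unname(pred))
    expect_gte(ni, max(2, floor(n0 * 0.8^5) - 2))
  }
  # no-op schedule keeps the parameter count
  res0 <- iterative_prune(m, data, data, r_p = 0, n_iters = 1,
                          finetune_epochs = 0, config = cfg)
  expect_equal(res0$history$n_params[1], count_parameters(m))
})
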