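test_that("masks and images round-trip through PNG", {
  m <- random_mask(12, 17, 5, seed = 1)
  f <- tempfile(fileext = ".png")
  write_mask(m, f)
  expect_identical(read_mask(f), m)
  expect_error(read_mask(f, K = 3), ">= K")
  img <- matrix(stats::runif(12 * 17), 12, 17)
  fi <- tempfile(fileext = ".png")
  write_image(img, fi)
  back <- read_image(fi)
  expect_lte(max(back), 1)
  expect_lt(max(abs(back - img)), 1 / 255)
  expect_error(read_image(tempfile()), "no such file")
  expect_error(write_mask(matrix(-1, 2, 2), f), "0..255")
})

test_that("tsdf stacks export to multi-page tiff and weights to png", {
  m <- layered_mask(16, 16, 3, seed = 2)
  st <- tsdf_stack(m, 3, 5)
  f <- tempfile(fileext = ".tiff")
  write_tsdf_tiff(st, f)
  back <- read_tsdf_tiff(f)
  expect_equal(dim(back), dim(st))
  expect_equal(back, st, tolerance = 1e-6)
  fw <- tempfile(fileext = ".png")
  write_weight_png(tsdf_weight_map(st), fw)
  expect_true(file.exists(fw))
})

test_that("yaml config reading validates keys and applies defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("train:", "  epochs: 3", "  batch_size: 2",
               "loss:", "  lambda_bou: 0.5"), f)
  cfg <- read_config(f)
  expect_equal(cfg$train$epochs, 3)
  expect_equal(cfg$loss$lambda_bou, 0.5)
  expect_equal(cfg$spec$channels, c(32L, 64L, 128L, 128L, 128L))
  expect_equal(cfg$prune$r_p, 0.2)
  writeLines(c("train:", "  epochs: 3", "  no_such_option: 1"), f)
  expect_warning(read_config(f), "no_such_option")
  expect_warning(read_config(f), "accepted")
})

test_that("checkpoints round-trip a model including pruned bookkeeping", {
  m <- build_model(tiny_spec(), seed = 4)
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  plan <- plan_prune(accumulate_importance(m, list(x)), 0.25, min_kept = 2)
  pm <- apply_prune(m, plan)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(pm, f)
  back <- load_checkpoint(f)
  expect_equal(model_forward(back, x)$seg, model_forward(pm, x)$seg)
  expect_equal(back$kept_n, pm$kept_n)
})

test_that("cli synth writes the expected files and tsdf reproduces the module", {
  out <- file.path(tempdir(), "cli_synth")
  expect_equal(layerseg_cli(c("synth", "--n", "4", "--out", out,
                              "--width", "32", "--height", "32",
                              "--K", "3", "--seed", "2")), 0L)
  expect_length(list.files(out), 9)

  mask <- matrix(c(0L, 0L, 1L, 1L, 1L), 1, 5)
  mf <- file.path(tempdir(), "toy_mask.png")
  write_mask(mask, mf)
  tout <- file.path(tempdir(), "cli_tsdf")
  expect_equal(layerseg_cli(c("tsdf", "--mask", mf, "--tau", "5",
                              "--out", tout)), 0L)
  back <- read_tsdf_tiff(file.path(tout, "tsdf.tiff"))
  st <- tsdf_stack(mask, 2, 5)
  expect_equal(back, st, tolerance = 1e-6)

  expect_equal(layerseg_cli(c("frobnicate")), 1L)
  expect_equal(layerseg_cli(character(0)), 1L)
  unlink(c(out, tout), recursive = TRUE)
})

test_that("predict and eval agree through the cli file formats", {
  m <- build_model(tiny_spec(), seed = 8)
  dir <- file.path(tempdir(), "cli_pred")
  dir.create(dir, showWarnings = FALSE)
  ck <- file.path(dir, "model.rds")
  save_checkpoint(m, ck)
  img <- synth_samples(1, width = 32, height = 32, K = 3, seed = 4)[[1]]
  imf <- file.path(dir, "img.png")
  write_image(img$image, imf)
  expect_equal(layerseg_cli(c("predict", "--image", imf,
                              "--checkpoint", ck, "--out", dir)), 0L)
  pred <- read_mask(file.path(dir, "pred_mask.png"))
  direct <- predict_model(m, read_image(imf))$mask
  expect_identical(pred, direct)
  unlink(dir, recursive = TRUE)
})
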