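# layerseg

Segmentation of ordered tissue layers in cross-sectional grayscale images —
the shape of the problem posed by retinal OCT B-scans, where bands such as
NFL, IPL, ONL and RPE stack vertically and their interfaces must be traced
pixel by pixel.  Plain encoder–decoder segmentation struggles exactly where
it matters: interfaces with weak intensity contrast, and small annotated
datasets that invite overfitting.

`layerseg` implements a dual-branch answer to both problems:

* **Dual-task network.**  A residual U-Net with channel attention in every
  block, one shared encoder and two decoders: one segments, the other
  regresses a per-class *truncated signed distance function* (TSDF)

  `d(x) = ∓ min(dist(x, ∂Ω_k), τ)`  (negative inside class k, τ = 5 px),

  normalized to [−1, 1].  Spatial attention gates fuse the encoder skip and
  both branches at every decoder level (four gates per level), so boundary
  features sharpen the segmentation and vice versa.

* **Entropy-weighted loss.**  Where the two largest TSDF channels nearly
  tie — boundaries and misclassified regions — the base-2 entropy of their
  two-way softmax `w(x) = −(p₁log p₁ + p₂log p₂)/log 2` approaches 1.
  This weight, computed from the predicted TSDF outside the gradient path,
  multiplies the cross-entropy and boundary-MSE terms of
  `L = L_ce + L_dice + λ·L_bou`.

* **Attention-scored structured pruning.**  The channel-attention vectors
  double as kernel-importance scores: summed over batches, sorted
  ascending, the bottom r% of kernels per convolution are cut, surviving
  weights are transferred into the rebuilt smaller network, and a short
  fine-tune follows — iterated five times with the best checkpoint kept.

A synthetic layered-image generator (smooth non-crossing interfaces,
per-layer reflectivity, noise, weak-contrast bands, bumps) makes the whole
pipeline testable at desk scale without any clinical data.

## Worked example

```r
library(layerseg)

# 16 synthetic B-scan-like images, 5 classes (background + 4 layers)
train <- synth_samples(16, width = 256, height = 128, K = 5, seed = 1, easy = TRUE)
test  <- synth_samples(4,  width = 256, height = 128, K = 5, seed = 2, easy = TRUE)

# TSDF stack and entropy weights for one mask
stack <- tsdf_stack(train[[1]]$mask, K = 5, tau = 5)
range(stack)                       # -1 1
w <- tsdf_weight_map(stack)
max(w)                             # 1 (at boundaries, where the top-2 tie)

# train a small dual-branch model
spec <- model_spec(channels = c(8, 16, 32, 32, 32), n_classes = 5)
cfg  <- train_config(epochs = 6, batch_size = 2, lr_start = 3e-3,
                     lr_end = 3e-5, crop = c(128, 48), vflip_p = 0,
                     brightness_p = 0, contrast_p = 0, seed = 1)
model <- build_model(spec, seed = 1)
fit   <- train_model(model, train, cfg)
evaluate_model(fit$model, test)[c("mean_dice", "topology_violation_rate")]
#> $mean_dice
#> [1] 0.983296
#> $topology_violation_rate
#> [1] 0.0078125

# prune 20% of the kernels per convolution and transfer the weights
imp    <- accumulate_importance(fit$model, lapply(train[1:8], `[[`, "image"))
plan   <- plan_prune(imp, r_p = 0.2)
pruned <- apply_prune(fit$model, plan)
c(before = count_parameters(fit$model), after = count_parameters(pruned))
#>  before   after
#>  298036  267772
```

Held-out mean Dice (background excluded) and the fraction of predicted
columns whose class sequence breaks the anatomical layer order; the pruned
model keeps the architecture's contracts (same output shapes, ~10 % fewer
parameters at this small width) and is masking-equivalent to zeroing the
cut kernels in place.  Longer desk-scale training (12 epochs on 64 images,
as in `run_recovery_experiment()`) reaches Dice ≈ 0.999 with zero topology
violations.

A command-line interface wraps the same functions
(`inst/cli/layerseg synth|tsdf|train|prune|eval|predict`).

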