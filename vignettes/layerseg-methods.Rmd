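---
title: "Layered-tissue segmentation with signed-distance boundary regression and attention-guided pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered-tissue segmentation with signed-distance boundary regression and attention-guided pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cross-sectional images of layered tissue — retinal OCT B-scans are the
motivating case — show a stack of vertically ordered bands (NFL through RPE
in the retina) whose interfaces must be delineated pixel by pixel.  Two
things make this hard for plain encoder–decoder segmentation: interfaces
with weak intensity contrast, where cross-entropy training happily trades a
few boundary pixels away, and small labelled datasets, which invite
overfitting.  `layerseg` implements a dual-task answer to both: a second
decoder regresses a signed-distance representation of every class boundary,
and a channel-attention mechanism doubles as a kernel-importance measure
for structured pruning.

## Model

The network is a residual U-Net with one shared encoder and two decoders.
Encoder and decoders are built from *residual channel-attention blocks*:

    conv 3x3 -> batchnorm -> relu -> conv 3x3 -> batchnorm ->
    channel attention -> (+ 1x1-projected input) -> relu

Channel attention squeezes each channel to a scalar descriptor
`z_c = max(X_c) + mean(X_c)` and excites through two dense layers,
`alpha = sigmoid(W2 relu(W1 z))`, with compression ratio `r = 4`.  The
residual projection is always a 1x1 convolution, also when input and output
widths agree; this makes pruning surgery well defined for every block
output without tying kept-kernel sets across layers.  The channel plan is
`[32, 64, 128, 128, 128]` (four encoder levels plus bottleneck) with a
mirrored decoder plan; 2x2 max pooling connects encoder levels and
bilinear x2 upsampling the decoder levels, so input sizes must be divisible
by 16 (prediction on other sizes reflection-pads and crops back).

At each decoder level the segmentation features `S_i`, boundary features
`B_i` and encoder skip `F_i` are fused by a block using spatial attention
gates, two per branch (four per level).  A gate computes
`map = sigmoid(w3 relu(w1 query + w2 gated))` with 1x1 convolutions
(`C -> C/2 -> 1`) and multiplies the gated features by the map.  The
segmentation branch queries with `S_i`, gates `F_i` and `B_i`, concatenates
`[S_i, gated F_i, gated B_i]` and reduces back to `C` channels with a 3x3
convolution; the boundary branch is symmetric.  Because the upsampled
deeper features carry the deeper level's width, a 1x1 projection aligns
them to the level width before fusion; the first decoder level of both
branches starts from the shared bottleneck.  The segmentation head ends in
a channel softmax, the boundary head in `tanh` since its targets live in
`[-1, 1]`.

## Boundary supervision

For class `k` with region `Omega_k` and boundary pixels `dOmega_k` (pixels
of the class with a 4-neighbor of another class; image borders alone do not
count), the truncated signed distance is

    d(x) = -min(dist(x, dOmega_k), tau)   inside,
           +min(dist(x, dOmega_k), tau)   outside,

with exact Euclidean distances (a two-pass exact distance transform; the
test suite checks it against a brute-force double loop).  Each map is
normalized by its global maximum absolute value, giving values in
`[-1, 1]`; a class absent from the image gets the constant `+tau`, a class
filling it `-tau`, so every channel remains a well-defined regression
target.  The truncation default is `tau = 5` pixels.

Near boundaries — and wherever the network has not learned the topology —
the two largest channels of the TSDF stack nearly tie.  The adaptive weight
exploits this: with `p1 = softmax` of the two largest channel values
(`p1 = exp(d1) / (exp(d1) + exp(d2))`), the weight is the base-2 entropy

    w(x) = -(p1 log p1 + p2 log p2) / log 2,

equal to 1 exactly at ties and decreasing monotonically in the gap.  By
default the weight is computed from the *predicted* TSDF and detached from
the gradient, so it highlights currently-misclassified regions; a
ground-truth source is available as a configuration switch.

The objective is `L = Lce + Ldice + lambda * Lbou`: per-pixel-averaged
weighted cross-entropy, Dice loss summed over classes and images, and the
weighted mean-squared error between predicted and target TSDF.  `lambda`
defaults to 1 (a neutral choice; the two tasks share the loss scale).  `N` is taken as the
number of images in a batch so each term is a batch mean; `epsilon = 1e-7`
stabilizes logs and Dice denominators.  The same weight map multiplies the
cross-entropy and the boundary MSE; the Dice term is unweighted.

## Pruning

After pre-training, each forward pass's attention vectors `alpha` are
summed over all batches (fixed order, no augmentation) to score every
kernel of every CA-bearing convolution — the second convolution of each of
the 13 residual blocks, which defines a block's output width.  One depth
group is one convolution: per group the `floor(r_p * n)` lowest-scoring
kernels are removed (ties: lower index first), never going below
`min_kept = 4` (2 in the smallest test models).  `r_p` applies to the
*current* kernel count, so five iterations at 20 % retain about
`0.8^5 = 33 %` of the original kernels rather than removing everything.

Surgery rebuilds the model at the reduced widths and copies every surviving
parameter: conv kernels and biases, batch-norm affine parameters and
running statistics, matching rows/columns of the attention matrices (the
hidden width is kept), residual projection rows, and the input channels of
every consumer — the next block, the encoder-skip gates, the concatenation
segments of the fusion convolutions, the upsample projections, and the
heads.  The correctness oracle, enforced in the tests, is masking
equivalence: zeroing a to-be-pruned kernel's weights, bias, batch-norm
affine and projection rows in the original network reproduces the pruned
network's outputs exactly.  The iterative schedule
(prune → fine-tune, five rounds, best-validation-Dice checkpoint kept)
scales down to desk size a full protocol of 100 pre-training epochs and
20 fine-tuning epochs.

## Synthetic data

Because the clinical datasets are external, the generator produces the
structure the method needs: `K - 1` smooth non-crossing interface curves
(low-frequency sinusoids plus smoothed noise, projected to a minimum
one-pixel gap), background above the first curve and the deepest layer
extending to the bottom edge, per-class mean intensities with additive
Gaussian noise, optional multiplicative speckle, column bands of reduced
contrast ("weak boundaries"), and occasional localized bumps.  Layer
intensities follow a fixed alternating bright/dark profile across a dataset
with small per-image jitter — layered tissue has characteristic per-band
reflectivity, and a learnable appearance is what makes desk-scale recovery
experiments meaningful.  What the generator does **not** emulate: real
speckle statistics, pathology such as fluid pockets, layer terminations, or
annotation noise.  Passing the recovery tests therefore demonstrates that
the pipeline can learn ordered-layer topology from consistent appearance,
not clinical-grade accuracy.

Every mask satisfies the column grammar (optional background, strictly
increasing tissue indices, optional trailing background), which the
evaluation module turns into a diagnostic: the fraction of predicted
columns violating that grammar.

## Desk-scale choices

The full training recipe (five-fold cross-validation, 256x256 crops,
flips and photometric jitter at probability 0.5, Adam with cosine annealing
5e-4 → 5e-6, weight decay 1e-5, batch 8, 100 epochs) is the package
default.  The bundled experiments run a deliberately small configuration,
chosen once while designing the study and used by the tests and the
reproduction script:

* 64 training and 8 held-out images of 128 x 256, `K = 5`, high contrast
  (noise sigma 0.03, no weak regions);
* channels `[8, 16, 32, 32, 32]`, 12 epochs, batch 2, cosine 3e-3 → 3e-5;
* full-height 128 x 48 crops — crops that cut the layer stack vertically
  remove the depth context the topology depends on, which measurably
  degrades column-topology cleanliness;
* horizontal flips only, no photometric jitter: brightness shifts of the
  default ±20 % are comparable to the synthetic inter-layer contrast and
  would destroy the intensity cue the small model must rely on (vertical
  flips likewise fight the depth prior; on real data with batch-scale
  training all of these augmentations are appropriate, and they remain the
  defaults);
* one prune iteration at `r_p = 0.2` scored on 16 images, two fine-tuning
  epochs at 3e-4.

## Numerical notes

* Exact-zero ReLU inputs take the subgradient 0; with zero-initialized
  biases a freshly built very narrow model can contain an entirely dead
  block, which is why the channel-attention hidden bias is initialized at
  0.1 and the gradient-flow test runs at realistic widths.
* Batch-norm uses biased batch variance, momentum 0.1, `eps = 1e-5`;
  running statistics are carried through pruning surgery.
* `top2` breaks ties toward the lower class index, making weight maps
  deterministic.
* The distance transform returns `+Inf` for an empty site set; the TSDF
  layer never sees that case because empty/full classes short-circuit to
  the `±tau` convention.
* Bilinear upsampling uses half-pixel-centre alignment; its adjoint is the
  exact transpose, which the gradient checks exercise.

## Limitations

The autodiff engine and kernels are sized for desk-scale experiments
(single CPU, minutes); they are not a general deep-learning framework.
Training at clinical scale (hundreds of 256x512 images, 100 epochs) is out
of reach of this implementation and of the synthetic scope: clinical-grade
Dice/IoU values are not claimed here.  The residual-block internals admit
several layouts, so the default plan's parameter count (~4.7 M) should be
read as characteristic of the architecture family, not canonical.
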