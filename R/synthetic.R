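#' Sample smooth, ordered layer-boundary curves
#'
#' Draws `K - 1` non-crossing boundary curves across the image width, each a
#' sum of low-frequency sinusoids plus smoothed Gaussian noise.  Curves are
#' projected to keep a minimum vertical gap of one pixel at every column and
#' to stay strictly inside `(0, height)`, emulating the ordered interfaces of
#' layered tissue in a flattened B-scan.
#'
#' @param width,height Image size in pixels (both at least 16).
#' @param K Number of classes including background (at least 2); `K - 1`
#'   curves are returned.
#' @param smoothness Amplitude scale (pixels) of the sinusoidal undulation;
#'   larger values give wavier interfaces.
#' @param seed Integer seed; the same seed reproduces identical curves.
#' @param n_bumps Number of localized bumps/depressions added to randomly
#'   chosen curves (0 disables).
#' @return A `(K - 1) x width` matrix; row `j` is the row coordinate of the
#'   interface above layer `j`, strictly increasing with `j` at every column.
#' @export
sample_boundaries <- function(width, height, K, smoothness = 4, seed = NULL,
                              n_bumps = 0L) {
  if (K < 2) stop("K must be >= 2 (got ", K, ")")
  if (width < 16 || height < 16) {
    stop("image too small: width and height must both be >= 16 (got ",
         width, "x", height, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  n_curves <- K - 1L
  margin <- max(2, 0.08 * height)
  base <- seq(margin, height - margin, length.out = n_curves + 1L)[seq_len(n_curves)]
  base <- base + diff(c(base, height - margin))[1] / 2
  xs <- seq_len(width) / width
  curves <- matrix(0, n_curves, width)
  for (j in seq_len(n_curves)) {
    y <- base[j]
    for (h in 1:3) {
      amp <- smoothness * stats::runif(1, 0.2, 1) / h
      y <- y + amp * sin(2 * pi * (h * stats::runif(1, 0.5, 1.5) * xs +
                                     stats::runif(1)))
    }
    noise <- stats::rnorm(width, sd = smoothness / 4)
    y <- y + as.numeric(stats::filter(noise, rep(1 / 15, 15), circular = TRUE))
    curves[j, ] <- y
  }
  if (n_bumps > 0) {
    for (b in seq_len(n_bumps)) {
      j <- sample.int(n_curves, 1)
      ctr <- stats::runif(1, 0.1, 0.9) * width
      wid <- stats::runif(1, 0.03, 0.1) * width
      amp <- stats::runif(1, -1.5, 1.5) * smoothness
      curves[j, ] <- curves[j, ] + amp * exp(-((seq_len(width) - ctr)^2) /
                                               (2 * wid^2))
    }
  }
  # enforce strict ordering with a >= 1 pixel gap, then keep inside (0, height)
  for (j in seq_len(n_curves)[-1]) {
    curves[j, ] <- pmax(curves[j, ], curves[j - 1, ] + 1)
  }
  lo <- min(curves); hi <- max(curves)
  if (lo < 1 || hi > height - 1) {
    span_lo <- min(lo, 1)
    span_hi <- max(hi, height - 1)
    curves <- 1 + (curves - span_lo) * (height - 2) / (span_hi - span_lo)
  }
  curves
}

#' Construct a layered-scene description
#'
#' Bundles everything needed to render one synthetic B-scan-like image:
#' boundary curves, per-class mean intensities, additive Gaussian noise level
#' and optional low-contrast ("weak boundary") column ranges.
#'
#' @param width,height Canvas size in pixels.
#' @param boundaries `(K - 1) x width` matrix of ordered interface rows, as
#'   from [sample_boundaries()].
#' @param intensities Numeric vector of `K` mean gray levels in `[0, 1]`;
#'   entry 1 is the background.
#' @param noise_sigma Standard deviation of additive Gaussian noise (>= 0).
#' @param weak_regions List of `c(col_start, col_end, contrast_scale)`
#'   triples; within those columns every adjacent-class intensity difference
#'   is multiplied by `contrast_scale` in `[0, 1]`.
#' @param speckle If `TRUE`, multiplies the clean image by unit-mean
#'   multiplicative noise before the additive term (OCT speckle is
#'   multiplicative; off by default).
#' @param seed Integer seed for the rendering noise.
#' @return An object of class `layer_scene`.
#' @export
layer_scene <- function(width, height, boundaries, intensities,
                        noise_sigma = 0.05, weak_regions = list(),
                        speckle = FALSE, seed = NULL) {
  K <- length(intensities)
  if (!is.matrix(boundaries) || nrow(boundaries) != K - 1 ||
      ncol(boundaries) != width) {
    stop("boundaries must be a (K-1) x width matrix")
  }
  if (nrow(boundaries) > 1 &&
      any(apply(boundaries, 2, function(col) any(diff(col) <= 0)))) {
    stop("boundaries must be strictly ordered at every column")
  }
  if (any(boundaries <= 0) || any(boundaries >= height)) {
    stop("all curve values must lie in (0, height)")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(width = width, height = height, boundaries = boundaries,
                 intensities = intensities, noise_sigma = noise_sigma,
                 weak_regions = weak_regions, speckle = speckle, seed = seed),
            class = "layer_scene")
}

#' Render a scene into an image and label mask
#'
#' The mask assigns row `r`, column `c` to class `j` when
#' `curve[j] <= r + 1 < curve[j + 1]` (1-based rows; background above the
#' first curve, and the deepest layer extends to the bottom edge).  The image
#' is the per-class mean intensity plus Gaussian noise; inside weak regions
#' the contrast between adjacent classes is scaled down.
#'
#' @param scene A [layer_scene()] object.
#' @return A list with `image` (`height x width` matrix in `[0, 1]` before
#'   noise clamping) and `mask` (`height x width` integer matrix with values
#'   `0 .. K-1`).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "layer_scene"))
  H <- scene$height; W <- scene$width
  K <- length(scene$intensities)
  if (!is.null(scene$seed)) set.seed(scene$seed)
  mask <- matrix(0L, H, W)
  rows <- seq_len(H)  # pixel r occupies row coordinate r (1-based)
  for (cc in seq_len(W)) {
    cuts <- scene$boundaries[, cc]
    # class j occupies 0-based rows r with cuts[j] <= r < cuts[j+1];
    # the deepest layer extends to the bottom edge
    mask[, cc] <- as.integer(findInterval(rows - 1, cuts))
  }
  img <- matrix(0, H, W)
  base_int <- scene$intensities
  for (cc in seq_len(W)) {
    ints <- base_int
    for (wr in scene$weak_regions) {
      if (cc >= wr[1] && cc <= wr[2]) {
        ints <- mean(ints) + (ints - mean(ints)) * wr[3]
      }
    }
    img[, cc] <- ints[mask[, cc] + 1L]
  }
  if (isTRUE(scene$speckle)) {
    img <- img * matrix(stats::rnorm(H * W, 1, 0.15), H, W)
  }
  if (scene$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, scene$noise_sigma), H, W)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` image/mask PNG pairs plus a CSV manifest.  Scene
#' parameters are drawn independently per image from the supplied ranges;
#' per-image seeds are derived from `seed` so regeneration is byte-identical.
#'
#' @param n_images Number of image/mask pairs.
#' @param out_dir Output directory (created if missing).
#' @param width,height Canvas size (defaults 256 x 128 for desk-scale work).
#' @param K Number of classes including background.
#' @param smoothness Boundary undulation amplitude in pixels.
#' @param intensity_range Range of tissue-layer mean intensities; layer means
#'   are evenly spaced inside it with small per-image jitter.
#' @param background_intensity Mean gray level of the background class.
#' @param noise_sigma Additive noise level.
#' @param weak_prob Probability that an image contains one weak-boundary
#'   column band (contrast scale drawn from `weak_contrast`).
#' @param weak_contrast Range of the contrast scale inside weak regions.
#' @param n_bumps Localized bumps per image passed to [sample_boundaries()].
#' @param seed Master seed.
#' @return Invisibly, the manifest data frame (`path_image`, `path_mask`,
#'   `K`, `seed`).
#' @export
make_dataset <- function(n_images, out_dir, width = 256, height = 128, K = 5,
                         smoothness = 4, intensity_range = c(0.35, 0.95),
                         background_intensity = 0.08, noise_sigma = 0.05,
                         weak_prob = 0.3, weak_contrast = c(0.2, 0.6),
                         n_bumps = 1L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  set.seed(seed)
  img_seeds <- sample.int(.Machine$integer.max / 2, n_images)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    s <- img_seeds[i]
    set.seed(s)
    bseed <- sample.int(.Machine$integer.max / 2, 1)
    curves <- sample_boundaries(width, height, K, smoothness, seed = bseed,
                                n_bumps = n_bumps)
    # each anatomical layer keeps a characteristic reflectivity across the
    # dataset (alternating bright/dark bands), plus small per-image jitter
    layer_means <- seq(intensity_range[1], intensity_range[2],
                       length.out = K - 1)
    nl <- K - 1L
    alt <- order(c(seq(1, nl, by = 2), seq(2, nl, by = 2)))
    ints <- c(background_intensity, layer_means[alt]) +
      stats::rnorm(K, 0, 0.01)
    ints <- pmin(pmax(ints, 0), 1)
    weak <- list()
    if (stats::runif(1) < weak_prob) {
      c0 <- sample.int(width - 16, 1)
      weak <- list(c(c0, min(width, c0 + sample(10:40, 1)),
                     stats::runif(1, weak_contrast[1], weak_contrast[2])))
    }
    scene <- layer_scene(width, height, curves, ints,
                         noise_sigma = noise_sigma, weak_regions = weak,
                         seed = s + 1L)
    r <- render_scene(scene)
    pi_ <- file.path(out_dir, sprintf("img_%03d.png", i))
    pm_ <- file.path(out_dir, sprintf("mask_%03d.png", i))
    write_image(r$image, pi_)
    write_mask(r$mask, pm_)
    rows[[i]] <- data.frame(path_image = pi_, path_mask = pm_, K = K,
                            seed = s, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Generate an in-memory synthetic dataset
#'
#' Like [make_dataset()] but returns a list of samples without touching disk;
#' used by the training and evaluation helpers.
#'
#' @inheritParams make_dataset
#' @param easy If `TRUE`, uses high-contrast defaults (no weak regions,
#'   low noise) suitable for quick parameter-recovery experiments.
#' @return List of `n_images` samples, each `list(image, mask)`.
#' @export
synth_samples <- function(n_images, width = 256, height = 128, K = 5,
                          seed = 1L, easy = FALSE, ...) {
  args <- list(...)
  if (easy) {
    args$noise_sigma <- args$noise_sigma %||% 0.03
    args$weak_prob <- args$weak_prob %||% 0
    args$n_bumps <- args$n_bumps %||% 0L
    args$smoothness <- args$smoothness %||% 3
  }
  td <- tempfile("synth")
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  manifest <- do.call(make_dataset,
                      c(list(n_images = n_images, out_dir = td, width = width,
                             height = height, K = K, seed = seed), args))
  lapply(seq_len(n_images), function(i) {
    list(image = read_image(manifest$path_image[i]),
         mask = read_mask(manifest$path_mask[i]))
  })
}
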