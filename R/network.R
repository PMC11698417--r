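# Dual-branch residual channel-attention encoder-decoder.
#
# Shared encoder (4 levels + bottleneck, 2x2 max pool between levels), two
# decoders (segmentation / boundary regression) whose levels upsample
# bilinearly, fuse the encoder skip and both branches through spatial
# attention gates (four gates per level), and finish with a residual
# channel-attention block.  Heads: 1x1 conv to K channels with channel
# softmax (segmentation) or tanh (TSDF regression).
#
# Arrays are (H, W, C, N); input H and W must be divisible by 16.

PRUNABLE_BLOCKS <- c("enc1", "enc2", "enc3", "enc4", "bott",
                     "d4s", "d3s", "d2s", "d1s",
                     "d4b", "d3b", "d2b", "d1b")

#' Model specification
#'
#' @param channels Five positive counts: four encoder levels + bottleneck.
#'   The decoder mirrors the encoder plan.
#' @param n_classes Number of output classes K (background included).
#' @param ca_reduction Channel-attention compression ratio r; the hidden
#'   width is `max(1, floor(channels/r))`.
#' @param kernel_size Spatial kernel size of the 3x3-style convolutions.
#' @param in_channels Input image channels (1 for grayscale).
#' @return A `model_spec` list.
#' @export
model_spec <- function(channels = c(32, 64, 128, 128, 128), n_classes = 5,
                       ca_reduction = 4, kernel_size = 3, in_channels = 1) {
  if (length(channels) != 5 || any(channels < 1)) {
    stop("channels must be 5 positive counts")
  }
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  structure(list(channels = as.integer(channels),
                 n_classes = as.integer(n_classes),
                 ca_reduction = as.integer(ca_reduction),
                 kernel_size = as.integer(kernel_size),
                 in_channels = as.integer(in_channels)),
            class = "model_spec")
}

he_weights <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

mk_param <- function(model, name, val) {
  model$params[[name]] <- param_node(val)
  invisible(NULL)
}

mk_conv <- function(model, name, k, cin, cout) {
  mk_param(model, paste0(name, ".w"), he_weights(k, k, cin, cout))
  mk_param(model, paste0(name, ".b"), numeric(cout))
}

mk_bn <- function(model, name, C) {
  mk_param(model, paste0(name, ".g"), rep(1, C))
  mk_param(model, paste0(name, ".b"), numeric(C))
  model$bn[[name]] <- new_bn_state(C)
}

mk_ca <- function(model, name, c_plan, c_in, r) {
  h <- max(1L, c_plan %/% r)
  mk_param(model, paste0(name, ".w1"),
           matrix(stats::rnorm(h * c_in, 0, sqrt(2 / c_in)), h, c_in))
  # small positive bias keeps the narrow hidden ReLU from going dead
  mk_param(model, paste0(name, ".b1"), rep(0.1, h))
  mk_param(model, paste0(name, ".w2"),
           matrix(stats::rnorm(c_in * h, 0, sqrt(2 / h)), c_in, h))
  mk_param(model, paste0(name, ".b2"), numeric(c_in))
}

mk_block <- function(model, pfx, cin, c_plan, n_out, r, k) {
  mk_conv(model, paste0(pfx, ".conv1"), k, cin, c_plan)
  mk_bn(model, paste0(pfx, ".bn1"), c_plan)
  mk_conv(model, paste0(pfx, ".conv2"), k, c_plan, n_out)
  mk_bn(model, paste0(pfx, ".bn2"), n_out)
  mk_ca(model, paste0(pfx, ".ca"), c_plan, n_out, r)
  mk_conv(model, paste0(pfx, ".proj"), 1, cin, n_out)
}

mk_gate <- function(model, name, cq, cg, c_plan) {
  h <- max(1L, c_plan %/% 2L)
  mk_conv(model, paste0(name, ".w1"), 1, cq, h)
  mk_conv(model, paste0(name, ".w2"), 1, cg, h)
  mk_conv(model, paste0(name, ".w3"), 1, h, 1)
}

#' Build the dual-branch model
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling the (He) initialization; a fixed seed
#'   reproduces identical parameters and hence identical forward outputs.
#' @param kept Optional named list (per prunable block) of kernel counts to
#'   build a pruned architecture; used internally by [apply_prune()].
#' @return A `layerseg_model` environment holding parameters, batch-norm
#'   state and bookkeeping.
#' @export
build_model <- function(spec, seed = NULL, kept = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  ch <- spec$channels
  r <- spec$ca_reduction
  k <- spec$kernel_size
  model <- new.env(parent = emptyenv())
  model$spec <- spec
  model$params <- list()
  model$bn <- list()
  model$plan <- c(enc1 = ch[1], enc2 = ch[2], enc3 = ch[3], enc4 = ch[4],
                  bott = ch[5],
                  d4s = ch[4], d3s = ch[3], d2s = ch[2], d1s = ch[1],
                  d4b = ch[4], d3b = ch[3], d2b = ch[2], d1b = ch[1])
  if (is.null(kept)) {
    kept <- as.list(model$plan)
  }
  model$kept_n <- vapply(PRUNABLE_BLOCKS, function(b) as.integer(kept[[b]]),
                         integer(1))
  kn <- model$kept_n
  # encoder
  mk_block(model, "enc1", spec$in_channels, ch[1], kn["enc1"], r, k)
  mk_block(model, "enc2", kn["enc1"], ch[2], kn["enc2"], r, k)
  mk_block(model, "enc3", kn["enc2"], ch[3], kn["enc3"], r, k)
  mk_block(model, "enc4", kn["enc3"], ch[4], kn["enc4"], r, k)
  mk_block(model, "bott", kn["enc4"], ch[5], kn["bott"], r, k)
  # decoders
  for (l in 4:1) {
    c_l <- ch[l]
    enc_w <- kn[paste0("enc", l)]
    for (br in c("s", "b")) {
      pfx <- paste0("d", l, br)
      deeper <- if (l == 4) kn["bott"] else kn[paste0("d", l + 1, br)]
      mk_conv(model, paste0(pfx, ".up"), 1, deeper, c_l)
      other <- if (br == "s") "B" else "S"
      mk_gate(model, paste0(pfx, ".gF"), c_l, enc_w, c_l)
      mk_gate(model, paste0(pfx, ".g", other), c_l, c_l, c_l)
      mk_conv(model, paste0(pfx, ".fuse"), k, c_l + enc_w + c_l, c_l)
      mk_bn(model, paste0(pfx, ".fusebn"), c_l)
      mk_block(model, pfx, c_l, c_l, kn[pfx], r, k)
    }
  }
  mk_conv(model, "head_s", 1, kn["d1s"], spec$n_classes)
  mk_conv(model, "head_b", 1, kn["d1b"], spec$n_classes)
  class(model) <- "layerseg_model"
  model
}

p_ <- function(model, name) {
  p <- model$params[[name]]
  if (is.null(p)) stop("unknown parameter: ", name)
  p
}

fwd_conv <- function(model, tape, name, x) {
  op_conv(tape, x, p_(model, paste0(name, ".w")), p_(model, paste0(name, ".b")))
}

fwd_bn <- function(model, tape, name, x, training) {
  op_batchnorm(tape, x, p_(model, paste0(name, ".g")),
               p_(model, paste0(name, ".b")), model$bn[[name]], training)
}

fwd_ca <- function(model, tape, name, x, record_into = NULL) {
  z <- op_gmaxmean(tape, x)
  a1 <- op_relu(tape, op_addbias_mat(
    tape, op_matmul(tape, p_(model, paste0(name, ".w1")), z),
    p_(model, paste0(name, ".b1"))))
  alpha <- op_sigmoid(tape, op_addbias_mat(
    tape, op_matmul(tape, p_(model, paste0(name, ".w2")), a1),
    p_(model, paste0(name, ".b2"))))
  if (!is.null(record_into)) model$last_alpha[[record_into]] <- alpha$val
  list(out = op_mul_channel(tape, x, alpha), alpha = alpha)
}

fwd_block <- function(model, tape, pfx, x, training, record = FALSE) {
  h <- op_relu(tape, fwd_bn(model, tape, paste0(pfx, ".bn1"),
                            fwd_conv(model, tape, paste0(pfx, ".conv1"), x),
                            training))
  h <- fwd_bn(model, tape, paste0(pfx, ".bn2"),
              fwd_conv(model, tape, paste0(pfx, ".conv2"), h), training)
  ca <- fwd_ca(model, tape, paste0(pfx, ".ca"), h,
               record_into = if (record) pfx else NULL)
  res <- fwd_conv(model, tape, paste0(pfx, ".proj"), x)
  op_relu(tape, op_add(tape, ca$out, res))
}

fwd_gate <- function(model, tape, name, query, gated) {
  s <- op_add(tape, fwd_conv(model, tape, paste0(name, ".w1"), query),
              fwd_conv(model, tape, paste0(name, ".w2"), gated))
  map <- op_sigmoid(tape, fwd_conv(model, tape, paste0(name, ".w3"),
                                   op_relu(tape, s)))
  list(out = op_mul_spatial(tape, gated, map), map = map)
}

#' Forward pass of the dual-branch model
#'
#' @param model A [build_model()] result.
#' @param x Input: `H x W` matrix or `H x W x C x N` array; `H` and `W` must
#'   be divisible by 16.
#' @param training Use batch statistics (and update the running ones) in the
#'   batch-norm layers.
#' @param tape Optional autodiff tape; supplied internally during training.
#' @param record_alpha Store every channel-attention vector of this pass in
#'   `model$last_alpha` (used by importance accumulation).
#' @return List with `seg` (`H x W x K x N` probabilities summing to 1 over
#'   classes), `tsdf` (`H x W x K x N` in `(-1, 1)`), and the output `nodes`
#'   when a tape is supplied.
#' @export
model_forward <- function(model, x, training = FALSE, tape = NULL,
                          record_alpha = FALSE) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L, 1L))
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
    stop("input height and width must be divisible by 16 (got ",
         d[1], "x", d[2], "); pad the image or use predict_model()")
  }
  if (record_alpha) model$last_alpha <- list()
  own_tape <- is.null(tape)
  if (own_tape) tape <- new_tape()
  xin <- nd(tape, x)
  e1 <- fwd_block(model, tape, "enc1", xin, training, record_alpha)
  e2 <- fwd_block(model, tape, "enc2", op_maxpool(tape, e1), training, record_alpha)
  e3 <- fwd_block(model, tape, "enc3", op_maxpool(tape, e2), training, record_alpha)
  e4 <- fwd_block(model, tape, "enc4", op_maxpool(tape, e3), training, record_alpha)
  bt <- fwd_block(model, tape, "bott", op_maxpool(tape, e4), training, record_alpha)
  skips <- list(e1, e2, e3, e4)
  deeper <- list(s = bt, b = bt)
  for (l in 4:1) {
    Fi <- skips[[l]]
    q <- list()
    for (br in c("s", "b")) {
      pfx <- paste0("d", l, br)
      q[[br]] <- fwd_conv(model, tape, paste0(pfx, ".up"),
                          op_upsample(tape, deeper[[br]]))
    }
    nxt <- list()
    for (br in c("s", "b")) {
      pfx <- paste0("d", l, br)
      other <- if (br == "s") "b" else "s"
      gF <- fwd_gate(model, tape, paste0(pfx, ".gF"), q[[br]], Fi)
      gO <- fwd_gate(model, tape, paste0(pfx, ".g", toupper(other)),
                     q[[br]], q[[other]])
      cat <- op_concat_c(tape, list(q[[br]], gF$out, gO$out))
      fused <- op_relu(tape, fwd_bn(model, tape, paste0(pfx, ".fusebn"),
                                    fwd_conv(model, tape, paste0(pfx, ".fuse"),
                                             cat), training))
      nxt[[br]] <- fwd_block(model, tape, pfx, fused, training, record_alpha)
    }
    deeper <- nxt
  }
  seg <- op_softmax_c(tape, fwd_conv(model, tape, "head_s", deeper$s))
  tsd <- op_tanh(tape, fwd_conv(model, tape, "head_b", deeper$b))
  list(seg = seg$val, tsdf = tsd$val,
       nodes = list(seg = seg, tsdf = tsd), tape = tape)
}

#' Count trainable parameters
#'
#' @param model A `layerseg_model`.
#' @return Total number of trainable scalars (batch-norm running statistics
#'   excluded).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$val), numeric(1)))
}

# ---- standalone functional units (single-image convenience wrappers) ----

as_hwcn <- function(x) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}

#' Channel attention on a feature map
#'
#' Squeeze (global max + global mean per channel), excite (two dense layers
#' with ReLU then sigmoid), and reweight the channels.
#'
#' @param features `H x W x C` (or `H x W x C x N`) array.
#' @param r Compression ratio.
#' @param seed Seed for the dense-layer initialization.
#' @param zero_init Use all-zero dense weights and biases (so every attention
#'   weight is exactly `sigmoid(0) = 0.5`).
#' @return List with `alpha` (`C x N` matrix in `(0, 1)`) and `output` (same
#'   shape as the input).
#' @export
channel_attention <- function(features, r = 4, seed = 1, zero_init = FALSE) {
  x <- as_hwcn(features)
  C <- dim(x)[3]
  h <- max(1L, C %/% r)
  if (C %/% r < 1) {
    warning("ca_reduction exceeds channel count; using hidden width 1")
  }
  set.seed(seed)
  w1 <- matrix(stats::rnorm(h * C, 0, sqrt(2 / C)), h, C)
  w2 <- matrix(stats::rnorm(C * h, 0, sqrt(2 / h)), C, h)
  if (zero_init) { w1[] <- 0; w2[] <- 0 }
  tape <- new_tape()
  xn <- nd(tape, x)
  z <- op_gmaxmean(tape, xn)
  a <- op_sigmoid(tape, op_addbias_mat(
    tape, op_matmul(tape, param_node(w2),
                    op_relu(tape, op_addbias_mat(
                      tape, op_matmul(tape, param_node(w1), z),
                      param_node(numeric(h))))),
    param_node(numeric(C))))
  out <- op_mul_channel(tape, xn, a)
  res <- out$val
  if (length(dim(features)) < 4) dim(res) <- dim(x)[1:3]
  list(alpha = a$val, output = res, z = z$val)
}

#' Spatial attention gate
#'
#' `map = sigmoid(w3 relu(w1 query + w2 gated))`, applied multiplicatively to
#' the gated features (`w1`, `w2`: 1x1 convolutions to C/2 channels; `w3`:
#' 1x1 convolution to one channel).
#'
#' @param query,gated `H x W x C` (or batched) arrays of equal spatial size.
#' @param seed Seed for the 1x1-convolution initialization.
#' @param zero_w3 Zero the final convolution so the map is exactly 0.5
#'   everywhere.
#' @return List with `map` (`H x W` matrix in `(0, 1)` for single-image
#'   input) and `output` (same shape as `gated`).
#' @export
attention_gate <- function(query, gated, seed = 1, zero_w3 = FALSE) {
  q <- as_hwcn(query); g <- as_hwcn(gated)
  if (!identical(dim(q)[c(1, 2, 4)], dim(g)[c(1, 2, 4)])) {
    stop("query and gated must share spatial size and batch size")
  }
  cq <- dim(q)[3]; cg <- dim(g)[3]
  h <- max(1L, cq %/% 2L)
  set.seed(seed)
  model <- new.env(parent = emptyenv()); model$params <- list()
  mk_conv(model, "gate.w1", 1, cq, h)
  mk_conv(model, "gate.w2", 1, cg, h)
  mk_conv(model, "gate.w3", 1, h, 1)
  if (zero_w3) {
    model$params[["gate.w3.w"]]$val[] <- 0
    model$params[["gate.w3.b"]]$val[] <- 0
  }
  tape <- new_tape()
  res <- fwd_gate(model, tape, "gate", nd(tape, q), nd(tape, g))
  out <- res$out$val
  map <- res$map$val
  if (length(dim(gated)) < 4) {
    dim(out) <- dim(g)[1:3]
    map <- matrix(map, dim(g)[1], dim(g)[2])
  }
  list(map = map, output = out)
}

#' Residual channel-attention block (standalone)
#'
#' conv -> batchnorm -> relu -> conv -> batchnorm -> channel attention ->
#' add 1x1-projected input -> relu.
#'
#' @param x `H x W x C` (or batched) input features.
#' @param out_channels Output channel count.
#' @param r Channel-attention compression ratio.
#' @param kernel_size Convolution kernel size.
#' @param seed Initialization seed.
#' @return List with `output` and `n_params` (trainable scalars in the
#'   block).
#' @export
res_att_block <- function(x, out_channels, r = 4, kernel_size = 3, seed = 1) {
  xa <- as_hwcn(x)
  set.seed(seed)
  model <- new.env(parent = emptyenv())
  model$params <- list(); model$bn <- list(); model$last_alpha <- list()
  mk_block(model, "blk", dim(xa)[3], out_channels, out_channels, r,
           kernel_size)
  tape <- new_tape()
  out <- fwd_block(model, tape, "blk", nd(tape, xa), training = FALSE)
  res <- out$val
  if (length(dim(x)) < 4) dim(res) <- dim(res)[1:3]
  list(output = res,
       n_params = sum(vapply(model$params, function(p) length(p$val),
                             numeric(1))))
}

#' Dual-branch information fusion (standalone)
#'
#' For the segmentation branch: gate the encoder skip `F_i` and the boundary
#' features `B_i` with the branch's own features `S_i` as query (two spatial
#' attention gates), concatenate `[query, gated F, gated other]`, and reduce
#' back to C channels with a 3x3 convolution + batchnorm + ReLU.  The
#' boundary branch is symmetric with `B_i` as query.
#'
#' @param f_i,s_i,b_i `H x W x C` (or batched) arrays with a common shape.
#' @param branch `"segmentation"` or `"boundary"`.
#' @param seed Initialization seed.
#' @param zero_w3 Zero the gates' final convolutions (maps become 0.5).
#' @return List with `output` (C channels), `gated_f`, `gated_other`, and
#'   `n_gates` (always 2 per branch).
#' @export
sadbifb <- function(f_i, s_i, b_i, branch = c("segmentation", "boundary"),
                    seed = 1, zero_w3 = FALSE) {
  branch <- match.arg(branch)
  fa <- as_hwcn(f_i); sa <- as_hwcn(s_i); ba <- as_hwcn(b_i)
  if (!identical(dim(fa), dim(sa)) || !identical(dim(fa), dim(ba))) {
    stop("F_i, S_i and B_i must share channel count and spatial size")
  }
  C <- dim(fa)[3]
  set.seed(seed)
  model <- new.env(parent = emptyenv())
  model$params <- list(); model$bn <- list()
  mk_gate(model, "gF", C, C, C)
  mk_gate(model, "gO", C, C, C)
  mk_conv(model, "fuse", 3, 3 * C, C)
  mk_bn(model, "fusebn", C)
  if (zero_w3) {
    for (nm in c("gF.w3.w", "gF.w3.b", "gO.w3.w", "gO.w3.b")) {
      model$params[[nm]]$val[] <- 0
    }
  }
  q <- if (branch == "segmentation") sa else ba
  o <- if (branch == "segmentation") ba else sa
  tape <- new_tape()
  qn <- nd(tape, q); fn <- nd(tape, fa); on_ <- nd(tape, o)
  gF <- fwd_gate(model, tape, "gF", qn, fn)
  gO <- fwd_gate(model, tape, "gO", qn, on_)
  cat <- op_concat_c(tape, list(qn, gF$out, gO$out))
  fused <- op_relu(tape, fwd_bn(model, tape, "fusebn",
                                fwd_conv(model, tape, "fuse", cat),
                                training = FALSE))
  res <- fused$val
  gf <- gF$out$val; go <- gO$out$val
  if (length(dim(f_i)) < 4) {
    dim(res) <- dim(res)[1:3]; dim(gf) <- dim(gf)[1:3]; dim(go) <- dim(go)[1:3]
  }
  list(output = res, gated_f = gf, gated_other = go, n_gates = 2L)
}
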