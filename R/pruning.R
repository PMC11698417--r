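# Channel-attention-guided structured pruning: kernel importance is the sum
# of the attention weights alpha over batches; the lowest-scoring kernels of
# each convolution (depth group) are removed and the surviving weights are
# transferred into a rebuilt, smaller architecture.

#' Accumulate kernel-importance scores
#'
#' Runs the model in inference mode over the given batches and, for every
#' channel-attention layer, sums the attention vector alpha over all batches
#' and images.  Importance is a pure sum, so it is invariant to batch order
#' and additive under dataset duplication.
#'
#' @param model A `layerseg_model`.
#' @param batches List of input arrays (`H x W x C x N` or `H x W`
#'   matrices).
#' @return An `importance_table`: list with `scores` (named list, one
#'   non-negative vector per prunable convolution) and `batches_seen`.
#' @export
accumulate_importance <- function(model, batches) {
  if (length(batches) == 0) stop("dataset must be nonempty")
  scores <- lapply(PRUNABLE_BLOCKS, function(b) numeric(model$kept_n[b]))
  names(scores) <- PRUNABLE_BLOCKS
  for (batch in batches) {
    model_forward(model, batch, training = FALSE, record_alpha = TRUE)
    for (b in PRUNABLE_BLOCKS) {
      scores[[b]] <- scores[[b]] + rowSums(model$last_alpha[[b]])
    }
  }
  structure(list(scores = scores, batches_seen = length(batches)),
            class = "importance_table")
}

#' Plan a structured prune
#'
#' Per convolution (one depth group each), removes the `floor(r_p * n)`
#' lowest-scoring kernels — ties broken by removing the lower index first —
#' while never keeping fewer than `min_kept`.
#'
#' @param table An [accumulate_importance()] result.
#' @param r_p Fraction to remove, in `[0, 1)`.
#' @param min_kept Minimum kernels retained per convolution.
#' @return A `prune_plan`: named list of strictly increasing kept indices.
#' @export
plan_prune <- function(table, r_p, min_kept = 4) {
  if (r_p < 0 || r_p >= 1) stop("r_p must be in [0, 1)")
  kept <- lapply(table$scores, function(s) {
    n <- length(s)
    n_rm <- min(floor(r_p * n), max(0L, n - min_kept))
    if (n_rm == 0) return(seq_len(n))
    rm_idx <- order(s, seq_along(s))[seq_len(n_rm)]
    sort(setdiff(seq_len(n), rm_idx))
  })
  structure(list(kept = kept, r_p = r_p, min_kept = min_kept),
            class = "prune_plan")
}

slice_out <- function(v, idx) {
  # slice the output-kernel (4th) dimension of a conv weight
  v[, , , idx, drop = FALSE]
}

slice_in <- function(v, idx) {
  v[, , idx, , drop = FALSE]
}

#' Apply a prune plan with weight transfer
#'
#' Rebuilds the model with reduced kernel counts and copies every surviving
#' parameter from the original: convolution kernels and biases, batch-norm
#' affine parameters and running statistics, the matching rows/columns of the
#' channel-attention matrices, the residual projections, and the input
#' channels of every downstream consumer (following the dependency graph
#' through pools, skips, gates, concatenations and both decoder branches).
#'
#' @param model The trained `layerseg_model`.
#' @param plan A [plan_prune()] result (kept indices relative to the current
#'   kernel counts).
#' @return A new, smaller `layerseg_model`.
#' @export
apply_prune <- function(model, plan) {
  kept <- plan$kept
  for (b in PRUNABLE_BLOCKS) {
    n <- model$kept_n[b]
    k <- kept[[b]]
    if (is.null(k)) stop("plan is missing block ", b)
    if (length(k) == 0 || any(k < 1 | k > n) || is.unsorted(k, strictly = TRUE)) {
      stop("inconsistent prune plan at block ", b)
    }
  }
  new_n <- lapply(kept, length)
  pruned <- build_model(model$spec, kept = new_n)
  op <- model$params
  np <- pruned$params
  set_p <- function(name, val) { np[[name]]$val <- val; invisible(NULL) }
  g <- function(name) op[[name]]$val
  ch <- model$spec$channels
  # per-block surgery: output side + input side
  in_kept <- list(enc1 = NULL, enc2 = kept$enc1, enc3 = kept$enc2,
                  enc4 = kept$enc3, bott = kept$enc4)
  for (b in PRUNABLE_BLOCKS) {
    S <- kept[[b]]
    ik <- in_kept[[b]]  # NULL means input space unpruned
    w1 <- g(paste0(b, ".conv1.w"))
    if (!is.null(ik)) w1 <- slice_in(w1, ik)
    set_p(paste0(b, ".conv1.w"), w1)
    set_p(paste0(b, ".conv1.b"), g(paste0(b, ".conv1.b")))
    set_p(paste0(b, ".bn1.g"), g(paste0(b, ".bn1.g")))
    set_p(paste0(b, ".bn1.b"), g(paste0(b, ".bn1.b")))
    pruned$bn[[paste0(b, ".bn1")]]$rm <- model$bn[[paste0(b, ".bn1")]]$rm
    pruned$bn[[paste0(b, ".bn1")]]$rv <- model$bn[[paste0(b, ".bn1")]]$rv
    set_p(paste0(b, ".conv2.w"), slice_out(g(paste0(b, ".conv2.w")), S))
    set_p(paste0(b, ".conv2.b"), g(paste0(b, ".conv2.b"))[S])
    set_p(paste0(b, ".bn2.g"), g(paste0(b, ".bn2.g"))[S])
    set_p(paste0(b, ".bn2.b"), g(paste0(b, ".bn2.b"))[S])
    pruned$bn[[paste0(b, ".bn2")]]$rm <- model$bn[[paste0(b, ".bn2")]]$rm[S]
    pruned$bn[[paste0(b, ".bn2")]]$rv <- model$bn[[paste0(b, ".bn2")]]$rv[S]
    set_p(paste0(b, ".ca.w1"), g(paste0(b, ".ca.w1"))[, S, drop = FALSE])
    set_p(paste0(b, ".ca.b1"), g(paste0(b, ".ca.b1")))
    set_p(paste0(b, ".ca.w2"), g(paste0(b, ".ca.w2"))[S, , drop = FALSE])
    set_p(paste0(b, ".ca.b2"), g(paste0(b, ".ca.b2"))[S])
    pw <- slice_out(g(paste0(b, ".proj.w")), S)
    if (!is.null(ik)) pw <- slice_in(pw, ik)
    set_p(paste0(b, ".proj.w"), pw)
    set_p(paste0(b, ".proj.b"), g(paste0(b, ".proj.b"))[S])
  }
  # decoder-level consumers
  for (l in 4:1) {
    c_l <- ch[l]
    encb <- paste0("enc", l)
    kF <- kept[[encb]]
    nF_old <- model$kept_n[encb]
    for (br in c("s", "b")) {
      pfx <- paste0("d", l, br)
      deeper <- if (l == 4) "bott" else paste0("d", l + 1, br)
      set_p(paste0(pfx, ".up.w"), slice_in(g(paste0(pfx, ".up.w")),
                                           kept[[deeper]]))
      set_p(paste0(pfx, ".up.b"), g(paste0(pfx, ".up.b")))
      other <- if (br == "s") "B" else "S"
      # gate on encoder skip: slice gated-input channels
      set_p(paste0(pfx, ".gF.w2.w"), slice_in(g(paste0(pfx, ".gF.w2.w")), kF))
      for (nm in c("gF.w1.w", "gF.w1.b", "gF.w2.b", "gF.w3.w", "gF.w3.b")) {
        set_p(paste0(pfx, ".", nm), g(paste0(pfx, ".", nm)))
      }
      for (nm in paste0("g", other, c(".w1.w", ".w1.b", ".w2.w", ".w2.b",
                                      ".w3.w", ".w3.b"))) {
        set_p(paste0(pfx, ".", nm), g(paste0(pfx, ".", nm)))
      }
      # fusion conv input: [query (c_l), gated F (enc kept), gated other (c_l)]
      fuse_in <- c(seq_len(c_l), c_l + kF, c_l + nF_old + seq_len(c_l))
      set_p(paste0(pfx, ".fuse.w"), slice_in(g(paste0(pfx, ".fuse.w")),
                                             fuse_in))
      set_p(paste0(pfx, ".fuse.b"), g(paste0(pfx, ".fuse.b")))
      set_p(paste0(pfx, ".fusebn.g"), g(paste0(pfx, ".fusebn.g")))
      set_p(paste0(pfx, ".fusebn.b"), g(paste0(pfx, ".fusebn.b")))
      pruned$bn[[paste0(pfx, ".fusebn")]]$rm <- model$bn[[paste0(pfx, ".fusebn")]]$rm
      pruned$bn[[paste0(pfx, ".fusebn")]]$rv <- model$bn[[paste0(pfx, ".fusebn")]]$rv
    }
  }
  set_p("head_s.w", slice_in(g("head_s.w"), kept$d1s))
  set_p("head_s.b", g("head_s.b"))
  set_p("head_b.w", slice_in(g("head_b.w"), kept$d1b))
  set_p("head_b.b", g("head_b.b"))
  pruned
}

#' Mask kernels in place (pruning-equivalence reference)
#'
#' Zeroes the weights, bias, batch-norm affine parameters, and residual
#' projection rows of the kernels a plan would remove, leaving the
#' architecture unchanged.  The masked model's forward pass equals the
#' pruned model's output, which is the correctness oracle for
#' [apply_prune()].
#'
#' @inheritParams apply_prune
#' @return A deep-copied, masked `layerseg_model`.
#' @export
mask_pruned_kernels <- function(model, plan) {
  masked <- clone_model(model)
  for (b in PRUNABLE_BLOCKS) {
    rm_idx <- setdiff(seq_len(masked$kept_n[b]), plan$kept[[b]])
    if (length(rm_idx) == 0) next
    masked$params[[paste0(b, ".conv2.w")]]$val[, , , rm_idx] <- 0
    masked$params[[paste0(b, ".conv2.b")]]$val[rm_idx] <- 0
    masked$params[[paste0(b, ".bn2.g")]]$val[rm_idx] <- 0
    masked$params[[paste0(b, ".bn2.b")]]$val[rm_idx] <- 0
    masked$params[[paste0(b, ".proj.w")]]$val[, , , rm_idx] <- 0
    masked$params[[paste0(b, ".proj.b")]]$val[rm_idx] <- 0
  }
  masked
}

#' Deep-copy a model
#'
#' @param model A `layerseg_model`.
#' @return An independent copy (parameters and batch-norm state detached).
#' @export
clone_model <- function(model) {
  out <- build_model(model$spec, kept = as.list(model$kept_n))
  for (nm in names(model$params)) out$params[[nm]]$val <- model$params[[nm]]$val
  for (nm in names(model$bn)) {
    out$bn[[nm]]$rm <- model$bn[[nm]]$rm
    out$bn[[nm]]$rv <- model$bn[[nm]]$rv
  }
  out
}

#' Serialize / restore prune plans and importance tables as JSON
#'
#' @param x A `prune_plan` or `importance_table`.
#' @param path JSON file path.
#' @return `write_prune_json()` returns the path invisibly;
#'   `read_prune_plan()` / `read_importance_table()` rebuild the objects.
#' @export
write_prune_json <- function(x, path) {
  stopifnot(inherits(x, c("prune_plan", "importance_table")))
  obj <- unclass(x)
  obj$.class <- class(x)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prune_json
#' @export
read_prune_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$.class, "prune_plan")) stop("not a prune_plan file")
  structure(list(kept = lapply(obj$kept, as.integer),
                 r_p = obj$r_p, min_kept = obj$min_kept),
            class = "prune_plan")
}

#' @rdname write_prune_json
#' @export
read_importance_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$.class, "importance_table")) {
    stop("not an importance_table file")
  }
  structure(list(scores = lapply(obj$scores, as.numeric),
                 batches_seen = as.integer(obj$batches_seen)),
            class = "importance_table")
}

#' Iterative prune / fine-tune schedule
#'
#' Starting from a pre-trained model, repeats `n_iters` times: accumulate
#' importance on the training inputs, plan a prune of `r_p` of the *current*
#' kernels per convolution, apply it with weight transfer, and fine-tune.
#' Returns the checkpoint with the best validation mean Dice across
#' iterations together with the per-iteration history.
#'
#' @param model Pre-trained `layerseg_model`.
#' @param train_data,val_data Lists of samples (`list(image, mask)`).
#' @param r_p Per-iteration prune fraction in `[0, 1)`.
#' @param n_iters Number of prune/fine-tune rounds.
#' @param finetune_epochs Epochs of fine-tuning after each prune.
#' @param config A [train_config()] for the fine-tuning runs.
#' @param min_kept Minimum kernels kept per convolution.
#' @return List with `model` (best checkpoint), `history` (data frame:
#'   iteration, n_params, val_dice), and `final_model` (after the last
#'   iteration).
#' @export
iterative_prune <- function(model, train_data, val_data, r_p, n_iters = 5,
                            finetune_epochs = 20, config = train_config(),
                            min_kept = 4) {
  history <- vector("list", n_iters)
  best <- NULL
  best_dice <- -Inf
  current <- model
  # fixed data order, no augmentation, for reproducible importance scores
  imp_batches <- lapply(train_data, function(s) s$image)
  cfg <- config
  cfg$epochs <- finetune_epochs
  for (it in seq_len(n_iters)) {
    tab <- accumulate_importance(current, imp_batches)
    plan <- plan_prune(tab, r_p, min_kept)
    current <- apply_prune(current, plan)
    if (finetune_epochs > 0) {
      fit <- train_model(current, train_data, cfg)
      current <- fit$model
    }
    vd <- evaluate_model(current, val_data)$mean_dice
    history[[it]] <- data.frame(iteration = it,
                                n_params = count_parameters(current),
                                val_dice = vd)
    if (vd > best_dice) {
      best_dice <- vd
      best <- clone_model(current)
    }
  }
  list(model = best, history = do.call(rbind, history), final_model = current)
}
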