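#' Encoder configuration
#'
#' Topology of the shared state-space encoder and the three task branches.
#' The shared encoder is a patch embedding followed by `n_shared_blocks`
#' VSS (visual state-space) blocks at constant resolution; each task branch
#' is one VSS block followed by `branch_stages - 1` downsample-plus-VSS
#' stages, doubling the channel width at each downsample. The defaults
#' (4 shared blocks, 4 branch stages) reproduce the reference topology;
#' widths are explicit configuration.
#'
#' @param patch_h,patch_w patch dimensions for the embedding (default 4 x 4).
#' @param embed_dim channel width after patch embedding.
#' @param n_shared_blocks number of shared VSS blocks (default 4).
#' @param branch_stages branch depth (default 4: one plain block, then three
#'   downsample+block units; final width is `8 * embed_dim`).
#' @param state_dim latent state size N of the selective scan.
#' @param expansion inner-width multiplier of each VSS block.
#' @param block_variant `"ss2d"` (four directional selective scans; the
#'   reference semantics) or `"lite"` (depthwise-separable convolution mixer
#'   with the same outer contract; fast CPU testing only).
#' @param init_seed integer; fixes every random parameter draw.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(patch_h = 4L, patch_w = 4L, embed_dim = 32L,
                           n_shared_blocks = 4L, branch_stages = 4L,
                           state_dim = 8L, expansion = 2L,
                           block_variant = c("ss2d", "lite"),
                           init_seed = 0L) {
  block_variant <- match.arg(block_variant)
  stopifnot(patch_h >= 1, patch_w >= 1, embed_dim >= 1,
            n_shared_blocks >= 1, branch_stages >= 1, state_dim >= 1,
            expansion >= 1)
  structure(list(patch_h = as.integer(patch_h), patch_w = as.integer(patch_w),
                 embed_dim = as.integer(embed_dim),
                 n_shared_blocks = as.integer(n_shared_blocks),
                 branch_stages = as.integer(branch_stages),
                 state_dim = as.integer(state_dim),
                 expansion = as.integer(expansion),
                 block_variant = block_variant,
                 init_seed = as.integer(init_seed)),
            class = "encoder_config")
}

#' Build a multi-task decoder model
#'
#' Initializes all parameters of the shared encoder, the requested task
#' branches (any subset of V, A, D), the per-branch classifier heads and the
#' per-branch feature heads. Projections use truncated-normal init (sd 0.02);
#' every block's output projection starts at zero so each block begins as the
#' identity map. `cfg$init_seed` makes initialization fully deterministic.
#'
#' @param cfg an [encoder_config()].
#' @param d_f feature-head embedding width (used by the coupling losses).
#' @param branches character subset of `c("V", "A", "D")`.
#' @return An object of class `eegcouple_model`.
#' @export
build_model <- function(cfg, d_f = 64L, branches = c("V", "A", "D")) {
  stopifnot(inherits(cfg, "encoder_config"), all(branches %in% c("V", "A", "D")))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$init_seed)
  E <- cfg$embed_dim
  init_branch <- function() {
    blocks <- list(init_vss_block(E, cfg$state_dim, cfg$expansion,
                                  cfg$block_variant))
    dim_cur <- E
    for (s in seq_len(cfg$branch_stages - 1L)) {
      blocks <- c(blocks, list(init_downsample(dim_cur)))
      dim_cur <- 2L * dim_cur
      blocks <- c(blocks, list(init_vss_block(dim_cur, cfg$state_dim,
                                              cfg$expansion, cfg$block_variant)))
    }
    list(blocks = blocks,
         cls = init_classifier_head(dim_cur),
         feat = init_feature_head(dim_cur, d_f))
  }
  params <- list(
    patch = init_patch_embed(cfg$patch_h, cfg$patch_w, E),
    shared = lapply(seq_len(cfg$n_shared_blocks), function(i)
      init_vss_block(E, cfg$state_dim, cfg$expansion, cfg$block_variant)),
    branch = setNames(lapply(branches, function(b) init_branch()), branches))
  structure(list(params = params, encoder = cfg, d_f = as.integer(d_f),
                 branches = branches),
            class = "eegcouple_model")
}

#' @export
print.eegcouple_model <- function(x, ...) {
  cat("<eegcouple_model>", x$encoder$block_variant, "blocks | embed",
      x$encoder$embed_dim, "| state", x$encoder$state_dim, "| branches",
      paste(x$branches, collapse = ""), "| d_f", x$d_f, "|",
      format(n_parameters(x), big.mark = ","), "parameters\n")
  invisible(x)
}

#' Count model parameters
#' @param model an `eegcouple_model`.
#' @return Integer number of scalar parameters.
#' @export
n_parameters <- function(model) {
  cnt <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) cnt <<- cnt + length(x)
    invisible(NULL)
  }
  walk(model$params)
  cnt
}

# Full forward pass. x: [B, channels, samples]. Returns predictions,
# embeddings and (optionally) all caches needed for the backward pass.
model_forward <- function(model, x, want_cache = FALSE) {
  p <- model$params; cfg <- model$encoder
  pe <- patch_embed_fwd(p$patch, x, cfg$patch_h, cfg$patch_w)
  h <- pe$y
  sh_caches <- vector("list", length(p$shared))
  for (i in seq_along(p$shared)) {
    r <- vss_fwd(p$shared[[i]], h)
    h <- r$y
    if (want_cache) sh_caches[[i]] <- r$cache
  }
  F_sh <- h
  out <- list(F_sh = F_sh, P = NULL, logits = NULL, f = list(),
              caches = NULL)
  P <- matrix(NA_real_, dim(x)[1], length(model$branches))
  logits <- P
  colnames(P) <- model$branches; colnames(logits) <- model$branches
  br_caches <- list()
  for (j in seq_along(model$branches)) {
    bname <- model$branches[j]
    bp <- p$branch[[bname]]
    hb <- F_sh
    bcaches <- vector("list", length(bp$blocks))
    for (i in seq_along(bp$blocks)) {
      blk <- bp$blocks[[i]]
      if (!is.null(attr(blk, "variant"))) {
        r <- vss_fwd(blk, hb)
      } else {
        r <- downsample_fwd(blk, hb)
      }
      hb <- r$y
      if (want_cache) bcaches[[i]] <- r$cache
    }
    cl <- classifier_head_fwd(bp$cls, hb)
    ft <- feature_head_fwd(bp$feat, hb)
    P[, j] <- cl$P; logits[, j] <- cl$logit
    out$f[[bname]] <- ft$f
    if (want_cache)
      br_caches[[bname]] <- list(blocks = bcaches, cls = cl$cache,
                                 feat = ft$cache, F_j = hb)
  }
  out$P <- P; out$logits <- logits
  if (want_cache) out$caches <- list(patch = pe$cache, shared = sh_caches,
                                     branch = br_caches)
  out
}

# Backward pass: dlogits [B, n_branches], df named list of [B, d_f].
# Returns a gradient tree mirroring model$params.
model_backward <- function(model, fwd, dlogits, df) {
  p <- model$params; ca <- fwd$caches
  grads <- list(patch = NULL, shared = vector("list", length(p$shared)),
                branch = list())
  dF_sh <- 0
  for (j in seq_along(model$branches)) {
    bname <- model$branches[j]
    bp <- p$branch[[bname]]; bca <- ca$branch[[bname]]
    cl <- classifier_head_bwd(bp$cls, bca$cls, dlogits[, j])
    dhb <- cl$dx
    gb <- list(cls = cl$grads)
    if (!is.null(df[[bname]])) {
      ft <- feature_head_bwd(bp$feat, bca$feat, df[[bname]])
      dhb <- dhb + ft$dx
      gb$feat <- ft$grads
    } else {
      gb$feat <- zero_like(bp$feat)
    }
    gblocks <- vector("list", length(bp$blocks))
    for (i in rev(seq_along(bp$blocks))) {
      blk <- bp$blocks[[i]]
      if (!is.null(attr(blk, "variant"))) {
        r <- vss_bwd(blk, bca$blocks[[i]], dhb)
        dhb <- r$dx; gblocks[[i]] <- r$grads
      } else {
        r <- downsample_bwd(blk, bca$blocks[[i]], dhb)
        dhb <- r$dx; gblocks[[i]] <- list(dW = r$dW, db = r$db)
      }
    }
    gb$blocks <- gblocks
    grads$branch[[bname]] <- gb
    dF_sh <- dF_sh + dhb
  }
  dh <- dF_sh
  for (i in rev(seq_along(p$shared))) {
    r <- vss_bwd(p$shared[[i]], ca$shared[[i]], dh)
    dh <- r$dx; grads$shared[[i]] <- r$grads
  }
  grads$patch <- patch_embed_bwd(p$patch, ca$patch, dh)
  grads
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like)
  else if (is.numeric(x)) { y <- x; y[] <- 0; y }
  else x
}

#' Run the shared encoder
#'
#' Patch embedding followed by the stacked shared VSS blocks (no
#' downsampling): produces the unified representation consumed by all task
#' branches.
#'
#' @param model an `eegcouple_model` from [build_model()].
#' @param x numeric array, batch x channels x samples (a batch of segments).
#' @return Token-grid array batch x grid_h x grid_w x embed_dim.
#' @export
shared_encode <- function(model, x) {
  p <- model$params; cfg <- model$encoder
  h <- patch_embed_fwd(p$patch, x, cfg$patch_h, cfg$patch_w)$y
  for (blk in p$shared) h <- vss_fwd(blk, h)$y
  h
}

#' Run one task branch encoder
#'
#' One VSS block, then the configured downsample+VSS stages, starting from
#' the shared representation. The three branches share this structure but
#' hold independent parameters.
#'
#' @param model an `eegcouple_model`.
#' @param F_sh token grid from [shared_encode()].
#' @param branch `"V"`, `"A"` or `"D"`.
#' @return The branch's final token grid.
#' @export
task_encode <- function(model, F_sh, branch = c("V", "A", "D")) {
  branch <- match.arg(branch)
  bp <- model$params$branch[[branch]]
  if (is.null(bp)) stop("model has no branch ", branch)
  h <- F_sh
  for (blk in bp$blocks) {
    h <- if (!is.null(attr(blk, "variant"))) vss_fwd(blk, h)$y
         else downsample_fwd(blk, h)$y
  }
  h
}

#' Patch-embed a batch of segments
#' @param model an `eegcouple_model`.
#' @param x array batch x channels x samples.
#' @return Token grid batch x ceil(channels/patch_h) x ceil(samples/patch_w)
#'   x embed_dim; trailing-edge zero padding is applied when the dims do not
#'   divide evenly.
#' @export
patch_embed <- function(model, x) {
  cfg <- model$encoder
  patch_embed_fwd(model$params$patch, x, cfg$patch_h, cfg$patch_w)$y
}

#' Apply one VSS block
#'
#' Shape-preserving token mixer: layer norm, gated linear expansion,
#' depthwise convolution + SiLU, four directional selective-scan recurrences
#' over the token grid (summed, normalized, gated), and a residual output
#' projection. The `lite` variant replaces the scans with a depthwise
#' separable convolution under the same outer contract.
#'
#' @param params block parameters (e.g. `model$params$shared[[1]]`).
#' @param grid token-grid array batch x H x W x C.
#' @return Token grid of identical shape.
#' @export
vss_block <- function(params, grid) vss_fwd(params, grid)$y

#' 2x2 patch-merging downsample
#'
#' Concatenates each 2x2 token neighborhood (zero-padding odd trailing edges)
#' and linearly projects to twice the channel width; grid dims halve
#' (ceiling).
#'
#' @param params downsample parameters (from a branch's block list).
#' @param grid token grid batch x H x W x C.
#' @return Token grid batch x ceil(H/2) x ceil(W/2) x 2C.
#' @export
downsample <- function(params, grid) downsample_fwd(params, grid)$y

#' Branch feature head
#'
#' Layer norm, global average pooling over the token grid, and a linear
#' reduction to the embedding used by the coupling losses. Not part of the
#' classification path.
#'
#' @param params feature-head parameters (e.g. `model$params$branch$V$feat`).
#' @param grid branch token grid.
#' @return Matrix batch x d_f of embeddings.
#' @export
feature_head <- function(params, grid) feature_head_fwd(params, grid)$f

#' Branch classifier head
#'
#' Layer norm, adaptive average pooling to 1x1, flatten, a fully connected
#' layer to one logit, and a sigmoid clamped to (1e-7, 1 - 1e-7).
#'
#' @param params classifier parameters (e.g. `model$params$branch$V$cls`).
#' @param grid branch token grid.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
classifier_head <- function(params, grid) classifier_head_fwd(params, grid)$P

#' Predict on a segment set
#'
#' @param model a trained `eegcouple_model`.
#' @param segs a [segment_set()].
#' @param batch_size forward batch size.
#' @return List with `P` (probabilities, n x branches), `logits`, and `f`
#'   (named list of embedding matrices).
#' @export
predict_segments <- function(model, segs, batch_size = 256L) {
  n <- n_segments(segs)
  P <- matrix(NA_real_, n, length(model$branches))
  colnames(P) <- model$branches
  logits <- P
  f <- setNames(lapply(model$branches, function(b)
    matrix(NA_real_, n, model$d_f)), model$branches)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batch_size - 1L, n)
    x <- segs$segments[idx, , , drop = FALSE]
    fw <- model_forward(model, x, want_cache = FALSE)
    P[idx, ] <- fw$P; logits[idx, ] <- fw$logits
    for (b in model$branches) f[[b]][idx, ] <- fw$f[[b]]
    i <- i + batch_size
  }
  list(P = P, logits = logits, f = f)
}

#' Save / load a model checkpoint
#'
#' Single-file RDS container with a format version tag.
#' @param model an `eegcouple_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "eegcouple-checkpoint-1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  o <- readRDS(path)
  if (!identical(o$format, "eegcouple-checkpoint-1"))
    stop("not an eegcouple checkpoint")
  o$model
}
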