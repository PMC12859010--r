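#' Training configuration
#'
#' Settings for joint end-to-end optimization: AdamW with decoupled weight
#' decay at a fixed learning rate (no schedule), per-dimension binary
#' cross-entropy plus the enabled coupling constraints.
#'
#' @param epochs training epochs (reference setting 200; scale down for
#'   desk-size runs).
#' @param learning_rate AdamW learning rate (reference setting 0.025).
#' @param weight_decay decoupled weight decay applied to weight matrices
#'   (not biases, norms or state-space parameters).
#' @param batch_size minibatch size.
#' @param seed integer seed controlling shuffling and (via
#'   `encoder$init_seed`, unless overridden) parameter init.
#' @param constraint_flags named logical length-3 vector: enable the VA, AD,
#'   VD constraint terms. A disabled term contributes exactly 0.
#' @param weights a [loss_weights()].
#' @param encoder an [encoder_config()].
#' @param d_f feature-head embedding width.
#' @param adam_beta1,adam_beta2 AdamW moment decay rates (defaults 0.9,
#'   0.999).
#' @param grad_clip global gradient-norm ceiling: the full gradient tree is
#'   rescaled when its L2 norm exceeds this value (default 1.0); `Inf`
#'   disables clipping. Keeps fixed-learning-rate training stable late in
#'   optimization.
#' @param eval_threshold decision threshold on the predicted probability;
#'   `P == threshold` counts as class 0.
#' @param eps,tau denominator guards of the cosine constraint terms.
#' @param ad_mask `"all"` (formula-faithful default) or
#'   `"high_arousal_only"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, learning_rate = 0.025,
                         weight_decay = 0.01, batch_size = 128L, seed = 1L,
                         constraint_flags = c(VA = TRUE, AD = TRUE, VD = TRUE),
                         weights = loss_weights(), encoder = encoder_config(),
                         d_f = 64L, adam_beta1 = 0.9, adam_beta2 = 0.999,
                 grad_clip = 1.0, eval_threshold = 0.5,
                         eps = 1e-8, tau = 1e-8,
                         ad_mask = c("all", "high_arousal_only")) {
  ad_mask <- match.arg(ad_mask)
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  if (is.null(names(constraint_flags)))
    names(constraint_flags) <- c("VA", "AD", "VD")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 constraint_flags = constraint_flags, weights = weights,
                 encoder = encoder, d_f = as.integer(d_f),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 grad_clip = grad_clip,
                 eval_threshold = eval_threshold, eps = eps, tau = tau,
                 ad_mask = ad_mask),
            class = "train_config")
}

## ---- AdamW over the nested parameter tree ----

# Walks params/grads/moment trees in parallel; decoupled weight decay is
# applied to 2-D weight matrices only. Non-numeric leaves pass through;
# list attributes (block variant/meta) are preserved.
adamw_step <- function(p, g, m, v, lr, wd, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  if (is.list(p)) {
    if (is.null(m)) m <- vector("list", length(p))
    if (is.null(v)) v <- vector("list", length(p))
    out_p <- p; out_m <- m; out_v <- v
    nms <- names(p)
    for (i in seq_along(p)) {
      # gradient children carry a d-prefix (W -> dW, dirs -> ddirs);
      # container names and unnamed (positional) lists match directly
      gi <- if (is.null(nms) || !nzchar(nms[i])) g[[i]]
            else if (!is.null(g[[nms[i]]])) g[[nms[i]]]
            else g[[paste0("d", nms[i])]]
      r <- adamw_step(p[[i]], gi, m[[i]], v[[i]], lr, wd, t, b1, b2, eps)
      out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
    }
    return(list(p = out_p, m = out_m, v = out_v))
  }
  if (is.null(g)) return(list(p = p, m = m, v = v))  # untouched leaf
  if (!is.numeric(p)) return(list(p = p, m = m, v = v))
  if (is.null(m)) { m <- p; m[] <- 0 }
  if (is.null(v)) { v <- p; v[] <- 0 }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  upd <- mhat / (sqrt(vhat) + eps)
  if (wd > 0 && length(dim(p)) == 2L) upd <- upd + wd * p
  list(p = p - lr * upd, m = m, v = v)
}

grad_sq_norm <- function(g) {
  if (is.list(g)) sum(vapply(g, grad_sq_norm, 0))
  else if (is.numeric(g)) sum(g * g)
  else 0
}

scale_grads <- function(g, s) {
  if (is.list(g)) lapply(g, scale_grads, s = s)
  else if (is.numeric(g)) g * s
  else g
}

clip_grads <- function(g, clip) {
  nrm <- sqrt(grad_sq_norm(g))
  if (nrm > clip) scale_grads(g, clip / nrm) else g
}

#' Train the multi-task decoder
#'
#' Joint optimization: every step runs the shared encoder, the three task
#' encoders, the classifier and feature heads, assembles the weighted loss
#' from the per-dimension cross-entropies and the enabled coupling
#' constraints, and applies one AdamW update. Fully deterministic for a
#' fixed (seed, config, data).
#'
#' @param train_set a [segment_set()].
#' @param cfg a [train_config()].
#' @param model optionally, a pre-built [build_model()] to continue from;
#'   by default a fresh model is initialized with
#'   `init_seed = cfg$encoder$init_seed`.
#' @param branches branches to build and train (subset of V, A, D);
#'   single-branch models train with only that dimension's cross-entropy and
#'   no constraints.
#' @param verbose print a line per epoch.
#' @return List with `model` (trained) and `history` (one row per epoch:
#'   the six loss terms, weighted total, and training accuracies).
#' @export
train_model <- function(train_set, cfg = train_config(), model = NULL,
                        branches = c("V", "A", "D"), verbose = FALSE) {
  n <- n_segments(train_set)
  if (n == 0L) stop("empty training set")
  if (is.null(model)) model <- build_model(cfg$encoder, cfg$d_f, branches)
  multi <- length(model$branches) == 3L
  flags <- if (multi) cfg$constraint_flags else c(VA = FALSE, AD = FALSE, VD = FALSE)
  lab_cols <- match(model$branches, c("V", "A", "D"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  mstate <- NULL; vstate <- NULL; t_step <- 0L
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    terms <- c(L_V = 0, L_A = 0, L_D = 0, L_VA = 0, L_AD = 0, L_VD = 0,
               total = 0)
    nseen <- 0L
    correct <- numeric(length(model$branches))
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(i + cfg$batch_size - 1L, n)]
      x <- train_set$segments[idx, , , drop = FALSE]
      y <- train_set$labels[idx, , drop = FALSE]
      fw <- model_forward(model, x, want_cache = TRUE)
      if (multi) {
        lg <- batch_loss_grads(fw$P, fw$logits, fw$f, y, cfg$weights,
                               flags, cfg$eps, cfg$tau, cfg$ad_mask)
        bd <- lg$breakdown
        dlogits <- lg$dlogits
        df <- lg$df
      } else {
        yb <- y[, lab_cols, drop = FALSE]
        Lb <- mean(bce_dimension(fw$P, yb))
        bd <- list(L_V = NA, L_A = NA, L_D = NA, L_VA = 0, L_AD = 0,
                   L_VD = 0, total = cfg$weights$lambda * Lb)
        bd[[paste0("L_", model$branches)]] <- Lb
        dlogits <- (cfg$weights$lambda / length(idx)) * (fw$P - yb)
        df <- setNames(vector("list", length(model$branches)), model$branches)
      }
      if (!is.finite(bd$total))
        stop("numeric error: non-finite loss at epoch ", ep, ", step ",
             (i - 1L) %/% cfg$batch_size + 1L)
      grads <- model_backward(model, fw, dlogits, df)
      if (is.finite(cfg$grad_clip)) grads <- clip_grads(grads, cfg$grad_clip)
      t_step <- t_step + 1L
      st <- adamw_step(model$params, grads, mstate, vstate,
                       cfg$learning_rate, cfg$weight_decay, t_step,
                       b1 = cfg$adam_beta1, b2 = cfg$adam_beta2)
      model$params <- st$p; mstate <- st$m; vstate <- st$v
      w <- length(idx)
      for (k in names(terms)) {
        val <- bd[[k]]
        if (!is.null(val) && is.finite(val)) terms[k] <- terms[k] + w * val
      }
      pred <- fw$P > cfg$eval_threshold
      correct <- correct + colSums(pred == (y[, lab_cols, drop = FALSE] == 1L))
      nseen <- nseen + w
      i <- i + cfg$batch_size
    }
    row <- as.list(terms / nseen)
    acc <- setNames(rep(NA_real_, 3), c("V", "A", "D"))
    acc[model$branches] <- 100 * correct / nseen
    hist[[ep]] <- c(list(epoch = ep), row,
                    list(valence_acc = acc[["V"]], arousal_acc = acc[["A"]],
                         dominance_acc = acc[["D"]]))
    if (verbose)
      message(sprintf("epoch %3d  total %.4f  acc %s", ep, row$total,
                      paste(sprintf("%.1f", acc[model$branches]),
                            collapse = "/")))
  }
  history <- do.call(rbind, lapply(hist, function(r)
    as.data.frame(r, check.names = FALSE)))
  names(history) <- c("epoch", "loss_v", "loss_a", "loss_d", "loss_va",
                      "loss_ad", "loss_vd", "loss_total", "valence_acc",
                      "arousal_acc", "dominance_acc")
  list(model = model, history = history)
}

#' Evaluate a model on a segment set
#'
#' Per-dimension accuracy is `100 * mean(1(P > threshold) == y)`;
#' `P == threshold` counts as class 0. Constraint diagnostics (mean V-A
#' circular loss, mean A-D norm gap, mean V-D cosine) are computed on the
#' same pass.
#'
#' @param model a trained `eegcouple_model`.
#' @param eval_set a [segment_set()].
#' @param threshold decision threshold (default 0.5).
#' @return List with per-dimension accuracies (percent), the prediction
#'   matrix, and a `diagnostics` record.
#' @export
evaluate_model <- function(model, eval_set, threshold = 0.5) {
  if (n_segments(eval_set) == 0L) stop("empty evaluation set")
  pr <- predict_segments(model, eval_set)
  lab_cols <- match(model$branches, c("V", "A", "D"))
  y <- eval_set$labels[, lab_cols, drop = FALSE]
  acc <- setNames(rep(NA_real_, 3), c("V", "A", "D"))
  for (j in seq_along(model$branches))
    acc[model$branches[j]] <-
      100 * mean((pr$P[, j] > threshold) == (y[, j] == 1L))
  diagnostics <- NULL
  if (length(model$branches) == 3L) {
    cosvd <- rowSums(pr$f$V * pr$f$D) /
      (sqrt(rowSums(pr$f$V^2)) * sqrt(rowSums(pr$f$D^2)) + 1e-12)
    diagnostics <- list(
      mean_loss_va = mean(loss_va_circular(pr$P[, 1:2],
                                           eval_set$labels[, 1:2])),
      mean_ad_norm_gap = mean(abs(sqrt(rowSums(pr$f$A^2)) -
                                    sqrt(rowSums(pr$f$D^2)))),
      mean_vd_cos = mean(cosvd))
  }
  list(acc_V = acc[["V"]], acc_A = acc[["A"]], acc_D = acc[["D"]],
       P = pr$P, f = pr$f, diagnostics = diagnostics)
}

## ---- fold plans ----

#' Build a k-fold plan
#'
#' Deterministic shuffled partition at segment, trial or subject granularity
#' with near-equal fold sizes (unit counts differ by at most 1). Trial and
#' subject units keep all segments of one trial/subject in the same fold.
#'
#' @param dataset a [segment_set()].
#' @param k number of folds (>= 2).
#' @param unit `"segment"`, `"trial"` or `"subject"`.
#' @param seed shuffle seed.
#' @return An object of class `fold_plan` with an `assignment` vector
#'   mapping each segment to a fold id in `1:k`.
#' @export
make_kfold <- function(dataset, k, unit = c("segment", "trial", "subject"),
                       seed = 1L) {
  unit <- match.arg(unit)
  n <- n_segments(dataset)
  keys <- switch(unit,
                 segment = as.character(seq_len(n)),
                 trial = paste(dataset$subject_id, dataset$trial_index,
                               sep = "::"),
                 subject = dataset$subject_id)
  uk <- unique(keys)
  if (length(uk) < k)
    stop("plan error: only ", length(uk), " ", unit, "(s) for ", k, " folds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(uk)
  fold_of_unit <- setNames(rep(seq_len(k), length.out = length(uk)), shuffled)
  assignment <- as.integer(fold_of_unit[keys])
  structure(list(unit = unit, k = as.integer(k), assignment = assignment),
            class = "fold_plan")
}

#' Build a leave-one-subject-out plan
#'
#' One fold per subject: fold i holds exactly the segments of the i-th
#' subject (folds are keyed by sorted subject id, not position).
#'
#' @param dataset a [segment_set()].
#' @return A `fold_plan` with `k` = number of subjects.
#' @export
make_loso <- function(dataset) {
  subjects <- sort(unique(dataset$subject_id))
  if (length(subjects) < 2L)
    stop("plan error: leave-one-subject-out needs >= 2 subjects")
  assignment <- match(dataset$subject_id, subjects)
  structure(list(unit = "subject", k = length(subjects),
                 assignment = as.integer(assignment), subjects = subjects),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan>", x$k, "folds at", x$unit, "granularity; fold sizes:",
      paste(tabulate(x$assignment, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Run cross-validation
#'
#' For every fold: fresh parameter init (seed + fold id), train on the other
#' folds, evaluate on the held-out fold. Aggregates mean and sd of the
#' per-dimension accuracies.
#'
#' @param dataset a [segment_set()].
#' @param plan a [make_kfold()] / [make_loso()] plan.
#' @param cfg a [train_config()].
#' @param branches branches to train.
#' @param verbose print per-fold progress.
#' @return List with `per_fold` (data.frame: fold, accuracies, diagnostics)
#'   and `summary` (mean and sd per dimension).
#' @export
run_cv <- function(dataset, plan, cfg = train_config(),
                   branches = c("V", "A", "D"), verbose = FALSE) {
  rows <- vector("list", plan$k)
  for (fold in seq_len(plan$k)) {
    test_idx <- which(plan$assignment == fold)
    train_idx <- which(plan$assignment != fold)
    cfg_fold <- cfg
    cfg_fold$encoder$init_seed <- cfg$encoder$init_seed + fold
    cfg_fold$seed <- cfg$seed + fold
    fit <- train_model(subset_segments(dataset, train_idx), cfg_fold,
                       branches = branches)
    ev <- evaluate_model(fit$model, subset_segments(dataset, test_idx),
                         cfg$eval_threshold)
    rows[[fold]] <- data.frame(
      fold = fold, n_test = length(test_idx),
      valence_acc = ev$acc_V, arousal_acc = ev$acc_A,
      dominance_acc = ev$acc_D,
      loss_va = if (is.null(ev$diagnostics)) NA else ev$diagnostics$mean_loss_va,
      ad_norm_gap = if (is.null(ev$diagnostics)) NA else ev$diagnostics$mean_ad_norm_gap,
      vd_cos = if (is.null(ev$diagnostics)) NA else ev$diagnostics$mean_vd_cos)
    if (verbose)
      message(sprintf("fold %d/%d  acc %s", fold, plan$k,
                      paste(sprintf("%.1f", unlist(rows[[fold]][3:5])),
                            collapse = "/")))
  }
  per_fold <- do.call(rbind, rows)
  summary <- data.frame(
    dimension = c("valence", "arousal", "dominance"),
    mean_acc = c(mean(per_fold$valence_acc), mean(per_fold$arousal_acc),
                 mean(per_fold$dominance_acc)),
    sd_acc = c(stats::sd(per_fold$valence_acc),
               stats::sd(per_fold$arousal_acc),
               stats::sd(per_fold$dominance_acc)))
  list(per_fold = per_fold, summary = summary)
}

#' Constraint ablation grid
#'
#' Nine rows: a single-task baseline (three independent single-branch
#' models, no constraints) plus the eight on/off combinations of the three
#' coupling constraints in the multi-task model, each evaluated with
#' [run_cv()].
#'
#' @param dataset a [segment_set()].
#' @param plan a fold plan.
#' @param cfg a [train_config()].
#' @param verbose print per-row progress.
#' @return Data.frame with columns `setting`, `va`, `ad`, `vd` (constraint
#'   on/off), and mean per-dimension accuracies.
#' @export
run_ablation <- function(dataset, plan, cfg = train_config(),
                         verbose = FALSE) {
  rows <- list()
  # single-task: one independent model per dimension
  acc <- c(V = NA_real_, A = NA_real_, D = NA_real_)
  for (b in c("V", "A", "D")) {
    r <- run_cv(dataset, plan, cfg, branches = b)
    acc[b] <- r$summary$mean_acc[match(b, c("V", "A", "D"))]
  }
  rows[[1]] <- data.frame(setting = "single_task", va = FALSE, ad = FALSE,
                          vd = FALSE, valence_acc = acc[["V"]],
                          arousal_acc = acc[["A"]],
                          dominance_acc = acc[["D"]])
  combos <- expand.grid(va = c(FALSE, TRUE), ad = c(FALSE, TRUE),
                        vd = c(FALSE, TRUE))
  combos <- combos[order(combos$va + combos$ad + combos$vd), ]
  for (i in seq_len(nrow(combos))) {
    cfg_i <- cfg
    cfg_i$constraint_flags <- c(VA = combos$va[i], AD = combos$ad[i],
                                VD = combos$vd[i])
    r <- run_cv(dataset, plan, cfg_i)
    rows[[length(rows) + 1]] <- data.frame(
      setting = "multi_task", va = combos$va[i], ad = combos$ad[i],
      vd = combos$vd[i], valence_acc = r$summary$mean_acc[1],
      arousal_acc = r$summary$mean_acc[2],
      dominance_acc = r$summary$mean_acc[3])
    if (verbose) message("ablation row ", length(rows), "/9 done")
  }
  do.call(rbind, rows)
}

#' Classification-weight sweep
#'
#' Re-runs cross-validation for each value of the classification-loss weight
#' lambda, holding the constraint weights at their defaults.
#'
#' @param dataset a [segment_set()].
#' @param plan a fold plan.
#' @param lambda_grid non-negative values of lambda to evaluate.
#' @param cfg a [train_config()].
#' @return Data.frame ordered by lambda with mean per-dimension accuracies.
#' @export
lambda_sweep <- function(dataset, plan, lambda_grid, cfg = train_config()) {
  if (any(lambda_grid < 0)) stop("config error: lambda must be >= 0")
  lambda_grid <- sort(lambda_grid)
  rows <- lapply(lambda_grid, function(lam) {
    cfg_i <- cfg
    cfg_i$weights$lambda <- lam
    r <- run_cv(dataset, plan, cfg_i)
    data.frame(lambda = lam, valence_acc = r$summary$mean_acc[1],
               arousal_acc = r$summary$mean_acc[2],
               dominance_acc = r$summary$mean_acc[3])
  })
  do.call(rbind, rows)
}

#' Constraint diagnostics on an evaluation set
#'
#' Reports the mean per-sample V-A circular loss, the mean absolute A-D
#' embedding-norm gap, and the mean V-D embedding cosine, overall and
#' stratified by true (V, A, D) label cell.
#'
#' @param model a trained 3-branch `eegcouple_model`.
#' @param eval_set a [segment_set()].
#' @return List with `overall` (named numerics) and `by_cell` (data.frame).
#' @export
constraint_diagnostics <- function(model, eval_set) {
  if (n_segments(eval_set) == 0L) stop("empty evaluation set")
  if (length(model$branches) != 3L)
    stop("diagnostics need a 3-branch model")
  pr <- predict_segments(model, eval_set)
  lva <- loss_va_circular(pr$P[, 1:2], eval_set$labels[, 1:2])
  gap <- abs(sqrt(rowSums(pr$f$A^2)) - sqrt(rowSums(pr$f$D^2)))
  cosvd <- rowSums(pr$f$V * pr$f$D) /
    (sqrt(rowSums(pr$f$V^2)) * sqrt(rowSums(pr$f$D^2)) + 1e-12)
  cell <- paste0(eval_set$labels[, 1], eval_set$labels[, 2],
                 eval_set$labels[, 3])
  by_cell <- do.call(rbind, lapply(sort(unique(cell)), function(cl) {
    m <- cell == cl
    data.frame(cell = cl, n = sum(m), mean_loss_va = mean(lva[m]),
               mean_ad_norm_gap = mean(gap[m]), mean_vd_cos = mean(cosvd[m]))
  }))
  list(overall = c(mean_loss_va = mean(lva), mean_ad_norm_gap = mean(gap),
                   mean_vd_cos = mean(cosvd)),
       by_cell = by_cell)
}

#' Band-importance diagnostic
#'
#' Plain spectral check of what separates the classes in a segment set: for
#' each channel and canonical band (alpha 8-13, beta 13-30, gamma 30-45 Hz),
#' the difference in mean log band power between high and low labels of each
#' dimension. Positive values mean more band power under the high label.
#'
#' @param segs a [segment_set()].
#' @param fs sampling rate (Hz).
#' @return Data.frame: channel, band, dimension, delta_log_power.
#' @export
band_importance <- function(segs, fs = EEG_FS) {
  bands <- list(alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 45))
  nch <- dim(segs$segments)[2]
  rows <- list()
  for (ch in seq_len(nch)) {
    bp <- vapply(seq_len(n_segments(segs)), function(i) {
      x <- segs$segments[i, ch, ]
      vapply(bands, function(b) band_power(x, fs, b[1], b[2]), 0)
    }, numeric(length(bands)))
    for (bi in seq_along(bands)) {
      lp <- log(bp[bi, ] + 1e-12)
      for (dj in 1:3) {
        hi <- segs$labels[, dj] == 1L
        if (!any(hi) || all(hi)) next
        rows[[length(rows) + 1]] <- data.frame(
          channel = ch, band = names(bands)[bi],
          dimension = c("valence", "arousal", "dominance")[dj],
          delta_log_power = mean(lp[hi]) - mean(lp[!hi]))
      }
    }
  }
  do.call(rbind, rows)
}
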