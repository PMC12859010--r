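test_that("k-fold plans partition segments with near-equal folds", {
  segs <- tiny_segments()
  n <- n_segments(segs)  # 2 subjects x 8 trials x 2 windows = 32
  plan <- make_kfold(segs, 4, unit = "segment", seed = 3)
  expect_equal(sort(unique(plan$assignment)), 1:4)
  expect_equal(length(plan$assignment), n)
  expect_true(max(tabulate(plan$assignment)) -
                min(tabulate(plan$assignment)) <= 1)
  # every segment in exactly one fold: train/test never overlap
  for (k in 1:4) {
    expect_equal(sum(plan$assignment == k) + sum(plan$assignment != k), n)
  }
  # 100 segments, k 10 -> folds of exactly 10
  big <- segment_set(array(0, c(100, 2, 8)),
                     matrix(0L, 100, 3), rep("s", 100), rep(1:10, 10))
  p10 <- make_kfold(big, 10, "segment", seed = 1)
  expect_true(all(tabulate(p10$assignment) == 10))
})

test_that("trial- and subject-unit plans never split their unit", {
  segs <- tiny_segments()
  pt <- make_kfold(segs, 4, unit = "trial", seed = 5)
  key <- paste(segs$subject_id, segs$trial_index)
  for (k in unique(key))
    expect_length(unique(pt$assignment[key == k]), 1L)
  ps <- make_kfold(segs, 2, unit = "subject", seed = 5)
  for (s in unique(segs$subject_id))
    expect_length(unique(ps$assignment[segs$subject_id == s]), 1L)
  expect_error(make_kfold(segs, 3, unit = "subject"), "plan error")
})

test_that("leave-one-subject-out builds one fold per subject, keyed by id", {
  sets <- generate_dataset(synth_config(n_subjects = 23L,
                                        trials_per_subject = 1L,
                                        channels = 4L, duration_s = 1,
                                        seed = 2L))
  segs <- bind_segment_sets(lapply(sets, segment_trials))
  plan <- make_loso(segs)
  expect_equal(plan$k, 23L)
  for (i in seq_len(23)) {
    held <- unique(segs$subject_id[plan$assignment == i])
    expect_length(held, 1L)
    expect_equal(held, plan$subjects[i])
  }
  # 2 subjects -> 2 complementary folds
  segs2 <- tiny_segments()
  plan2 <- make_loso(segs2)
  expect_equal(plan2$k, 2L)
  expect_setequal(unique(plan2$assignment), 1:2)
  # single subject is an error
  one <- subset_segments(segs2, which(segs2$subject_id ==
                                        segs2$subject_id[1]))
  expect_error(make_loso(one), "plan error")
  # ids with gaps: folds keyed by id, not position
  segs3 <- segs2
  segs3$subject_id <- ifelse(segs3$subject_id == "sim01", "s01", "s99")
  plan3 <- make_loso(segs3)
  expect_equal(plan3$subjects, c("s01", "s99"))
})

test_that("evaluation accuracy follows the strict-threshold convention", {
  segs <- tiny_segments()
  model <- build_model(tiny_encoder("lite"), d_f = 8L)
  # a model with zeroed classifier output emits P = 0.5 everywhere:
  # at threshold 0.5 every prediction is class 0
  for (b in c("V", "A", "D")) {
    model$params$branch[[b]]$cls$W[] <- 0
    model$params$branch[[b]]$cls$b[] <- 0
  }
  ev <- evaluate_model(model, segs, threshold = 0.5)
  expect_equal(ev$acc_V, 100 * mean(segs$labels[, 1] == 0L))
  # all-high labels with P = 0.5 -> 0% accuracy
  segs1 <- segs; segs1$labels[] <- 1L
  ev1 <- evaluate_model(model, segs1, threshold = 0.5)
  expect_equal(ev1$acc_A, 0)
  # hand-built 4-sample case: biasing one classifier shifts all P one way
  model$params$branch$V$cls$b[] <- 3  # P_V = sigmoid(3) > 0.5 everywhere
  four <- subset_segments(segs, 1:4)
  ev4 <- evaluate_model(model, four, threshold = 0.5)
  expect_equal(ev4$acc_V, 100 * mean(four$labels[, 1] == 1L))
  expect_error(evaluate_model(model, subset_segments(segs, integer(0))),
               "empty")
})

test_that("one training epoch logs every loss term and accuracy", {
  segs <- tiny_segments()
  cfg <- tiny_train_config(epochs = 1L, variant = "lite")
  fit <- train_model(segs, cfg)
  expect_equal(nrow(fit$history), 1L)
  expect_named(fit$history,
               c("epoch", "loss_v", "loss_a", "loss_d", "loss_va", "loss_ad",
                 "loss_vd", "loss_total", "valence_acc", "arousal_acc",
                 "dominance_acc"))
  expect_true(all(is.finite(unlist(fit$history))))
})

test_that("training is deterministic for a fixed seed and config", {
  segs <- tiny_segments()
  cfg <- tiny_train_config(epochs = 2L)
  f1 <- train_model(segs, cfg)
  f2 <- train_model(segs, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("constraints off reproduces the plain multi-task run bit-for-bit", {
  segs <- tiny_segments()  # 32 segments
  half <- subset_segments(segs, 1:32)
  cfg_off <- tiny_train_config(epochs = 3L)
  cfg_off$constraint_flags <- c(VA = FALSE, AD = FALSE, VD = FALSE)
  cfg_plain <- tiny_train_config(epochs = 3L)
  cfg_plain$weights <- loss_weights(1, 0, 0, 0)
  f_off <- train_model(half, cfg_off)
  f_plain <- train_model(half, cfg_plain)
  expect_identical(f_off$model$params, f_plain$model$params)
  expect_identical(f_off$history[c("loss_v", "loss_a", "loss_d")],
                   f_plain$history[c("loss_v", "loss_a", "loss_d")])
  # flags-off training is invariant to the constraint weight values
  cfg_off2 <- cfg_off
  cfg_off2$weights <- loss_weights(1, 7, 7, 7)
  f_off2 <- train_model(half, cfg_off2)
  expect_identical(f_off$model$params, f_off2$model$params)
})

test_that("cross-validation aggregates per-fold accuracies", {
  segs <- tiny_segments()
  plan <- make_kfold(segs, 2, "segment", seed = 4)
  cfg <- tiny_train_config(epochs = 1L, variant = "lite")
  r <- run_cv(segs, plan, cfg)
  expect_equal(nrow(r$per_fold), 2L)
  expect_equal(r$summary$mean_acc[1], mean(r$per_fold$valence_acc))
  expect_equal(r$summary$mean_acc[3], mean(r$per_fold$dominance_acc))
  # rerun with the same seeds reproduces the table
  r2 <- run_cv(segs, plan, cfg)
  expect_identical(r$per_fold, r2$per_fold)
})

test_that("ablation covers single-task plus the 8 constraint combinations", {
  segs <- tiny_segments()
  plan <- make_kfold(segs, 2, "segment", seed = 4)
  cfg <- tiny_train_config(epochs = 1L, variant = "lite")
  tab <- run_ablation(segs, plan, cfg)
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$setting[1], "single_task")
  combos <- unique(tab[tab$setting == "multi_task", c("va", "ad", "vd")])
  expect_equal(nrow(combos), 8L)
  expect_true(all(is.finite(tab$valence_acc)))
})

test_that("lambda sweep runs per weight value, ordered, with zero allowed", {
  segs <- tiny_segments()
  plan <- make_kfold(segs, 2, "segment", seed = 4)
  cfg <- tiny_train_config(epochs = 1L, variant = "lite")
  tab <- lambda_sweep(segs, plan, c(1, 0), cfg)
  expect_equal(tab$lambda, c(0, 1))
  expect_true(all(is.finite(unlist(tab[-1]))))
  tab1 <- lambda_sweep(segs, plan, 1.0, cfg)
  expect_equal(nrow(tab1), 1L)
  expect_error(lambda_sweep(segs, plan, c(-1, 1), cfg), "config error")
})

test_that("constraint diagnostics stratify by label cell", {
  segs <- tiny_segments()
  model <- build_model(tiny_encoder("lite"), d_f = 8L)
  diag <- constraint_diagnostics(model, segs)
  expect_true(all(is.finite(diag$overall)))
  cells <- paste0(segs$labels[, 1], segs$labels[, 2], segs$labels[, 3])
  expect_setequal(diag$by_cell$cell, unique(cells))
  expect_equal(sum(diag$by_cell$n), n_segments(segs))
  # a single-sample set reproduces that sample's raw terms
  one <- subset_segments(segs, 1L)
  d1 <- constraint_diagnostics(model, one)
  pr <- predict_segments(model, one)
  expect_equal(unname(d1$overall["mean_loss_va"]),
               loss_va_circular(pr$P[, 1:2], one$labels[, 1:2]))
  expect_equal(unname(d1$overall["mean_ad_norm_gap"]),
               abs(sqrt(sum(pr$f$A^2)) - sqrt(sum(pr$f$D^2))))
})

test_that("band importance recovers the planted spectral directions", {
  segs <- tiny_segments(seed = 31L)
  bi <- band_importance(segs)
  roles <- default_channel_roles(8L)
  # left-frontal alpha down for high valence
  lf <- which(roles == "left_frontal")
  av <- bi[bi$channel %in% lf & bi$band == "alpha" &
             bi$dimension == "valence", "delta_log_power"]
  expect_true(all(av < 0))
  # central gamma up for high arousal
  ce <- which(roles == "central")
  ag <- bi[bi$channel %in% ce & bi$band == "gamma" &
             bi$dimension == "arousal", "delta_log_power"]
  expect_true(all(ag > 0))
  # posterior beta up for high dominance
  po <- which(roles == "posterior")
  ab <- bi[bi$channel %in% po & bi$band == "beta" &
             bi$dimension == "dominance", "delta_log_power"]
  expect_true(all(ab > 0))
})
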