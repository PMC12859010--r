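# Shared fixtures, generated in code at test time (nothing on disk).

# small synthetic config for fast tests: 2 subjects x 8 trials x 8 ch x 2 s
tiny_synth_config <- function(seed = 42L, ...) {
  synth_config(n_subjects = 2L, trials_per_subject = 8L, channels = 8L,
               duration_s = 2, seed = seed, ...)
}

tiny_segments <- function(seed = 42L, normalize = TRUE, ...) {
  sets <- generate_dataset(tiny_synth_config(seed = seed, ...))
  segs <- bind_segment_sets(lapply(sets, segment_trials))
  if (normalize) normalize_segments(segs) else segs
}

# small encoder for fast end-to-end tests
tiny_encoder <- function(variant = "ss2d", init_seed = 1L) {
  encoder_config(embed_dim = 8L, state_dim = 2L, n_shared_blocks = 2L,
                 branch_stages = 2L, block_variant = variant,
                 init_seed = init_seed)
}

tiny_train_config <- function(epochs = 2L, seed = 3L, variant = "ss2d", ...) {
  train_config(epochs = epochs, learning_rate = 0.005, batch_size = 32L,
               seed = seed, encoder = tiny_encoder(variant, init_seed = seed),
               d_f = 8L, ...)
}

# hand-rolled DEAP-dialect file with recognizable contents
write_manual_deap <- function(path, n_trials = 40L, n_chan = 40L,
                              n_samp = 8064L, k_labels = 4L, seed = 9L) {
  set.seed(seed)
  d <- array(stats::rnorm(n_trials * n_chan * n_samp, sd = 0.1),
             dim = c(n_trials, n_chan, n_samp))
  labels <- matrix(stats::runif(n_trials * k_labels, 1, 9), n_trials, k_labels)
  saveRDS(list(data = d, labels = labels), path)
  list(data = d, labels = labels)
}
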