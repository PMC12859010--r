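#' Synthetic coupled V-A-D EEG configuration
#'
#' Defines the generative conditions for synthetic EEG with planted spectral
#' effects. Labels are drawn from a joint distribution over the eight
#' (valence, arousal, dominance) cells; each dimension then leaves a band-power
#' signature on role-assigned channels: left-frontal alpha (8-13 Hz) power is
#' lowered under high valence (frontal alpha asymmetry / desynchronization),
#' central gamma (30-45 Hz) power is raised under high arousal, and posterior
#' beta (13-30 Hz) power is raised under high dominance. The background on
#' every channel is 1/f-shaped (pink) noise; oscillations are random-phase
#' band-limited processes, so no classifier can key on phase.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject trials per subject.
#' @param channels channel count.
#' @param duration_s trial duration in seconds.
#' @param sampling_rate Hz; must be at least 90 so the 30-45 Hz gamma band
#'   sits below Nyquist.
#' @param cell_probs eight non-negative numbers summing to 1: the joint
#'   probability of each (y_V, y_A, y_D) cell, named `"000"` ... `"111"`
#'   (digits in V, A, D order). The default couples the dimensions the way
#'   affect theory does: the high-V/high-A/high-D "joy" cell dominates and
#'   the low-valence/high-arousal/high-dominance "anger" cell (`"011"`) has
#'   substantial mass.
#' @param alpha_gain,gamma_gain,beta_gain dimensionless effect amplitudes
#'   (>= 0). Alpha is multiplicative-symmetric: left-frontal alpha amplitude
#'   is `base * (1 + alpha_gain)` for low valence and `base / (1 + alpha_gain)`
#'   for high valence. Gamma/beta amplitudes scale by `(1 + gain * y)`.
#' @param noise_sd standard deviation of the pink background, amplitude units.
#' @param channel_roles character vector length `channels` with values in
#'   `left_frontal`, `right_frontal`, `central`, `posterior`, `other`;
#'   defaults to an even block assignment.
#' @param seed integer master seed; each trial derives its own stream from
#'   (seed, subject, trial) so regeneration is order-independent.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 4L, trials_per_subject = 40L,
                         channels = 8L, duration_s = 5, sampling_rate = EEG_FS,
                         cell_probs = default_cell_probs(),
                         alpha_gain = 2, gamma_gain = 2, beta_gain = 2,
                         noise_sd = 0.3,
                         channel_roles = default_channel_roles(channels),
                         seed = 1L) {
  if (sampling_rate < 90)
    stop("config error: sampling_rate < 90 Hz cannot represent the 30-45 Hz gamma band")
  if (length(cell_probs) != 8L || any(cell_probs < 0) ||
      abs(sum(cell_probs) - 1) > 1e-12)
    stop("config error: cell_probs must be 8 non-negative values summing to 1")
  if (any(c(alpha_gain, gamma_gain, beta_gain) < 0))
    stop("config error: gains must be >= 0")
  n_samp <- duration_s * sampling_rate
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("config error: duration_s x sampling_rate must be an integer")
  if (length(channel_roles) != channels)
    stop("config error: channel_roles must cover all channels")
  if (is.null(names(cell_probs))) names(cell_probs) <- cell_names()
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 channels = as.integer(channels), duration_s = duration_s,
                 sampling_rate = as.integer(sampling_rate),
                 cell_probs = cell_probs, alpha_gain = alpha_gain,
                 gamma_gain = gamma_gain, beta_gain = beta_gain,
                 noise_sd = noise_sd, channel_roles = channel_roles,
                 seed = as.integer(seed)),
            class = "synth_config")
}

cell_names <- function() {
  g <- expand.grid(D = 0:1, A = 0:1, V = 0:1)
  paste0(g$V, g$A, g$D)[order(paste0(g$V, g$A, g$D))]
}

#' @rdname synth_config
#' @export
default_cell_probs <- function() {
  setNames(c(0.18, 0.04, 0.08, 0.15, 0.05, 0.08, 0.07, 0.35), cell_names())
}

#' @rdname synth_config
#' @export
default_channel_roles <- function(channels) {
  rep(c("left_frontal", "central", "posterior", "other"),
      each = ceiling(channels / 4))[seq_len(channels)]
}

# Deterministic per-trial sub-seed, kept below 2^31.
trial_seed <- function(seed, subject, trial) {
  as.integer((as.double(seed) * 1000003 + subject * 10007 + trial * 101) %%
               2147483629)
}

# Random-phase signal with a prescribed amplitude spectrum, unit sd.
# shape "pink": amplitude ~ 1/sqrt(f); shape "band": flat inside [f_lo, f_hi].
rand_spectrum_signal <- function(L, fs, shape = c("pink", "band"),
                                 f_lo = NULL, f_hi = NULL) {
  shape <- match.arg(shape)
  nf <- L %/% 2
  f <- (1:nf) * fs / L
  amp <- if (shape == "pink") 1 / sqrt(f) else as.numeric(f >= f_lo & f <= f_hi)
  if (all(amp == 0)) return(numeric(L))
  ph <- complex(modulus = amp * stats::rnorm(nf, sd = 1),
                argument = stats::runif(nf, 0, 2 * pi))
  spec <- complex(length.out = L)
  spec[2:(nf + 1)] <- ph
  spec[L:(L - nf + 2)] <- Conj(ph[seq_len(nf - 1)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / L
  s <- stats::sd(x)
  if (s < 1e-12) numeric(L) else x / s
}

#' Draw the trial label table
#'
#' Samples `n_subjects * trials_per_subject` binary (V, A, D) triples i.i.d.
#' from the configured joint cell distribution, deterministically for a fixed
#' seed.
#'
#' @param config a [synth_config()].
#' @return Integer matrix n x 3 (columns valence, arousal, dominance) with
#'   attributes `subject` and `trial` giving each row's provenance.
#' @export
sample_label_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_subjects * config$trials_per_subject
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  cells <- sample(names(config$cell_probs), n, replace = TRUE,
                  prob = config$cell_probs)
  lab <- t(vapply(strsplit(cells, ""), function(s) as.integer(s), integer(3)))
  colnames(lab) <- c("valence", "arousal", "dominance")
  attr(lab, "subject") <- rep(seq_len(config$n_subjects),
                              each = config$trials_per_subject)
  attr(lab, "trial") <- rep(seq_len(config$trials_per_subject),
                            config$n_subjects)
  lab
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthesize one EEG trial with planted spectral effects
#'
#' All channels carry pink background noise; role channels additionally carry
#' a random-phase band-limited oscillation whose amplitude is modulated by the
#' trial's binary labels (see [synth_config()]).
#'
#' @param label integer length-3 vector (y_V, y_A, y_D) in \{0, 1\}.
#' @param config a [synth_config()].
#' @param subject,trial indices used to derive the trial's own random stream,
#'   so the same (seed, subject, trial) always yields the same array.
#' @return Numeric matrix channels x samples.
#' @export
synthesize_trial <- function(label, config, subject = 1L, trial = 1L) {
  stopifnot(inherits(config, "synth_config"), length(label) == 3L,
            all(label %in% c(0, 1)))
  L <- as.integer(round(config$duration_s * config$sampling_rate))
  fs <- config$sampling_rate
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(trial_seed(config$seed, subject, trial))
  out <- matrix(0, config$channels, L)
  alpha_amp <- if (label[1] == 1) 1 / (1 + config$alpha_gain) else
    (1 + config$alpha_gain)
  gamma_amp <- 1 + config$gamma_gain * label[2]
  beta_amp <- 1 + config$beta_gain * label[3]
  for (ch in seq_len(config$channels)) {
    x <- config$noise_sd * rand_spectrum_signal(L, fs, "pink")
    role <- config$channel_roles[ch]
    if (role == "left_frontal")
      x <- x + alpha_amp * rand_spectrum_signal(L, fs, "band", 8, 13)
    else if (role == "central")
      x <- x + gamma_amp * rand_spectrum_signal(L, fs, "band", 30, 45)
    else if (role == "posterior")
      x <- x + beta_amp * rand_spectrum_signal(L, fs, "band", 13, 30)
    out[ch, ] <- x
  }
  out
}

#' Generate a full synthetic dataset
#'
#' Composes [sample_label_table()] and [synthesize_trial()] into one
#' [trial_set()] per subject. Ratings are written at the scale extremes
#' consistent with the binary cell (low -> scale minimum, high -> scale
#' maximum), so binarization at the scale midpoint recovers the planted
#' labels exactly.
#'
#' @param config a [synth_config()].
#' @param rating_scale length-2 rating interval for the emitted ratings.
#' @return List of [trial_set()] of length `config$n_subjects`.
#' @export
generate_dataset <- function(config, rating_scale = c(1, 9)) {
  lab <- sample_label_table(config)
  subj <- attr(lab, "subject"); tri <- attr(lab, "trial")
  lapply(seq_len(config$n_subjects), function(s) {
    rows <- which(subj == s)
    trials <- lapply(rows, function(r)
      synthesize_trial(lab[r, ], config, subject = s, trial = tri[r]))
    ratings <- matrix(rating_scale[1], length(rows), 3)
    ratings[lab[rows, , drop = FALSE] == 1L] <- rating_scale[2]
    trial_set(trials, ratings, rating_scale, sprintf("sim%02d", s), "synthetic")
  })
}

#' Write DEAP-layout fixture files
#'
#' Emits one RDS file per subject in the DEAP per-subject dialect accepted by
#' [read_deap_subject()]: `data` 40 x 40 x 8064 (EEG in channel rows 1-32,
#' synthetic peripheral noise in rows 33-40) and `labels` 40 x 4 (valence,
#' arousal, dominance, liking on 1-9). Requires `channels = 32`,
#' `trials_per_subject = 40` and `duration_s * sampling_rate = 8064`.
#'
#' @param dir output directory (created if missing).
#' @param config a [synth_config()].
#' @return Character vector of written file paths, invisibly.
#' @export
write_deap_like_fixture <- function(dir, config) {
  if (config$channels != DEAP_EEG_CHANNELS)
    stop("config error: deap dialect needs 32 channels, got ", config$channels)
  if (config$trials_per_subject != 40L)
    stop("config error: deap dialect needs 40 trials per subject")
  if (round(config$duration_s * config$sampling_rate) != 8064)
    stop("config error: deap dialect needs 8064 samples per trial")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- generate_dataset(config, rating_scale = c(1, 9))
  paths <- character(config$n_subjects)
  for (s in seq_along(sets)) {
    ts <- sets[[s]]
    d <- array(0, dim = c(40, 40, 8064))
    for (i in seq_len(40)) d[i, 1:32, ] <- ts$data[[i]]
    old <- .Random.seed_save()
    set.seed(trial_seed(config$seed, s, 0L))
    d[, 33:40, ] <- stats::rnorm(40 * 8 * 8064, sd = config$noise_sd)
    .Random.seed_restore(old)
    labels <- cbind(ts$ratings, liking = 5)
    paths[s] <- file.path(dir, sprintf("s%02d.rds", s))
    saveRDS(list(data = d, labels = labels, subject_id = ts$subject_id),
            paths[s])
  }
  invisible(paths)
}

#' Write a DREAMER-layout fixture file
#'
#' Emits a single RDS file in the dialect accepted by [read_dreamer()]:
#' a list of subjects, each with 18 variable-length 14-channel trials at
#' 128 Hz and 18 x 3 ratings on 1-5 (written at the scale extremes of the
#' planted labels). Trial lengths are drawn uniformly in
#' `trial_length_range_s` (default the 65-393 s film-clip range).
#'
#' @param path output file path.
#' @param config a [synth_config()]; must have `channels = 14` and
#'   `trials_per_subject = 18`.
#' @param trial_length_range_s length-2 integer range of clip lengths in
#'   seconds.
#' @return Invisibly, a list with `path` and the per-subject integer matrix of
#'   trial lengths in samples (`lengths`).
#' @export
write_dreamer_like_fixture <- function(path, config,
                                       trial_length_range_s = c(65, 393)) {
  if (config$channels != DREAMER_CHANNELS)
    stop("config error: dreamer dialect needs 14 channels, got ", config$channels)
  if (config$trials_per_subject != 18L)
    stop("config error: dreamer dialect needs 18 trials per subject")
  lab <- sample_label_table(config)
  subj <- attr(lab, "subject"); tri <- attr(lab, "trial")
  old <- .Random.seed_save()
  set.seed(trial_seed(config$seed, 0L, 0L))
  lens_s <- matrix(sample(trial_length_range_s[1]:trial_length_range_s[2],
                          config$n_subjects * 18L, replace = TRUE),
                   config$n_subjects, 18L)
  .Random.seed_restore(old)
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    rows <- which(subj == s)
    trials <- lapply(seq_along(rows), function(k) {
      cfg_t <- config
      cfg_t$duration_s <- lens_s[s, k]
      synthesize_trial(lab[rows[k], ], cfg_t, subject = s, trial = tri[rows[k]])
    })
    ratings <- matrix(1, 18L, 3)
    ratings[lab[rows, , drop = FALSE] == 1L] <- 5
    list(trials = trials, ratings = ratings, subject_id = sprintf("sim%02d", s))
  })
  saveRDS(subjects, path)
  invisible(list(path = path, lengths = lens_s * config$sampling_rate))
}

#' Band power of a trace via the periodogram
#'
#' Mean periodogram power inside a frequency band; an independent spectral
#' oracle used to verify planted effects (not part of the decoder).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param f_lo,f_hi band edges (Hz).
#' @return Mean power in the band.
#' @export
band_power <- function(x, fs, f_lo, f_hi) {
  L <- length(x)
  sp <- Mod(stats::fft(x))^2 / L
  f <- (0:(L - 1)) * fs / L
  keep <- f >= f_lo & f <= f_hi & f <= fs / 2
  mean(sp[keep])
}
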