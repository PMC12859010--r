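#' @useDynLib eegcouple, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
NULL

DEAP_EEG_CHANNELS <- 32L
DREAMER_CHANNELS <- 14L
EEG_FS <- 128L

#' Construct a trial set
#'
#' A trial set holds one subject's raw trials: a list of channel-by-sample
#' matrices (ragged lengths allowed), the native-scale valence/arousal/dominance
#' ratings, and provenance. All supported layouts are sampled at 128 Hz.
#'
#' @param data list of numeric matrices, one per trial, channels x samples.
#' @param ratings numeric matrix, trials x 3, columns valence, arousal,
#'   dominance on the native rating scale.
#' @param rating_scale length-2 numeric, closed rating interval (e.g. `c(1, 9)`).
#' @param subject_id character scalar.
#' @param dialect one of `"deap"`, `"dreamer"`, `"synthetic"`.
#' @param sampling_rate samples per second; 128 for all supported layouts.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, ratings, rating_scale, subject_id,
                      dialect = c("synthetic", "deap", "dreamer"),
                      sampling_rate = EEG_FS) {
  dialect <- match.arg(dialect)
  stopifnot(is.list(data), length(data) >= 1L)
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 3L)
    stop("ratings must have 3 columns (valence, arousal, dominance)")
  if (nrow(ratings) != length(data))
    stop("ratings rows (", nrow(ratings), ") != trial count (", length(data), ")")
  if (any(!is.finite(ratings))) stop("non-finite rating")
  if (any(ratings < rating_scale[1] - 1e-9) || any(ratings > rating_scale[2] + 1e-9))
    stop("ratings outside rating scale [", rating_scale[1], ", ", rating_scale[2], "]")
  nch <- vapply(data, nrow, 0L)
  if (length(unique(nch)) != 1L) stop("inconsistent channel counts across trials")
  colnames(ratings) <- c("valence", "arousal", "dominance")
  structure(list(data = data, ratings = ratings,
                 rating_scale = as.numeric(rating_scale),
                 subject_id = as.character(subject_id), dialect = dialect,
                 sampling_rate = as.integer(sampling_rate)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  lens <- vapply(x$data, ncol, 0L)
  cat("<trial_set> subject", x$subject_id, "|", x$dialect, "layout |",
      length(x$data), "trials x", nrow(x$data[[1]]), "channels |",
      if (length(unique(lens)) == 1L) paste(lens[1], "samples/trial")
      else paste0("samples/trial in [", min(lens), ", ", max(lens), "]"),
      "| ratings on [", x$rating_scale[1], ",", x$rating_scale[2], "]\n")
  invisible(x)
}

#' Read one DEAP-layout subject file
#'
#' The DEAP per-subject dialect is an RDS file holding a named list with
#' `data` (40 trials x 40 channels x 8064 samples; the first 32 channel rows
#' are EEG, the remainder peripheral and discarded) and `labels`
#' (40 x k, k >= 3, columns valence, arousal, dominance, then optionally
#' liking, on a 1-9 scale). Only the EEG modality is retained.
#'
#' @param path path to an RDS file in the DEAP per-subject dialect.
#' @return A [trial_set()] with 40 trials of 32 x 8064, ratings 40 x 3.
#' @export
read_deap_subject <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels))
    stop("dialect error: expected a list with `data` and `labels` arrays")
  d <- obj$data
  if (length(dim(d)) != 3L)
    stop("dialect error: `data` must be a 3-axis array (trial x channel x sample)")
  if (dim(d)[1] != 40L)
    stop("dialect error: trial axis has length ", dim(d)[1], ", expected 40")
  if (dim(d)[2] < DEAP_EEG_CHANNELS)
    stop("dialect error: channel axis has length ", dim(d)[2], ", expected >= 32")
  if (dim(d)[3] != 8064L)
    stop("dialect error: sample axis has length ", dim(d)[3], ", expected 8064")
  lab <- as.matrix(obj$labels)
  if (nrow(lab) != 40L)
    stop("dialect error: labels trial axis has length ", nrow(lab), ", expected 40")
  if (ncol(lab) < 3L)
    stop("dialect error: labels axis has ", ncol(lab), " columns, expected >= 3")
  trials <- lapply(seq_len(40L), function(i)
    matrix(d[i, seq_len(DEAP_EEG_CHANNELS), ], nrow = DEAP_EEG_CHANNELS))
  sid <- if (!is.null(obj$subject_id)) obj$subject_id else
    sub("\\.rds$", "", basename(path))
  trial_set(trials, lab[, 1:3, drop = FALSE], c(1, 9), sid, "deap")
}

#' Read a DREAMER-layout file
#'
#' The DREAMER dialect is a single RDS file holding a list of subjects; each
#' subject is a list with `trials` (a list of 18 matrices, 14 channels x
#' variable samples at 128 Hz) and `ratings` (18 x 3 on a 1-5 scale).
#' Trial lengths are preserved; no truncation to a common length.
#'
#' @param path path to an RDS file in the DREAMER dialect.
#' @return A list of [trial_set()], one per subject.
#' @export
read_dreamer <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || length(obj) == 0L)
    stop("dialect error: expected a non-empty list of subjects")
  lapply(seq_along(obj), function(i) {
    s <- obj[[i]]
    if (is.null(s$trials) || is.null(s$ratings))
      stop("dialect error: subject ", i, " missing `trials` or `ratings`")
    nch <- vapply(s$trials, nrow, 0L)
    if (any(nch != DREAMER_CHANNELS))
      stop("dialect error: subject ", i, " channel axis has length ",
           nch[which(nch != DREAMER_CHANNELS)[1]], ", expected 14")
    r <- as.matrix(s$ratings)
    if (any(r < 1 - 1e-9) || any(r > 5 + 1e-9))
      stop("dialect error: subject ", i, " ratings outside 1-5")
    sid <- if (!is.null(s$subject_id)) s$subject_id else sprintf("s%02d", i)
    trial_set(s$trials, r, c(1, 5), sid, "dreamer")
  })
}

#' Binarize affective ratings
#'
#' A dimension is labelled high (1) iff its rating is strictly greater than
#' the threshold; a rating equal to the threshold is labelled low (0). Use
#' threshold 5 for 1-9 scales (DEAP convention) and 3 for 1-5 scales
#' (DREAMER convention).
#'
#' @param ratings numeric matrix, trials x 3.
#' @param threshold numeric scalar.
#' @return Integer matrix trials x 3 of 0/1 labels, columns V, A, D.
#' @export
binarize_ratings <- function(ratings, threshold) {
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings))) stop("non-finite rating")
  lab <- matrix(as.integer(ratings > threshold), nrow = nrow(ratings))
  colnames(lab) <- c("valence", "arousal", "dominance")[seq_len(ncol(lab))]
  lab
}

#' Construct a segment set
#'
#' Windowed EEG segments with binary V-A-D labels and provenance. Labels are
#' constant across all segments of one trial.
#'
#' @param segments numeric 3-D array, n x channels x window_len.
#' @param labels integer matrix n x 3 of 0/1 (valence, arousal, dominance).
#' @param subject_id character vector length n.
#' @param trial_index integer vector length n.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(segments, labels, subject_id, trial_index) {
  stopifnot(length(dim(segments)) == 3L)
  n <- dim(segments)[1]
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == n, ncol(labels) == 3L,
            length(subject_id) == n, length(trial_index) == n,
            all(labels %in% c(0L, 1L)))
  colnames(labels) <- c("valence", "arousal", "dominance")
  structure(list(segments = segments, labels = labels,
                 subject_id = as.character(subject_id),
                 trial_index = as.integer(trial_index),
                 window_len = dim(segments)[3]),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set>", dim(x$segments)[1], "segments of",
      dim(x$segments)[2], "x", x$window_len, "|",
      length(unique(x$subject_id)), "subject(s) |",
      "high-label rates V/A/D:",
      paste(sprintf("%.2f", colMeans(x$labels)), collapse = "/"), "\n")
  invisible(x)
}

#' Number of segments
#' @param x a `segment_set`.
#' @return Integer count.
#' @export
n_segments <- function(x) dim(x$segments)[1]

#' Subset a segment set by index
#' @param x a `segment_set`.
#' @param idx integer indices of segments to keep.
#' @return A `segment_set` with the selected segments.
#' @export
subset_segments <- function(x, idx) {
  segment_set(x$segments[idx, , , drop = FALSE], x$labels[idx, , drop = FALSE],
              x$subject_id[idx], x$trial_index[idx])
}

#' Window trials into fixed-length segments
#'
#' Each trial is cut into windows starting at offset `leading_drop_s *
#' sampling_rate`, advancing by `stride` while a full window fits. The count
#' per trial is `floor((L - drop*fs - window)/stride) + 1`. Trial labels
#' (binarized ratings) broadcast to every window of the trial. With the
#' defaults (1 s window, non-overlapping, 3 s leading baseline dropped) a
#' DEAP-layout subject of 40 trials x 8064 samples yields 40 x 60 = 2400
#' segments of 32 x 128.
#'
#' @param trialset a [trial_set()].
#' @param window window length in samples (default 128, i.e. 1 s).
#' @param stride hop in samples (default = window: non-overlapping).
#' @param leading_drop_s leading baseline seconds discarded per trial
#'   (default 3 for the DEAP layout; use 0 for DREAMER/synthetic).
#' @param threshold binarization threshold; default is the midpoint of the
#'   rating scale (5 on 1-9, 3 on 1-5).
#' @return A [segment_set()].
#' @export
segment_trials <- function(trialset, window = 128L, stride = window,
                           leading_drop_s = if (trialset$dialect == "deap") 3 else 0,
                           threshold = mean(trialset$rating_scale)) {
  stopifnot(window >= 1L, stride >= 1L, leading_drop_s >= 0)
  fs <- trialset$sampling_rate
  drop <- as.integer(round(leading_drop_s * fs))
  labels <- binarize_ratings(trialset$ratings, threshold)
  nch <- nrow(trialset$data[[1]])
  counts <- vapply(trialset$data, function(m) {
    avail <- ncol(m) - drop
    if (avail < window) 0L else as.integer((avail - window) %/% stride + 1L)
  }, 0L)
  if (any(counts == 0L))
    warning("trial(s) ", paste(which(counts == 0L), collapse = ", "),
            " shorter than one window after leading drop; yielding 0 segments")
  total <- sum(counts)
  if (total == 0L) stop("no trial long enough for a single window")
  segs <- array(0, dim = c(total, nch, window))
  lab <- matrix(0L, total, 3L)
  tri <- integer(total)
  pos <- 0L
  for (i in seq_along(trialset$data)) {
    m <- trialset$data[[i]]
    if (counts[i] == 0L) next
    starts <- drop + (seq_len(counts[i]) - 1L) * stride
    for (s in seq_len(counts[i])) {
      segs[pos + s, , ] <- m[, (starts[s] + 1L):(starts[s] + window)]
    }
    lab[(pos + 1L):(pos + counts[i]), ] <- matrix(labels[i, ], counts[i], 3L, byrow = TRUE)
    tri[(pos + 1L):(pos + counts[i])] <- i
    pos <- pos + counts[i]
  }
  segment_set(segs, lab, rep(trialset$subject_id, total), tri)
}

#' Combine segment sets from several subjects
#' @param sets list of `segment_set` objects with equal channel/window dims.
#' @return A pooled `segment_set`.
#' @export
bind_segment_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  if (length(sets) == 1L) return(sets[[1]])
  d2 <- dim(sets[[1]]$segments)[2]; d3 <- dim(sets[[1]]$segments)[3]
  n <- sum(vapply(sets, n_segments, 0L))
  segs <- array(0, dim = c(n, d2, d3))
  pos <- 0L
  for (s in sets) {
    k <- n_segments(s)
    segs[(pos + 1L):(pos + k), , ] <- s$segments
    pos <- pos + k
  }
  segment_set(segs,
              do.call(rbind, lapply(sets, `[[`, "labels")),
              unlist(lapply(sets, `[[`, "subject_id")),
              unlist(lapply(sets, `[[`, "trial_index")))
}

#' Normalize segments
#'
#' `zscore` standardizes each (segment, channel) trace to mean 0 and unit
#' variance; traces with variance below the floor (1e-8) are set to zero
#' rather than blown up. `none` is the identity.
#'
#' @param segs a [segment_set()].
#' @param mode `"zscore"` or `"none"`.
#' @return A [segment_set()] with normalized traces.
#' @export
normalize_segments <- function(segs, mode = c("zscore", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(segs)
  x <- segs$segments
  if (any(!is.finite(x))) stop("non-finite segment values")
  d <- dim(x)
  # moments over the sample axis for every (segment, channel) pair
  m <- rowMeans(x, dims = 2L)
  xc <- x - as.vector(m)  # [n, ch] recycles over sample axis
  v <- rowMeans(xc * xc, dims = 2L)
  sdv <- sqrt(pmax(v, 1e-8))
  # constant traces: centred values are exactly 0, so the floor maps them to 0
  segs$segments <- xc / as.vector(sdv)
  segs
}

#' Save / load a segment-set cache
#'
#' Single-file RDS container with `segments`, `labels`, `subject_id`,
#' `trial_index` entries, for fast re-use of preprocessed data.
#' @param segs a [segment_set()].
#' @param path file path.
#' @return `write_segment_cache` returns `path` invisibly;
#'   `read_segment_cache` returns a [segment_set()].
#' @export
write_segment_cache <- function(segs, path) {
  saveRDS(unclass(segs), path)
  invisible(path)
}

#' @rdname write_segment_cache
#' @export
read_segment_cache <- function(path) {
  o <- readRDS(path)
  segment_set(o$segments, o$labels, o$subject_id, o$trial_index)
}
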