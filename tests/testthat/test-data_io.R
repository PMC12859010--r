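test_that("DEAP reader returns 32-channel EEG trials and preserves content", {
  path <- withr::local_tempfile(fileext = ".rds")
  ref <- write_manual_deap(path)
  ts <- read_deap_subject(path)
  expect_s3_class(ts, "trial_set")
  expect_length(ts$data, 40L)
  expect_equal(dim(ts$data[[1]]), c(32L, 8064L))
  expect_equal(ts$rating_scale, c(1, 9))
  # retained EEG rows are bit-exact; ratings are the first three label columns
  expect_identical(ts$data[[7]], matrix(ref$data[7, 1:32, ], 32))
  expect_identical(unname(ts$ratings), unname(ref$labels[, 1:3]))
})

test_that("DEAP reader rejects malformed dialects naming the offending axis", {
  bad_trials <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(data = array(0, c(39, 40, 8064)),
               labels = matrix(5, 39, 4)), bad_trials)
  expect_error(read_deap_subject(bad_trials), "trial axis")

  bad_samples <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(data = array(0, c(40, 40, 100)),
               labels = matrix(5, 40, 4)), bad_samples)
  expect_error(read_deap_subject(bad_samples), "sample axis")

  bad_labels <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(data = array(0, c(40, 40, 8064)),
               labels = matrix(5, 40, 2)), bad_labels)
  expect_error(read_deap_subject(bad_labels), "labels axis")

  missing <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(foo = 1), missing)
  expect_error(read_deap_subject(missing), "dialect error")
})

test_that("all-zero DEAP data passes through with ratings intact", {
  path <- withr::local_tempfile(fileext = ".rds")
  lab <- matrix(seq(1, 9, length.out = 120), 40, 3)
  saveRDS(list(data = array(0, c(40, 40, 8064)), labels = lab), path)
  ts <- read_deap_subject(path)
  expect_true(all(vapply(ts$data, function(m) all(m == 0), TRUE)))
  expect_identical(unname(ts$ratings), unname(lab))
})

test_that("DREAMER reader keeps ragged trial lengths and validates dialect", {
  path <- withr::local_tempfile(fileext = ".rds")
  # one subject with one 65 s and one 393 s clip (plus filler trials)
  lens <- c(65L, 393L, rep(100L, 16L)) * 128L
  subj <- list(trials = lapply(lens, function(L) matrix(0, 14, L)),
               ratings = matrix(3, 18, 3))
  saveRDS(list(subj), path)
  sets <- read_dreamer(path)
  expect_length(sets, 1L)
  expect_equal(ncol(sets[[1]]$data[[1]]), 8320L)
  expect_equal(ncol(sets[[1]]$data[[2]]), 50304L)
  expect_equal(sets[[1]]$rating_scale, c(1, 5))

  bad_ch <- withr::local_tempfile(fileext = ".rds")
  subj$trials[[1]] <- matrix(0, 13, 128)
  saveRDS(list(subj), bad_ch)
  expect_error(read_dreamer(bad_ch), "channel axis")

  bad_rating <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(list(trials = lapply(lens, function(L) matrix(0, 14, L)),
                    ratings = matrix(7, 18, 3))), bad_rating)
  expect_error(read_dreamer(bad_rating), "ratings outside 1-5")

  empty <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(), empty)
  expect_error(read_dreamer(empty), "dialect error")
})

test_that("binarization is strict-greater with tie going to the low class", {
  expect_equal(unname(binarize_ratings(rbind(c(7, 2, 9)), 5)[1, ]),
               c(1L, 0L, 1L))
  expect_equal(unname(binarize_ratings(rbind(c(5, 5, 5)), 5)[1, ]),
               c(0L, 0L, 0L))
  expect_equal(unname(binarize_ratings(rbind(c(4, 3, 1)), 3)[1, ]),
               c(1L, 0L, 0L))
  expect_error(binarize_ratings(rbind(c(NA, 1, 1)), 5), "non-finite")
})

test_that("binarization is monotone: raising a rating never flips 1 -> 0", {
  set.seed(1)
  for (rep in 1:20) {
    r <- matrix(runif(12, 1, 9), 4, 3)
    bump <- r + matrix(runif(12, 0, 3), 4, 3)
    expect_true(all(binarize_ratings(bump, 5) >= binarize_ratings(r, 5)))
  }
})

test_that("segmentation yields the closed-form window count", {
  # 300 samples, window 128, stride 64 -> offsets 0, 64, 128 -> 3 segments
  ts <- trial_set(list(matrix(rnorm(2 * 300), 2)), rbind(c(9, 1, 9)),
                  c(1, 9), "s", "synthetic")
  segs <- segment_trials(ts, window = 128L, stride = 64L, leading_drop_s = 0)
  expect_equal(n_segments(segs), 3L)
  # 256 samples, non-overlapping -> 2 segments
  ts2 <- trial_set(list(matrix(rnorm(2 * 256), 2)), rbind(c(9, 1, 9)),
                   c(1, 9), "s", "synthetic")
  expect_equal(n_segments(segment_trials(ts2, 128L, 128L, 0)), 2L)
})

test_that("segment counts match a brute-force offset enumerator", {
  set.seed(7)
  for (rep in 1:15) {
    lens <- sample(100:900, 3)
    window <- sample(c(32L, 64L, 128L), 1)
    stride <- sample(c(16L, 32L, 64L, 128L), 1)
    drop_n <- sample(c(0L, 64L), 1)
    ts <- trial_set(lapply(lens, function(L) matrix(0, 2, L)),
                    matrix(5, 3, 3), c(1, 9), "s", "synthetic")
    brute <- sum(vapply(lens, function(L) {
      starts <- seq(drop_n, L, by = stride)
      sum(starts + window <= L)
    }, 0))
    got <- tryCatch(
      n_segments(suppressWarnings(
        segment_trials(ts, window, stride, drop_n / 128))),
      error = function(e) 0L)
    expect_equal(got, brute, info = paste(lens, collapse = ","))
  }
})

test_that("segment labels broadcast from their source trial", {
  ts <- trial_set(list(matrix(0, 2, 384), matrix(0, 2, 384)),
                  rbind(c(9, 1, 9), c(1, 9, 1)), c(1, 9), "s", "synthetic")
  segs <- segment_trials(ts, 128L, 128L, 0)
  expect_equal(n_segments(segs), 6L)
  for (i in seq_len(6)) {
    expected <- binarize_ratings(ts$ratings, 5)[segs$trial_index[i], ]
    expect_equal(unname(segs$labels[i, ]), unname(expected))
  }
})

test_that("a trial shorter than one window yields zero segments with a warning", {
  ts <- trial_set(list(matrix(0, 2, 384), matrix(0, 2, 100)),
                  matrix(5, 2, 3), c(1, 9), "s", "synthetic")
  expect_warning(segs <- segment_trials(ts, 128L, 128L, 0), "0 segments")
  expect_equal(n_segments(segs), 3L)
  expect_true(all(segs$trial_index == 1L))
})

test_that("z-score normalization centers and scales every channel trace", {
  segs <- tiny_segments(normalize = FALSE)
  nz <- normalize_segments(segs, "zscore")
  mu <- apply(nz$segments, c(1, 2), mean)
  # population (1/n) variance convention
  v <- apply(nz$segments, c(1, 2), function(x) mean((x - mean(x))^2))
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(max(abs(v - 1)), 1e-6)
  # mode none is the identity
  expect_identical(normalize_segments(segs, "none"), segs)
  # constant traces floor to zero rather than exploding
  cseg <- segment_set(array(3, c(2, 2, 16)), matrix(0L, 2, 3),
                      c("a", "a"), c(1L, 1L))
  expect_true(all(normalize_segments(cseg)$segments == 0))
})

test_that("segment cache round-trips", {
  segs <- tiny_segments()
  path <- withr::local_tempfile(fileext = ".rds")
  write_segment_cache(segs, path)
  back <- read_segment_cache(path)
  expect_equal(back$segments, segs$segments)
  expect_equal(back$labels, segs$labels)
  expect_equal(back$subject_id, segs$subject_id)
})
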