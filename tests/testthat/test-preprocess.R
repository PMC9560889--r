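# Ingest and conditioning chain.

test_that("read_delimited ingests, selects columns and reports bad cells", {
  df <- data.frame(EEG_C3 = rnorm(100), EMG_ext = rnorm(100))
  path <- write_temp_csv(df)
  rec <- read_delimited(path, fs = 250)
  expect_s3_class(rec, "raw_recording")
  expect_equal(dim(rec$samples), c(2L, 100L))
  expect_equal(rec$fs, 250)
  # round trip: requesting one column returns exactly that channel
  one <- read_delimited(path, fs = 250, columns = "EMG_ext")
  expect_equal(unname(one$samples[1, ]), df$EMG_ext)
  expect_equal(one$channel_labels, "EMG_ext")
  expect_error(read_delimited(path, fs = 250, columns = "EMG_flex"),
               "missing column")
  empty <- tempfile(fileext = ".csv"); file.create(empty)
  expect_error(read_delimited(empty, fs = 250))
  bad <- write_temp_csv(data.frame(a = c("1", "2", "oops", "4")))
  expect_error(read_delimited(bad, fs = 250), "non-numeric cell.*row 3")
  expect_error(read_delimited("/nonexistent.csv", fs = 250), "not found")
})

test_that("common average reference zeroes the per-sample channel mean", {
  rec <- new_raw_recording(rbind(rep(3, 10), rep(1, 10)), fs = 100)
  out <- common_average_reference(rec)
  expect_equal(unname(out$samples), rbind(rep(1, 10), rep(-1, 10)))
  set.seed(5)
  noisy <- new_raw_recording(matrix(rnorm(60 * 500), 60), fs = 250)
  ref <- common_average_reference(noisy)
  expect_lt(max(abs(colMeans(ref$samples))), 1e-12)
  expect_error(common_average_reference(new_raw_recording(matrix(1, 1, 10), 100)),
               "single channel")
})

test_that("bandpass rejects DC and stopband, preserves passband", {
  fs <- 2500; n <- 10000
  rec <- new_raw_recording(rbind(rep(5, n),
                                 sine_at(100, fs, n),
                                 sine_at(10, fs, n)), fs = fs)
  out <- bandpass_filter(rec, 1, 60)
  expect_lt(mean(abs(out$samples[1, ])), 0.01 * 5)
  atten_db <- 20 * log10(sd(out$samples[2, ]) / sd(rec$samples[2, ]))
  expect_lt(atten_db, -20)
  expect_gt(cor(out$samples[3, ], rec$samples[3, ]), 0.99)
  expect_error(bandpass_filter(rec, 0, 60), "band edges")
  expect_error(bandpass_filter(rec, 10, 2000), "band edges")
})

test_that("resample decimates with correct geometry and spectral fidelity", {
  fs <- 2500; n <- 17500
  rec <- new_raw_recording(matrix(sine_at(10, fs, n), 1), fs = fs)
  out <- resample(rec, 250)
  expect_equal(ncol(out$samples), 1750L)
  expect_equal(out$fs, 250)
  expect_gt(cor(out$samples[1, ], sine_at(10, 250, 1750)), 0.99)
  expect_identical(resample(rec, fs), rec)
  expect_error(resample(rec, 5000), "no upsampling")
  expect_error(resample(rec, 751), "integer decimation")
})

test_that("segment_trials slices the declared geometry", {
  fs <- 250
  sig <- matrix(seq_len(10 * fs), 1)
  rec <- new_raw_recording(sig, fs = fs)
  seg <- segment_trials(rec, onsets = 1000, pre_s = 3, post_s = 4)
  expect_equal(ncol(seg$trials[[1]]), 1750L)
  expect_equal(unname(seg$period_split), c(750L, 1000L))
  expect_equal(seg$onset_index, 751L)
  # slice oracle: trial equals the directly indexed window
  expect_equal(unname(seg$trials[[1]][1, ]), as.numeric(sig[1, 250:1999]))
  tiny <- segment_trials(rec, onsets = 100, pre_s = 0.004, post_s = 0.004)
  expect_equal(ncol(tiny$trials[[1]]), 2L)
  expect_error(segment_trials(rec, onsets = c(100, 2400), pre_s = 3, post_s = 4),
               "2400")
  # many onsets: each trial equals its slice
  ons <- seq(800, 1600, by = 40)
  seg50 <- segment_trials(rec, ons, pre_s = 1, post_s = 1)
  for (k in c(1, 10, 21)) {
    expect_equal(unname(seg50$trials[[1]][k, ]),
                 as.numeric(sig[1, (ons[k] - 250):(ons[k] + 249)]))
  }
})

test_that("baseline correction zeroes the preparation-window mean", {
  rec <- new_raw_recording(matrix(2, 1, 1000), fs = 100)
  seg <- segment_trials(rec, onsets = 500, pre_s = 2, post_s = 2)
  out <- baseline_correct(seg)
  expect_true(all(out$trials[[1]] == 0))
  # oscillation preserved, offset removed
  rec2 <- new_raw_recording(matrix(sine_at(7, 100, 1000) + 3, 1), fs = 100)
  seg2 <- baseline_correct(segment_trials(rec2, onsets = 500, pre_s = 2, post_s = 2))
  base <- seg2$trials[[1]][1, 1:200]
  expect_lt(abs(mean(base)), 0.05)
  expect_equal(sd(seg2$trials[[1]][1, ]), sd(sine_at(7, 100, 400)),
               tolerance = 0.01)
  expect_error(baseline_correct(seg, window = integer(0)), "empty")
})

test_that("normalization is a per-channel z-score, scale-invariant, idempotent", {
  set.seed(8)
  rec <- new_raw_recording(rbind(rnorm(2000, sd = 1e-6),   # "uV" channel
                                 rnorm(2000, sd = 1e-3)),  # "mV" channel
                           fs = 250)
  seg <- segment_trials(rec, onsets = c(500, 1200), pre_s = 1, post_s = 1)
  norm <- normalize_amplitude(seg)
  for (ch in 1:2) {
    v <- as.vector(norm$trials[[ch]])
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  # scale invariance: x1000 input gives the same output to rounding
  rec_k <- rec; rec_k$samples <- rec_k$samples * 1000
  norm_k <- normalize_amplitude(segment_trials(rec_k, c(500, 1200), 1, 1))
  expect_equal(norm$trials, norm_k$trials, tolerance = 1e-10)
  # idempotence
  expect_equal(normalize_amplitude(norm)$trials, norm$trials, tolerance = 1e-10)
  flat <- new_raw_recording(rbind(rep(1, 1000), rnorm(1000)), fs = 100,
                            channel_labels = c("flat", "ok"))
  expect_error(normalize_amplitude(segment_trials(flat, 500, 1, 1)),
               "flat")
})

test_that("trial averaging reduces independent noise as 1/sqrt(n)", {
  base <- sine_at(5, 100, 200)
  m <- matrix(rep(base, 3), nrow = 3, byrow = TRUE)
  seg <- structure(list(trials = list(ch = m), fs = 100, onset_index = 101L,
                        period_split = c(preparation = 100L, execution = 100L),
                        channel_labels = "ch"),
                   class = "trial_segments")
  avg <- average_trials(seg)
  expect_equal(avg$trials[[1]][1, ], base)
  two <- seg; two$trials$ch <- rbind(rep(1, 200), rep(3, 200))
  expect_equal(average_trials(two)$trials[[1]][1, ], rep(2, 200))
  # Monte Carlo: n trials of signal + N(0, sigma) -> residual sd ~ sigma/sqrt(n)
  set.seed(12)
  sigma <- 0.5; n_tr <- 50
  noisy <- seg
  noisy$trials$ch <- t(replicate(n_tr, base + rnorm(200, 0, sigma)))
  resid <- average_trials(noisy)$trials[[1]][1, ] - base
  expect_equal(sd(resid), sigma / sqrt(n_tr), tolerance = 0.2)
})

test_that("the full chain is deterministic and preserves geometry", {
  set.seed(21)
  n <- 25000; fs <- 2500
  rec <- new_raw_recording(rbind(eeg = rnorm(n), emg = rnorm(n)), fs = fs)
  onsets <- c(9000, 16000)
  run <- function() preprocess_chain(rec, onsets, band = c(1, 60),
                                     target_fs = 250, pre_s = 1, post_s = 1.4,
                                     average = FALSE)
  a <- run(); b <- run()
  expect_identical(a, b)
  expect_equal(nrow(a$trials[[1]]), 2L)
  expect_equal(ncol(a$trials[[1]]), 600L)
  expect_equal(unname(a$period_split), c(250L, 350L))
  avg <- preprocess_chain(rec, onsets, band = c(1, 60), target_fs = 250,
                          pre_s = 1, post_s = 1.4, average = TRUE)
  expect_equal(nrow(avg$trials[[1]]), 1L)
})
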