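# Conditioning chain for raw paired recordings: referencing, bandpass,
# downsampling, trial segmentation, baseline correction, amplitude
# normalization and trial averaging. Artifact removal by ICA/IClabel and
# line-noise cleaning are assumed to have happened upstream.

#' Read a delimited multi-channel recording
#'
#' Reads a CSV with one column per channel (header optional) and attaches
#' the declared sampling rate; the rate is never inferred from the file.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param columns Optional character vector of channel names to keep (in
#'   the requested order). Requires a header row.
#' @param header Logical; default `TRUE`.
#' @return A `raw_recording`: `samples` (channels x time matrix), `fs`,
#'   `channel_labels`.
#' @export
read_delimited <- function(path, fs, columns = NULL, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate in Hz")
  df <- tryCatch(
    utils::read.csv(path, header = header, check.names = FALSE),
    error = function(e) stop("parse error reading ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0L || ncol(df) == 0L) stop("parse error: ", path, " has no data rows")
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, names(df))
    if (length(missing_cols) > 0L) {
      stop("missing column(s): ", paste(missing_cols, collapse = ", "),
           " (available: ", paste(names(df), collapse = ", "), ")")
    }
    df <- df[, columns, drop = FALSE]
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop("non-numeric cell in column '", names(df)[j], "' at data row ", bad[1])
      }
      df[[j]] <- vn
    }
  }
  m <- t(as.matrix(df))
  if (anyNA(m)) stop("missing values in ", path)
  new_raw_recording(m, fs, rownames(m))
}

new_raw_recording <- function(samples, fs, channel_labels = NULL) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(samples)))
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("Raw recording: %d channel(s) x %d samples at %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean of the result is zero.
#'
#' @param rec A `raw_recording` with at least 2 channels.
#' @return Re-referenced `raw_recording`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  if (nrow(rec$samples) < 2L) {
    stop("common average reference undefined for a single channel")
  }
  rec$samples <- sweep(rec$samples, 2L, colMeans(rec$samples))
  rec
}

#' Zero-phase bandpass filter
#'
#' Butterworth bandpass (4th-order prototype per pass) applied forward and
#' backward through second-order sections, so the net response is zero-phase
#' and 8th-order in magnitude. Zero phase matters because lagged directed
#' inference downstream must not see filter-induced delays.
#'
#' @param rec A `raw_recording`.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Prototype order per pass, default 4.
#' @return Filtered `raw_recording`.
#' @export
bandpass_filter <- function(rec, low, high, order = 4L) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2 = ", rec$fs / 2,
         " Hz (got ", low, "-", high, ")")
  }
  des <- butter_design(order, c(low, high), rec$fs, "pass")
  # pad by one period of the low edge so slow transients settle off-signal
  pad <- min(ncol(rec$samples) - 1L, ceiling(rec$fs / low))
  rec$samples <- t(apply(rec$samples, 1L, function(ch) sosfiltfilt(des$sos, ch, pad = pad)))
  rec
}

#' Anti-aliased downsampling
#'
#' Lowpass filters at 80% of the target Nyquist rate (zero-phase
#' Butterworth) and then decimates. Only integer decimation factors are
#' supported; upsampling is refused.
#'
#' @param rec A `raw_recording`.
#' @param target_fs Target rate in Hz, `target_fs <= fs`, `fs / target_fs`
#'   an integer.
#' @return Downsampled `raw_recording` with updated `fs`.
#' @export
resample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "raw_recording"))
  if (target_fs > rec$fs) stop("no upsampling: target_fs ", target_fs,
                               " > fs ", rec$fs)
  if (target_fs == rec$fs) return(rec)
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("fs/target_fs = ", factor, " is not an integer decimation factor")
  }
  factor <- as.integer(round(factor))
  des <- butter_design(4L, 0.8 * target_fs / 2, rec$fs, "low")
  keep <- seq.int(1L, ncol(rec$samples), by = factor)
  rec$samples <- t(apply(rec$samples, 1L, function(ch) {
    sosfiltfilt(des$sos, ch)[keep]
  }))
  rec$fs <- target_fs
  rec
}

#' Cut a recording into fixed-geometry trials around event onsets
#'
#' Each trial spans `pre_s` seconds before to `post_s` seconds after its
#' onset sample; the pre-onset part is the movement preparation period and
#' the post-onset part the execution period.
#'
#' @param rec A `raw_recording`.
#' @param onsets Integer sample indices (1-based) of movement start.
#' @param pre_s,post_s Seconds before/after each onset.
#' @return A `trial_segments` object: per-channel trial x time arrays,
#'   `fs`, `onset_index` (sample of movement start within a trial) and
#'   `period_split = c(preparation, execution)` sample counts.
#' @export
segment_trials <- function(rec, onsets, pre_s = 3, post_s = 4) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- ncol(rec$samples)
  n_pre <- round(pre_s * rec$fs)
  n_post <- round(post_s * rec$fs)
  if (n_pre + n_post < 1L) stop("empty segment geometry")
  first <- onsets - n_pre
  last <- onsets + n_post - 1L
  bad <- which(first < 1L | last > n)
  if (length(bad) > 0L) {
    stop("onset(s) too near the recording edge: ",
         paste(onsets[bad], collapse = ", "),
         " (need ", n_pre, " samples before and ", n_post, " after)")
  }
  trials <- lapply(seq_len(nrow(rec$samples)), function(ch) {
    t(vapply(seq_along(onsets),
             function(k) rec$samples[ch, first[k]:last[k]],
             numeric(n_pre + n_post)))
  })
  names(trials) <- rec$channel_labels
  structure(
    list(trials = trials, fs = rec$fs, onset_index = n_pre + 1L,
         period_split = c(preparation = n_pre, execution = n_post),
         channel_labels = rec$channel_labels),
    class = "trial_segments"
  )
}

#' @export
print.trial_segments <- function(x, ...) {
  n_tr <- nrow(x$trials[[1L]])
  len <- ncol(x$trials[[1L]])
  cat(sprintf("Trial segments: %d trial(s) x %d samples, %d channel(s) at %g Hz\n",
              n_tr, len, length(x$trials), x$fs))
  cat(sprintf("  split: %d preparation + %d execution samples\n",
              x$period_split[[1L]], x$period_split[[2L]]))
  invisible(x)
}

#' Baseline-correct trials
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (default: the whole preparation period).
#'
#' @param segments A `trial_segments`.
#' @param window Optional integer sample range within the trial to use as
#'   baseline; default `1:period_split["preparation"]`.
#' @return Corrected `trial_segments`.
#' @export
baseline_correct <- function(segments, window = NULL) {
  stopifnot(inherits(segments, "trial_segments"))
  if (is.null(window)) window <- seq_len(segments$period_split[[1L]])
  if (length(window) == 0L) stop("baseline window is empty")
  segments$trials <- lapply(segments$trials, function(m) {
    m - rowMeans(m[, window, drop = FALSE])
  })
  segments
}

#' Normalize amplitudes to a common scale
#'
#' Z-scores each channel over all its trials concatenated (mean 0, sd 1),
#' removing the unit mismatch between e.g. microvolt EEG and millivolt EMG
#' while keeping preparation and execution on one scale.
#'
#' @param segments A `trial_segments`.
#' @return Normalized `trial_segments`.
#' @export
normalize_amplitude <- function(segments) {
  stopifnot(inherits(segments, "trial_segments"))
  segments$trials <- lapply(seq_along(segments$trials), function(i) {
    m <- segments$trials[[i]]
    s <- stats::sd(as.vector(m))
    if (!is.finite(s) || s == 0) {
      stop("zero-variance channel '", names(segments$trials)[i],
           "': cannot normalize")
    }
    (m - mean(m)) / s
  })
  names(segments$trials) <- segments$channel_labels
  segments
}

#' Average trials pointwise
#'
#' Superimposes and averages all trials of each channel, suppressing
#' activity not phase-locked to the onset (background noise shrinks as
#' `1/sqrt(n_trials)`).
#'
#' @param segments A `trial_segments`.
#' @return A `trial_segments` with a single (averaged) trial per channel.
#' @export
average_trials <- function(segments) {
  stopifnot(inherits(segments, "trial_segments"))
  lens <- vapply(segments$trials, ncol, integer(1))
  if (length(unique(lens)) != 1L) stop("ragged trials: differing lengths")
  segments$trials <- lapply(segments$trials, function(m) {
    matrix(colMeans(m), nrow = 1L)
  })
  names(segments$trials) <- segments$channel_labels
  segments
}

#' Full preprocessing chain
#'
#' Convenience wrapper running common average reference (EEG channels only,
#' skipped when fewer than 2 channels are tagged), bandpass, downsampling,
#' segmentation, baseline correction, normalization and (optionally) trial
#' averaging, in that order. Baseline correction precedes normalization;
#' the chain is fully deterministic.
#'
#' @param rec A `raw_recording`.
#' @param onsets Onset sample indices (at the *original* rate).
#' @param band Bandpass edges in Hz, default `c(1, 60)`.
#' @param target_fs Analysis rate in Hz, default 250.
#' @param pre_s,post_s Segment geometry in seconds, defaults 3 and 4.
#' @param car Logical, apply common average referencing first (default
#'   `TRUE` when the recording has >= 2 channels).
#' @param average Logical, average trials at the end (default `TRUE`).
#' @return A `trial_segments` object.
#' @export
preprocess_chain <- function(rec, onsets, band = c(1, 60), target_fs = 250,
                             pre_s = 3, post_s = 4,
                             car = nrow(rec$samples) >= 2L, average = TRUE) {
  stopifnot(inherits(rec, "raw_recording"))
  if (isTRUE(car)) rec <- common_average_reference(rec)
  rec <- bandpass_filter(rec, band[1], band[2])
  ratio <- rec$fs / target_fs
  rec <- resample(rec, target_fs)
  onsets <- as.integer(round((onsets - 1L) / ratio)) + 1L
  seg <- segment_trials(rec, onsets, pre_s, post_s)
  seg <- baseline_correct(seg)
  seg <- normalize_amplitude(seg)
  if (isTRUE(average)) seg <- average_trials(seg)
  seg
}
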