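#' Preprocessing configuration
#'
#' Settings for the shared ERP/ErPR preprocessing path: resampling to a common
#' rate, zero-phase Butterworth band-pass filtering of the EEG, epoch span and
#' baseline window, and blink handling for the pupil trace.
#'
#' Epochs span -200 to +800 ms around stimulus onset so that all three feature
#' windows (P3a 200-350, P3b 400-490, LPP 530-750 ms) fit inside the epoch
#' with the 200 ms pre-stimulus baseline.
#'
#' @param target_rate Common analysis rate, Hz (EEG is downsampled to it).
#' @param band_low,band_high Band-pass edges, Hz; must satisfy
#'   `band_low < band_high < target_rate/2`. Set `band_low = NULL` to skip
#'   filtering entirely.
#' @param filter_order Butterworth design order.
#' @param epoch_start,epoch_end Epoch span relative to onset, ms.
#' @param baseline_window Two-element vector, ms; samples with
#'   `t >= baseline_window[1] & t < baseline_window[2]` form the baseline.
#'   `NULL` skips baseline correction.
#' @param blink_interpolation `"linear"` (interpolate across invalid gaps
#'   before differencing) or `"none"`.
#' @param epoch_reject_threshold Absolute-amplitude rejection threshold in
#'   signal units, or `NULL` (off). A documented automated stand-in for
#'   manual artifact screening.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 200,
                              band_low = 0.1,
                              band_high = 50,
                              filter_order = 4,
                              epoch_start = -200,
                              epoch_end = 800,
                              baseline_window = c(-200, 0),
                              blink_interpolation = c("linear", "none"),
                              epoch_reject_threshold = NULL) {
  blink_interpolation <- match.arg(blink_interpolation)
  if (!is.null(band_low)) {
    if (band_low <= 0 || band_high <= band_low ||
        band_high >= target_rate / 2) {
      config_stop("band_low/band_high",
                  "must satisfy 0 < low < high < target_rate/2")
    }
  }
  if (epoch_start >= epoch_end) {
    config_stop("epoch_start", "must be earlier than `epoch_end`")
  }
  if (!is.null(baseline_window) &&
      (baseline_window[1] < epoch_start || baseline_window[2] > 0 ||
       baseline_window[1] >= baseline_window[2])) {
    config_stop("baseline_window",
                paste("must be an increasing interval within",
                      "[epoch_start, 0], or NULL to skip baseline correction"))
  }
  structure(
    list(target_rate = target_rate, band_low = band_low,
         band_high = band_high, filter_order = filter_order,
         epoch_start = epoch_start, epoch_end = epoch_end,
         baseline_window = baseline_window,
         blink_interpolation = blink_interpolation,
         epoch_reject_threshold = epoch_reject_threshold),
    class = "preprocess_config"
  )
}

# Zero-phase filtering with odd (anti-symmetric) edge extension, which
# preserves the signal level and slope at the boundaries and so avoids the
# start-up transients of plain forward-backward filtering.
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(as.numeric(signal::filtfilt(filt, x)))
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(filt, ext)
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Anti-aliased downsampling
#'
#' Low-pass filters at 80% of the target Nyquist frequency (zero-phase,
#' 8th-order Butterworth) and interpolates at the target sample times
#' `0, 1/to_rate, 2/to_rate, ...`, so downstream event alignment is exact.
#'
#' @param x Numeric series.
#' @param from_rate,to_rate Sampling rates, Hz; `to_rate <= from_rate`.
#' @return Series of length `round(length(x) * to_rate / from_rate)`.
#' @export
resample_series <- function(x, from_rate, to_rate) {
  if (to_rate > from_rate) {
    stop("upsampling is not supported (`to_rate` > `from_rate`)",
         call. = FALSE)
  }
  n_out <- round(length(x) * to_rate / from_rate)
  if (to_rate == from_rate) return(x[seq_len(n_out)])
  lp <- signal::butter(8, 0.8 * to_rate / from_rate, type = "low")
  y <- filtfilt_padded(lp, x, pad = ceiling(40 * from_rate / to_rate))
  t_in <- (seq_along(x) - 1) / from_rate
  t_out <- (seq_len(n_out) - 1) / to_rate
  stats::approx(t_in, y, xout = t_out, rule = 2)$y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applied forward and backward (`signal::filtfilt`) so that peak latencies
#' are not shifted by the filter's phase response.
#'
#' @param x Numeric series.
#' @param rate Sampling rate, Hz.
#' @param low,high Band edges, Hz.
#' @param order Butterworth design order (default 4).
#' @return Filtered series, same length.
#' @export
bandpass_filter <- function(x, rate, low = 0.1, high = 50, order = 4) {
  if (low <= 0 || high <= low || high >= rate / 2) {
    stop("band edges must satisfy 0 < low < high < rate/2", call. = FALSE)
  }
  if (length(x) <= 3 * order) {
    stop("series too short for the requested filter order", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  # pad by a few time constants of the low band edge
  filtfilt_padded(bf, x, pad = ceiling(3 * rate / low))
}

#' Interpolate invalid (blink) samples
#'
#' Linear interpolation across `NA` runs; leading/trailing gaps are filled by
#' the nearest valid value.
#'
#' @param x Series with `NA` marking invalid samples.
#' @param max_gap Longest gap (in samples) that may be bridged; longer gaps
#'   raise an error. `NULL` disables the cap.
#' @return Series without `NA`s.
#' @export
interpolate_blinks <- function(x, max_gap = NULL) {
  ok <- !is.na(x)
  if (sum(ok) < 2) {
    stop("fewer than 2 valid samples; cannot interpolate", call. = FALSE)
  }
  if (!is.null(max_gap)) {
    r <- rle(!ok)
    gaps <- r$lengths[r$values]
    if (length(gaps) && max(gaps) > max_gap) {
      stop(sprintf("blink gap of %d samples exceeds `max_gap` = %d",
                   max(gaps), max_gap), call. = FALSE)
    }
  }
  idx <- seq_along(x)
  stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
}

#' Pupil size change (frame difference)
#'
#' `PSC[i] = diameter[i] - diameter[i-1]`; the i-th difference carries the
#' timestamp of sample `i`, so the PSC series starts one frame after the
#' diameter series.
#'
#' @param x Pupil diameter series (no `NA`; interpolate blinks first).
#' @param rate Sampling rate, Hz.
#' @return List with `values` (length `length(x) - 1`), `rate` and `t0`
#'   (time of the first PSC sample, seconds).
#' @export
compute_psc <- function(x, rate) {
  if (anyNA(x)) {
    stop("diameter series contains invalid samples; interpolate blinks first",
         call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  list(values = diff(x), rate = rate, t0 = 1 / rate)
}

#' Extract event-locked epochs
#'
#' Cuts one fixed-length segment per event from a uniformly sampled series.
#' The onset sample is the nearest sample to the event time, ties resolved to
#' the earlier sample. Overlapping epochs are permitted (RSVP onsets are
#' 200 ms apart while epochs span 1 s). Events whose window would exceed the
#' recording are excluded and counted.
#'
#' @param values Numeric matrix (samples x channels) or vector.
#' @param rate Sampling rate, Hz.
#' @param events Event table with columns `onset_ms` and `label`.
#' @param config A [preprocess_config()].
#' @param t0 Time of the first sample, seconds (nonzero for PSC series).
#' @param channels Channel names (defaults to matrix column names).
#' @param subject_id,modality Metadata stored on the result.
#' @return An object of class `epoch_set`: `data` is an array
#'   `[epochs x samples x channels]`, `time_ms` the epoch time axis relative
#'   to onset, `labels` the per-epoch condition, `events` the retained event
#'   rows, `n_excluded` the number of out-of-range events.
#' @export
extract_epochs <- function(values, rate, events, config = preprocess_config(),
                           t0 = 0, channels = NULL,
                           subject_id = NA_character_,
                           modality = NA_character_) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (is.null(channels)) {
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  }
  n <- nrow(values)
  start_off <- round(config$epoch_start / 1000 * rate)
  n_samp <- round((config$epoch_end - config$epoch_start) / 1000 * rate)
  time_ms <- (start_off + seq_len(n_samp) - 1) / rate * 1000

  # nearest sample to the event time; exact midpoints go to the earlier sample
  rel <- events$onset_ms / 1000 - t0
  idx0 <- ceiling(rel * rate - 0.5) + 1L
  first <- idx0 + start_off
  last <- first + n_samp - 1L
  keep <- first >= 1L & last <= n
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("extract_epochs: excluded %d event(s) outside the recording",
                    n_excluded))
  }
  ev_keep <- events[keep, , drop = FALSE]
  data <- array(NA_real_, c(sum(keep), n_samp, ncol(values)),
                dimnames = list(NULL, NULL, channels))
  fk <- first[keep]
  for (e in seq_len(sum(keep))) {
    data[e, , ] <- values[fk[e]:(fk[e] + n_samp - 1L), , drop = FALSE]
  }
  structure(
    list(data = data, time_ms = time_ms, rate = rate,
         labels = ev_keep$label, events = ev_keep, channels = channels,
         n_excluded = n_excluded, subject_id = subject_id,
         modality = modality, baseline_corrected = FALSE),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "epoch_set: %d epochs x %d samples x %d channel(s) [%s], %d target / %d nontarget\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    paste(x$channels, collapse = ", "),
    sum(x$labels == "target"), sum(x$labels == "nontarget")
  ))
  invisible(x)
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus baseline
#' window. Idempotent: correcting twice equals correcting once.
#'
#' @param epochs An `epoch_set`.
#' @param baseline_window Two-element vector in ms (`t >= w[1] & t < w[2]`).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$time_ms >= baseline_window[1] &
    epochs$time_ms < baseline_window[2]
  if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
  for (ch in seq_len(dim(epochs$data)[3])) {
    bl <- rowMeans(epochs$data[, sel, ch, drop = FALSE])
    epochs$data[, , ch] <- epochs$data[, , ch] - bl
  }
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Reject epochs exceeding an absolute-amplitude threshold
#'
#' Automated stand-in for manual artifact screening: drops every epoch whose
#' absolute amplitude exceeds `threshold` in any channel.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Absolute amplitude bound, signal units.
#' @return The pruned `epoch_set` (rejected count added to `n_excluded`).
#' @export
reject_epochs <- function(epochs, threshold) {
  stopifnot(inherits(epochs, "epoch_set"))
  bad <- apply(abs(epochs$data), 1, max) > threshold
  epochs$data <- epochs$data[!bad, , , drop = FALSE]
  epochs$labels <- epochs$labels[!bad]
  epochs$events <- epochs$events[!bad, , drop = FALSE]
  epochs$n_excluded <- epochs$n_excluded + sum(bad)
  epochs
}

#' Average epochs per condition
#'
#' Pointwise arithmetic mean of all epochs of each label; the averaged target
#' epoch is the ERP (or ErPR, for pupil-size-change epochs).
#'
#' @param epochs An `epoch_set`.
#' @param which_epochs Optional logical or integer subset of epochs to
#'   average (used by trial sweeps).
#' @return An object of class `avg_epochs`: list with per-label matrices
#'   (samples x channels), `time_ms`, `channels`, `n_used` counts, and
#'   metadata.
#' @export
average_epochs <- function(epochs, which_epochs = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  data <- epochs$data
  labels <- epochs$labels
  if (!is.null(which_epochs)) {
    data <- data[which_epochs, , , drop = FALSE]
    labels <- labels[which_epochs]
  }
  out <- list()
  n_used <- c()
  for (lb in c("target", "nontarget")) {
    sel <- labels == lb
    if (!any(sel)) {
      stop(sprintf("no usable epochs for label '%s'", lb), call. = FALSE)
    }
    m <- apply(data[sel, , , drop = FALSE], c(2, 3), mean)
    colnames(m) <- epochs$channels
    out[[lb]] <- m
    n_used[lb] <- sum(sel)
  }
  structure(
    list(target = out$target, nontarget = out$nontarget,
         time_ms = epochs$time_ms, channels = epochs$channels,
         n_used = n_used, subject_id = epochs$subject_id,
         modality = epochs$modality),
    class = "avg_epochs"
  )
}

#' Preprocess one subject recording into averaged ERP and ErPR epochs
#'
#' ERP path: downsample each EEG channel to `target_rate`, band-pass filter
#' (zero-phase Butterworth), epoch around every stimulus onset, baseline
#' correct, and average per condition. ErPR path: interpolate blink gaps in
#' the pupil diameter trace, difference it into the pupil-size-change (PSC)
#' series, epoch, baseline correct, and average. Both paths share the
#' epoch/baseline/average implementation.
#'
#' @param recording A `subject_recording` (or an equivalent list with `eeg`,
#'   `pupil`, `events`, `subject_id`).
#' @param config A [preprocess_config()].
#' @param keep_epochs Keep the per-event epoch sets (needed for trial
#'   sweeps) in addition to the averages.
#' @return List with `erp` and `erpr` (`avg_epochs`), counts, and when
#'   `keep_epochs = TRUE` also `erp_epochs` / `erpr_epochs`.
#' @export
preprocess_subject <- function(recording, config = preprocess_config(),
                               keep_epochs = FALSE) {
  eeg <- recording$eeg
  n_out <- round(nrow(eeg$values) * config$target_rate / eeg$rate)
  eeg_ds <- matrix(0, n_out, ncol(eeg$values),
                   dimnames = list(NULL, colnames(eeg$values)))
  for (ch in seq_len(ncol(eeg$values))) {
    x <- resample_series(eeg$values[, ch], eeg$rate, config$target_rate)
    if (!is.null(config$band_low)) {
      x <- bandpass_filter(x, config$target_rate, config$band_low,
                           config$band_high, config$filter_order)
    }
    eeg_ds[, ch] <- x
  }
  erp_ep <- extract_epochs(eeg_ds, config$target_rate, recording$events,
                           config, subject_id = recording$subject_id,
                           modality = "ERP")
  if (!is.null(config$baseline_window)) {
    erp_ep <- baseline_correct(erp_ep, config$baseline_window)
  }
  if (!is.null(config$epoch_reject_threshold)) {
    erp_ep <- reject_epochs(erp_ep, config$epoch_reject_threshold)
  }

  pup <- recording$pupil$values
  if (anyNA(pup)) {
    if (config$blink_interpolation == "none") {
      stop("pupil trace contains blink gaps but blink_interpolation = 'none'",
           call. = FALSE)
    }
    pup <- interpolate_blinks(pup)
  }
  if (recording$pupil$rate != config$target_rate) {
    pup <- resample_series(pup, recording$pupil$rate, config$target_rate)
  }
  psc <- compute_psc(pup, config$target_rate)
  erpr_ep <- extract_epochs(psc$values, psc$rate, recording$events, config,
                            t0 = psc$t0, channels = "pupil",
                            subject_id = recording$subject_id,
                            modality = "ErPR")
  if (!is.null(config$baseline_window)) {
    erpr_ep <- baseline_correct(erpr_ep, config$baseline_window)
  }

  out <- list(
    erp = average_epochs(erp_ep),
    erpr = average_epochs(erpr_ep),
    subject_id = recording$subject_id,
    n_epochs = c(erp = dim(erp_ep$data)[1], erpr = dim(erpr_ep$data)[1]),
    n_excluded = c(erp = erp_ep$n_excluded, erpr = erpr_ep$n_excluded)
  )
  if (keep_epochs) {
    out$erp_epochs <- erp_ep
    out$erpr_epochs <- erpr_ep
  }
  out
}
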