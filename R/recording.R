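#' Multichannel EEG recording container
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique channel labels.
#' @param events data.frame with columns `onset` (seconds from recording
#'   start) and `condition` (e.g. "right", "left", "rest").
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channels = rownames(signal),
                          events = data.frame(onset = numeric(),
                                              condition = character())) {
  signal <- as.matrix(signal)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(signal)))
  stopifnot(is_scalar_number(fs), fs > 0,
            length(channels) == nrow(signal),
            !anyDuplicated(channels),
            all(c("onset", "condition") %in% names(events)))
  dur <- ncol(signal) / fs
  if (nrow(events) && (any(events$onset < 0) || any(events$onset > dur)))
    stop("all events must lie inside the recording span")
  rownames(signal) <- channels
  structure(list(signal = signal, fs = fs, channels = channels,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channel(s) [%s], %.1f s at %g Hz, %d event(s)\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              ncol(x$signal) / x$fs, x$fs, nrow(x$events)))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order (by default) zero-phase non-causal Butterworth band-pass
#' applied per channel; used as 0.5-45 Hz to remove DC offset and
#' high-frequency noise while keeping the broadband dynamics.  Event times
#' are unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order designed filter order before forward-backward doubling.
#' @return filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 45, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  filt <- butter_filter(order, c(low, high), rec$fs, "pass")
  rec$signal <- t(apply(rec$signal, 1L, function(ch) filtfilt_sos(filt, ch)))
  rec
}

#' Zero-phase notch filter
#'
#' Removes power-line interference with a narrow Butterworth band-stop
#' (default 2 Hz wide) centred at `freq`.
#'
#' @param rec an [eeg_recording()].
#' @param freq centre frequency in Hz (default 50, European mains).
#' @param bandwidth stop-band width in Hz.
#' @param order designed band-stop order.
#' @return filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, freq = 50, bandwidth = 2, order = 2L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(freq > 0 && freq + bandwidth / 2 < rec$fs / 2))
    stop("notch frequency must lie below the Nyquist frequency")
  filt <- butter_filter(order, freq + c(-1, 1) * bandwidth / 2, rec$fs,
                        "stop")
  rec$signal <- t(apply(rec$signal, 1L, function(ch)
    filtfilt_sos(filt, ch, padlen = min(ncol(rec$signal) - 1L,
                                        10L * as.integer(rec$fs)))))
  rec
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (8th-order Butterworth at 45%
#' of the target Nyquist rate) and keeps every `fs/target_fs`-th sample.
#' Event times are expressed in seconds and are unchanged.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs new sampling rate; must divide `rec$fs`.
#' @return downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target_fs = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs >= rec$fs) stop("target_fs must be below the current rate")
  if (rec$fs %% target_fs != 0)
    stop("target_fs must divide the current sampling rate")
  factor <- rec$fs / target_fs
  filt <- butter_filter(8L, 0.45 * target_fs, rec$fs, "low")
  keep <- seq(1L, ncol(rec$signal), by = factor)
  rec$signal <- t(apply(rec$signal, 1L, function(ch)
    filtfilt_sos(filt, ch, padlen = min(ncol(rec$signal) - 1L, 256L))))[,
      keep, drop = FALSE]
  rownames(rec$signal) <- rec$channels
  rec$fs <- target_fs
  rec
}

#' Epoch a recording into onset-locked trials
#'
#' One trial per event, time-locked to the event onset over `span`
#' seconds (default -3 to +3).  Events too close to the recording edges
#' are dropped with a warning.  Rest trials are expected to carry
#' surrogate onset markers (drawn from the movement-onset latency
#' distribution, see [synthesize_movement_dataset()]).
#'
#' @param rec an [eeg_recording()].
#' @param span numeric length-2, trial span in seconds relative to onset.
#' @return object of class `trial_set`: `data` (trials x channels x
#'   samples array), `condition`, `onset`, `time` (seconds relative to
#'   onset), `fs`, `channels`.
#' @export
epoch_trials <- function(rec, span = c(-3, 3)) {
  stopifnot(inherits(rec, "eeg_recording"), length(span) == 2L,
            span[1] < span[2])
  fs <- rec$fs
  n_samp <- as.integer(round((span[2] - span[1]) * fs))
  total <- ncol(rec$signal)
  keep <- logical(nrow(rec$events))
  starts <- integer(nrow(rec$events))
  for (i in seq_len(nrow(rec$events))) {
    i0 <- as.integer(round((rec$events$onset[i] + span[1]) * fs)) + 1L
    if (i0 >= 1L && i0 + n_samp - 1L <= total) {
      keep[i] <- TRUE
      starts[i] <- i0
    }
  }
  if (any(!keep))
    warning(sum(!keep), " event(s) too close to the recording edge; dropped")
  idx <- which(keep)
  dat <- array(NA_real_,
               dim = c(length(idx), length(rec$channels), n_samp),
               dimnames = list(NULL, rec$channels, NULL))
  for (j in seq_along(idx)) {
    rngs <- starts[idx[j]]:(starts[idx[j]] + n_samp - 1L)
    dat[j, , ] <- rec$signal[, rngs, drop = FALSE]
  }
  structure(list(data = dat,
                 condition = rec$events$condition[idx],
                 onset = rec$events$onset[idx],
                 time = span[1] + (seq_len(n_samp) - 1L) / fs,
                 fs = fs, channels = rec$channels),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d trial(s) x %d channel(s) x %d samples (%.2f..%.2f s, %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time), max(x$time), x$fs))
  if (length(x$condition)) print(table(x$condition))
  invisible(x)
}

#' Causal sliding windows over a single-channel trial
#'
#' The window labelled `t` covers `[t - length, t]`, so every feature is
#' computed causally; windows advance by `step` (default 100 ms, i.e. new
#' features every 100 ms).  For a 6 s trial with 2 s windows this yields
#' 41 windows labelled -1.0 ... +3.0 s relative to movement onset.
#'
#' @param x numeric single-channel series.
#' @param fs sampling rate in Hz.
#' @param length_s window length in seconds (default 2).
#' @param step_s window step in seconds (default 0.1).
#' @param t_start time (seconds, relative to onset) of the first sample of
#'   `x`; window labels are `t_start + length_s + k*step_s`.
#' @param channel optional channel label carried in the result.
#' @return object of class `window_set`: `data` (windows x samples
#'   matrix), `t` (window end-time labels), `fs`, `channel`.
#' @export
sliding_windows <- function(x, fs, length_s = 2, step_s = 0.1,
                            t_start = -3, channel = NA_character_) {
  x <- as.numeric(x)
  n <- length(x)
  wlen <- as.integer(round(length_s * fs))
  if (n < wlen) stop("trial shorter than the window length")
  n_win <- floor((n - wlen) / (step_s * fs) + 1e-9) + 1L
  dat <- matrix(NA_real_, nrow = n_win, ncol = wlen)
  for (k in seq_len(n_win)) {
    off <- as.integer(round((k - 1L) * step_s * fs))
    dat[k, ] <- x[(off + 1L):(off + wlen)]
  }
  structure(list(data = dat,
                 t = t_start + length_s + (seq_len(n_win) - 1L) * step_s,
                 fs = fs, length_s = length_s, step_s = step_s,
                 channel = channel),
            class = "window_set")
}

#' Single analysis window
#'
#' A 2 s single-channel segment ending at time `t` relative to movement
#' onset; the unit on which all per-window features (H, ARFIMA, ERD) are
#' computed.
#'
#' @param samples numeric vector.
#' @param fs sampling rate in Hz.
#' @param t window end time in seconds relative to onset.
#' @param channel channel label.
#' @export
analysis_window <- function(samples, fs, t = NA_real_,
                            channel = NA_character_) {
  stopifnot(is.numeric(samples), is_scalar_number(fs))
  structure(list(samples = as.numeric(samples), fs = fs, t = t,
                 channel = channel),
            class = "analysis_window")
}
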