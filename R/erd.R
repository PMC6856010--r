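# Percent event-related desynchronization of alpha-band power against a
# resting-state baseline.

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation; `Mod(hilbert_analytic(x))` is the instantaneous
#' amplitude envelope.
#'
#' @param x numeric series.
#' @return complex analytic signal.
#' @keywords internal
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# analytic signal of each column of a matrix
.hilbert_analytic_mat <- function(M) {
  n <- nrow(M)
  X <- stats::mvfft(M)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Alpha-band power of one analysis window
#'
#' The window is demeaned, band-pass filtered (zero-phase Butterworth,
#' default 8-13 Hz), and the band amplitude is taken as the absolute value
#' of the Hilbert transform; power is the mean squared amplitude.  Because
#' the Hilbert envelope is unreliable at segment edges, the outermost 5%
#' of samples on each side are excluded from the mean (the filter itself
#' is applied with reflection padding).
#'
#' @param window numeric series or [analysis_window()].
#' @param fs sampling rate in Hz (taken from the window if available).
#' @param band length-2 numeric, band edges in Hz.
#' @param edge_frac fraction of samples trimmed from each end of the
#'   envelope before averaging (default 0.05).
#' @return scalar band power (signal units squared).
#' @export
alpha_band_power <- function(window, fs = NULL, band = c(8, 13),
                             edge_frac = 0.05) {
  x <- if (inherits(window, "analysis_window")) {
    fs <- fs %||% window$fs
    window$samples
  } else as.numeric(window)
  fs <- fs %||% 128
  if (band[2] >= fs / 2) stop("band edge at or above the Nyquist frequency")
  n <- length(x)
  x <- x - mean(x)
  filt <- butter_filter(4L, band, fs, "pass")
  xb <- filtfilt_sos(filt, x, padlen = min(n - 1L, as.integer(fs)))
  env <- Mod(hilbert_analytic(xb))
  trim <- floor(edge_frac * n)
  inner <- (trim + 1L):(n - trim)
  mean(env[inner]^2)
}

#' Resting-state baseline band power
#'
#' The baseline `R` is the mean alpha power over every sliding window of
#' every resting-state trial, computed per channel (and per participant by
#' construction, since a `trial_set` belongs to one recording).
#'
#' @param rest a `trial_set` containing resting-state trials (any
#'   non-rest trials present are ignored).
#' @param channel channel label or index.
#' @param band,length_s,step_s window parameters as in the main pipeline.
#' @return scalar baseline power.
#' @export
resting_baseline <- function(rest, channel, band = c(8, 13),
                             length_s = 2, step_s = 0.1) {
  stopifnot(inherits(rest, "trial_set"))
  idx <- which(rest$condition == "rest")
  if (!length(idx)) idx <- seq_along(rest$condition)
  if (!length(idx)) stop("no resting-state trials to compute a baseline from")
  pows <- unlist(lapply(idx, function(i) {
    ws <- sliding_windows(rest$data[i, channel, ], rest$fs,
                          length_s = length_s, step_s = step_s,
                          t_start = min(rest$time))
    apply(ws$data, 1L, alpha_band_power, fs = rest$fs, band = band)
  }))
  mean(pows)
}

#' Percent ERD from band power and baseline
#'
#' \eqn{ERD_t = 100 (A_t - R) / R}; negative values indicate
#' desynchronization (power loss relative to rest).
#'
#' @param A_t band power (scalar or vector).
#' @param R baseline power, must be positive.
#' @return percent ERD, same shape as `A_t`.
#' @export
erd_percent <- function(A_t, R) {
  if (!is_scalar_number(R) || R <= 0)
    stop("baseline power R must be a positive number")
  100 * (A_t - R) / R
}

#' ERD time course for every trial and channel
#'
#' Slides 2 s windows over each trial and channel and converts band power
#' to percent ERD against the per-channel resting baseline.  Also applies
#' to fractionally differenced trials (used to probe the effect of LRTC
#' removal on ERD).
#'
#' @param trials a `trial_set`.
#' @param R named numeric vector of baselines, one per channel (or a
#'   single scalar reused for all channels).
#' @param band,length_s,step_s window parameters.
#' @return data.frame with columns `trial`, `condition`, `channel`, `t`,
#'   `band_power`, `erd`.
#' @export
erd_timecourse <- function(trials, R, band = c(8, 13),
                           length_s = 2, step_s = 0.1) {
  stopifnot(inherits(trials, "trial_set"))
  chans <- trials$channels
  if (length(R) == 1L && is.null(names(R)))
    R <- stats::setNames(rep(R, length(chans)), chans)
  out <- list()
  for (ch in seq_along(chans)) {
    Rch <- R[[chans[ch]]]
    for (i in seq_len(dim(trials$data)[1])) {
      ws <- sliding_windows(trials$data[i, ch, ], trials$fs,
                            length_s = length_s, step_s = step_s,
                            t_start = min(trials$time))
      A <- apply(ws$data, 1L, alpha_band_power, fs = trials$fs, band = band)
      out[[length(out) + 1L]] <- data.frame(
        trial = i, condition = trials$condition[i], channel = chans[ch],
        t = ws$t, band_power = A, erd = erd_percent(A, Rch))
    }
  }
  do.call(rbind, out)
}
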