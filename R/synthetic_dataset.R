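#' Configuration for the synthetic movement experiment
#'
#' Defines the ground-truth world the generator emulates: three motor
#' channels at 128 Hz, 40 six-second trials per condition, a broadband
#' 1/f-like ARFIMA background whose fractional-integration parameter d
#' ramps from `d_baseline` to `d_peak` inside `d_ramp_window` around
#' movement onset (long-range correlation increase), and a 10 Hz
#' oscillation whose amplitude is scaled by `1 - alpha_suppression` inside
#' `erd_ramp_window` (event-related desynchronization).  Defaults place
#' the broadband dynamics 0.5 s ahead of the narrowband suppression, and
#' effect sizes at values typical of sensorimotor recordings: rest Hurst
#' exponent near 0.6 rising to about 0.75, 30% alpha suppression, and an
#' alpha amplitude placing roughly 10% of broadband power in the alpha
#' band over central channels (much larger values would make the
#' oscillation, whose detrended fluctuations saturate beyond its period,
#' dominate the DFA scales and mask the programmed broadband scaling).
#'
#' @param n_participants number of simulated participants.
#' @param n_trials_per_condition trials per condition (right/left/rest).
#' @param fs sampling rate in Hz.
#' @param trial_span trial span in seconds around onset.
#' @param channels channel labels.
#' @param d_baseline,d_peak fractional parameter at rest / movement peak;
#'   `0 <= d_baseline <= d_peak < 0.5`.
#' @param d_ramp_window seconds (relative to onset) over which d ramps
#'   linearly from baseline to peak; d stays at peak afterwards.
#' @param alpha_freq oscillation frequency in Hz.
#' @param alpha_amplitude oscillation amplitude in signal units.
#' @param alpha_suppression fractional amplitude drop in `[0, 1]`.
#' @param erd_ramp_window seconds over which the suppression ramps in.
#' @param phase_jitter_sd per-sample random phase-increment sd (radians),
#'   giving the oscillator a realistic finite bandwidth.
#' @param innovation_sd broadband innovation standard deviation.
#' @param het_alpha_amplitude_rel,het_alpha_suppression,het_d between-
#'   participant heterogeneity: per-participant log-normal relative sd of
#'   the alpha amplitude, and additive normal sds of the suppression
#'   fraction and of the d levels (clipped to their valid ranges).  Zero
#'   by default so single-participant properties hold exactly; cohort
#'   analyses enable them to emulate real inter-subject variability.
#' @param seed integer seed; the dataset is a pure function of the config.
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 1L,
                             n_trials_per_condition = 40L,
                             fs = 128,
                             trial_span = c(-3, 3),
                             channels = c("C3", "Cz", "C4"),
                             d_baseline = 0.12,
                             d_peak = 0.25,
                             d_ramp_window = c(-1.5, -0.5),
                             alpha_freq = 10,
                             alpha_amplitude = 0.5,
                             alpha_suppression = 0.3,
                             erd_ramp_window = c(-1, 0),
                             phase_jitter_sd = 0.05,
                             innovation_sd = 1,
                             het_alpha_amplitude_rel = 0,
                             het_alpha_suppression = 0,
                             het_d = 0,
                             seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_trials_per_condition = as.integer(n_trials_per_condition),
              fs = fs, trial_span = trial_span, channels = channels,
              d_baseline = d_baseline, d_peak = d_peak,
              d_ramp_window = d_ramp_window, alpha_freq = alpha_freq,
              alpha_amplitude = alpha_amplitude,
              alpha_suppression = alpha_suppression,
              erd_ramp_window = erd_ramp_window,
              phase_jitter_sd = phase_jitter_sd,
              innovation_sd = innovation_sd,
              het_alpha_amplitude_rel = het_alpha_amplitude_rel,
              het_alpha_suppression = het_alpha_suppression,
              het_d = het_d, seed = as.integer(seed))
  stopifnot(cfg$n_participants >= 1L, cfg$n_trials_per_condition >= 1L,
            cfg$fs > 0, length(cfg$trial_span) == 2L,
            cfg$trial_span[1] < cfg$trial_span[2],
            length(cfg$channels) >= 1L, !anyDuplicated(cfg$channels),
            cfg$alpha_freq > 0, cfg$alpha_freq < cfg$fs / 2,
            cfg$innovation_sd > 0)
  if (!(0 <= cfg$d_baseline && cfg$d_baseline <= cfg$d_peak &&
        cfg$d_peak < 0.5))
    stop("need 0 <= d_baseline <= d_peak < 0.5")
  if (cfg$alpha_suppression < 0 || cfg$alpha_suppression > 1)
    stop("alpha_suppression must lie in [0, 1]")
  trial_len <- diff(cfg$trial_span) * cfg$fs
  if (abs(trial_len - round(trial_len)) > 1e-9)
    stop("fs x trial length must be an integer sample count")
  class(cfg) <- "synthetic_config"
  cfg
}

# linear 0 -> 1 ramp positioned inside [w1, w2] on time axis tt
.ramp01 <- function(tt, w) {
  pmin(1, pmax(0, (tt - w[1]) / max(w[2] - w[1], 1e-12)))
}

# theoretical alpha-band power of fractionally integrated unit white noise:
# spectral density |1 - e^{-i 2 pi f / fs}|^{-2d}, averaged over the band.
# Used to scale the high-d background so the programmed d ramp is neutral
# for narrowband alpha power (the two programmed effects stay independent).
.fracint_band_power <- function(d, fs, band = c(8, 13)) {
  f <- seq(band[1], band[2], length.out = 101)
  mean((2 * sin(pi * f / fs))^(-2 * d))
}

#' Generate a synthetic movement-experiment dataset
#'
#' Builds one continuous recording per participant.  Each trial occupies
#' its own slot (a guard second on each side of the 6 s trial); within a
#' slot the broadband background is produced by fractionally integrating
#' one innovation stream by `d_baseline` and by `d_peak` and cross-fading
#' the two integrated series with the programmed ramp weight, which
#' preserves local scaling while avoiding segment seams.  The high-d
#' series is rescaled so both backgrounds carry the same theoretical
#' alpha-band power: without this the d ramp would tilt the background
#' spectrum into the 8-13 Hz band and the "broadband" and "narrowband"
#' programmed effects would not be independent.  The alpha
#' component is an amplitude-modulated phase-jittered oscillator added on
#' top.  Movement trials carry both the d ramp and the alpha suppression;
#' rest trials are stationary with constant `d = d_baseline` and unscaled
#' alpha.  All channels receive independent noise realizations with the
#' same programmed dynamics.  Event markers (including surrogate rest
#' onsets at the same within-slot latency) are attached to the recording.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with one element per
#'   participant, each a list with `recording` (an [eeg_recording()]) and
#'   `ground_truth` (list: `condition`, `onset`, `d` and `s` matrices of
#'   programmed per-sample fractional parameter and alpha scale, trials x
#'   samples on the trial time axis).
#' @export
synthesize_movement_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$fs
  span <- config$trial_span
  guard <- 1
  slot_len <- diff(span) + 2 * guard
  n_slot <- as.integer(round(slot_len * fs))
  n_trial <- as.integer(round(diff(span) * fs))
  conds <- rep(c("right", "left", "rest"),
               each = config$n_trials_per_condition)
  burn <- 1024L

  participants <- vector("list", config$n_participants)
  for (pp in seq_len(config$n_participants)) with_seed(
    config$seed + 1000L * (pp - 1L), {
    # participant-level parameters (identical to the config unless the
    # heterogeneity sds are set)
    amp_pp <- config$alpha_amplitude *
      exp(stats::rnorm(1, 0, config$het_alpha_amplitude_rel))
    sup_pp <- min(1, max(0, config$alpha_suppression +
                           stats::rnorm(1, 0, config$het_alpha_suppression)))
    dshift <- stats::rnorm(1, 0, config$het_d)
    dbase_pp <- min(0.49, max(0, config$d_baseline + dshift))
    dpeak_pp <- min(0.49, max(dbase_pp, config$d_peak + dshift))
    bg_scale <- sqrt(.fracint_band_power(dbase_pp, fs) /
                       .fracint_band_power(dpeak_pp, fs))
    cond_order <- sample(conds)
    n_tr <- length(cond_order)
    sig <- matrix(0, nrow = length(config$channels),
                  ncol = n_tr * n_slot)
    onsets <- numeric(n_tr)
    d_true <- matrix(NA_real_, n_tr, n_trial)
    s_true <- matrix(NA_real_, n_tr, n_trial)
    # slot time axis relative to onset (onset at guard - span[1] into slot)
    tt_slot <- (seq_len(n_slot) - 1L) / fs - guard + span[1]
    trial_idx <- which(tt_slot >= span[1] - 1e-9 &
                         tt_slot < span[2] - 1e-9)[seq_len(n_trial)]

    for (tr in seq_len(n_tr)) {
      move <- cond_order[tr] != "rest"
      wd <- if (move) .ramp01(tt_slot, config$d_ramp_window) else
        numeric(n_slot)
      s_t <- 1 - (if (move) sup_pp *
                    .ramp01(tt_slot, config$erd_ramp_window) else 0)
      s_t <- rep(s_t, length.out = n_slot)
      for (ch in seq_along(config$channels)) {
        eps <- stats::rnorm(n_slot + burn, sd = config$innovation_sd)
        x_lo <- fractional_integrate(eps, dbase_pp)
        x_hi <- if (dpeak_pp > dbase_pp)
          fractional_integrate(eps, dpeak_pp) * bg_scale else x_lo
        bg <- ((1 - wd) * x_lo[-seq_len(burn)] + wd * x_hi[-seq_len(burn)])
        dphi <- 2 * pi * config$alpha_freq / fs +
          stats::rnorm(n_slot, sd = config$phase_jitter_sd)
        osc <- amp_pp * s_t *
          sin(stats::runif(1, 0, 2 * pi) + cumsum(dphi))
        cols <- ((tr - 1L) * n_slot + 1L):(tr * n_slot)
        sig[ch, cols] <- bg + osc
      }
      onsets[tr] <- (tr - 1L) * slot_len + guard - span[1]
      d_prog <- dbase_pp + wd * (dpeak_pp - dbase_pp)
      d_true[tr, ] <- d_prog[trial_idx]
      s_true[tr, ] <- s_t[trial_idx]
    }
    rec <- eeg_recording(sig, fs = fs, channels = config$channels,
                         events = data.frame(onset = onsets,
                                             condition = cond_order))
    participants[[pp]] <- list(
      recording = rec,
      ground_truth = list(condition = cond_order, onset = onsets,
                          d = d_true, s = s_true,
                          time = span[1] + (seq_len(n_trial) - 1L) / fs,
                          params = list(d_baseline = dbase_pp,
                                        d_peak = dpeak_pp,
                                        alpha_amplitude = amp_pp,
                                        alpha_suppression = sup_pp)))
  })
  structure(participants, class = "synthetic_dataset", config = config)
}

#' Write a synthetic dataset to disk (EDF + TSV)
#'
#' One EDF per participant plus its sidecar event TSV, and the ground
#' truth (programmed condition and onset) as a TSV.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pp in seq_along(dataset)) {
    base <- file.path(dir, sprintf("participant%02d", pp))
    write_edf(dataset[[pp]]$recording, paste0(base, ".edf"))
    gt <- dataset[[pp]]$ground_truth
    utils::write.table(
      data.frame(trial = seq_along(gt$condition), condition = gt$condition,
                 onset_seconds = gt$onset),
      paste0(base, ".ground_truth.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
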