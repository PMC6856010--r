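# Study orchestration: per-participant feature extraction, grand averages,
# and report tables.

#' Study configuration
#'
#' All tunable parameters of the pipeline, with the defaults used
#' throughout: broadband 0.5-45 Hz, 2 s windows stepped by 100 ms over
#' -3..+3 s trials, Hanning-tapered DFA smoothed with lambda = 0.3,
#' ARFIMA(10, d, 0), alpha band 8-13 Hz, 10 x 10-fold cross-validation.
#' Set `bandpass`/`notch`/`downsample_to` to `NULL` to skip those stages
#' (synthetic recordings are generated band-limited at 128 Hz already).
#'
#' @param bandpass band edges in Hz, or `NULL` to skip filtering.
#' @param notch mains frequency in Hz, or `NULL` to skip.
#' @param downsample_to target rate in Hz, or `NULL` to skip.
#' @param span trial span (s, relative to onset).
#' @param window_length,window_step sliding-window geometry in seconds.
#' @param taper Hanning taper before DFA.
#' @param smoothing exponential smoothing factor for the H time course.
#' @param ar_order AR order of the per-window ARFIMA fit.
#' @param erd_band ERD band in Hz.
#' @param diagnostics run per-window residual diagnostics and ADF.
#' @param folds,repeats cross-validation geometry.
#' @param seed base seed for all stochastic stages.
#' @return a `study_config` list.
#' @export
study_config <- function(bandpass = NULL, notch = NULL, downsample_to = NULL,
                         span = c(-3, 3), window_length = 2,
                         window_step = 0.1, taper = TRUE, smoothing = 0.3,
                         ar_order = 10L, erd_band = c(8, 13),
                         diagnostics = TRUE, folds = 10L, repeats = 10L,
                         seed = 1L) {
  cfg <- list(bandpass = bandpass, notch = notch,
              downsample_to = downsample_to, span = span,
              window_length = window_length, window_step = window_step,
              taper = taper, smoothing = smoothing,
              ar_order = as.integer(ar_order), erd_band = erd_band,
              diagnostics = diagnostics, folds = as.integer(folds),
              repeats = as.integer(repeats), seed = as.integer(seed))
  class(cfg) <- "study_config"
  cfg
}

#' Write / read a study configuration as structured text
#'
#' Plain `dput` serialization: human-readable and lossless.
#'
#' @param config a [study_config()].
#' @param path file path.
#' @return the path (write) / the config (read).
#' @export
write_study_config <- function(config, path) {
  dput(unclass(config), file = path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  cfg <- dget(path)
  do.call(study_config, cfg)
}

#' Run the full per-participant feature extraction
#'
#' Optional filtering/downsampling, epoching, then for every trial,
#' channel and 2 s sliding window: the DFA Hurst exponent (tapered,
#' exponentially smoothed along the trial), the two-stage
#' ARFIMA(ar_order, d, 0) fit (d = H - 0.5, fractional differencing, AR
#' least squares, optional ADF + residual diagnostics), and the alpha-band
#' power with percent ERD against the participant's resting baseline.
#'
#' @param rec an [eeg_recording()] with events.
#' @param config a [study_config()].
#' @return long data.frame (the per-window feature store) with columns
#'   `trial`, `condition`, `channel`, `t`, `H`, `H_smooth`, `d`,
#'   `phi1..phi<p>`, `aic`, `ljung_box_p`, `ks_p`, `adf_stationary`,
#'   `band_power`, `erd`.
#' @export
run_participant <- function(rec, config = study_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$signal) == 0 || nrow(rec$events) == 0)
    stop("empty recording (no samples or no events)")
  if (!is.null(config$bandpass))
    rec <- bandpass_filter(rec, config$bandpass[1], config$bandpass[2])
  if (!is.null(config$notch)) rec <- notch_filter(rec, config$notch)
  if (!is.null(config$downsample_to)) rec <- downsample(rec, config$downsample_to)

  trials <- epoch_trials(rec, span = config$span)
  n_tr <- dim(trials$data)[1]
  if (n_tr == 0) stop("no usable trials after epoching")
  p <- config$ar_order
  filt <- butter_filter(4L, config$erd_band, trials$fs, "pass")

  # per-channel resting baseline
  has_rest <- any(trials$condition == "rest")
  R <- stats::setNames(rep(NA_real_, length(trials$channels)),
                       trials$channels)
  wl <- config$window_length; st <- config$window_step

  rows <- vector("list", n_tr * length(trials$channels))
  ri <- 0L
  for (ch in seq_along(trials$channels)) {
    for (i in seq_len(n_tr)) {
      ws <- sliding_windows(trials$data[i, ch, ], trials$fs,
                            length_s = wl, step_s = st,
                            t_start = min(trials$time))
      nw <- nrow(ws$data)
      H <- numeric(nw); dcol <- numeric(nw)
      phis <- matrix(NA_real_, nw, p)
      aics <- lb <- ks <- rep(NA_real_, nw)
      adf_ok <- rep(NA, nw)
      for (k in seq_len(nw)) {
        x <- ws$data[k, ]
        hres <- estimate_hurst(x, taper = config$taper)
        H[k] <- hres$H
        if (!is.na(hres$H)) {
          d <- hres$H - 0.5
          w <- fractional_difference(x - mean(x), d)
          fit <- fit_ar(w, p = p)
          dcol[k] <- d
          phis[k, ] <- fit$phi
          aics[k] <- fit$aic
          if (config$diagnostics) {
            fit <- residual_diagnostics(fit)
            lb[k] <- fit$ljung_box_p
            ks[k] <- fit$ks_p
            adf_ok[k] <- tryCatch(adf_stationarity_test(w)$stationary,
                                  error = function(e) NA)
          }
        } else dcol[k] <- NA_real_
      }
      # alpha power of all windows of the trial in one batch
      wlen_n <- ncol(ws$data)
      Wm <- t(ws$data)
      Wm <- sweep(Wm, 2L, colMeans(Wm))
      Xb <- filtfilt_sos(filt, Wm,
                         padlen = min(wlen_n - 1L, as.integer(trials$fs)))
      env2 <- Mod(.hilbert_analytic_mat(Xb))^2
      trim <- floor(0.05 * wlen_n)
      bp <- colMeans(env2[(trim + 1L):(wlen_n - trim), , drop = FALSE])
      df <- data.frame(trial = i, condition = trials$condition[i],
                       channel = trials$channels[ch], t = ws$t,
                       H = H, H_smooth = smooth_hurst_series(H, config$smoothing),
                       d = dcol, aic = aics, ljung_box_p = lb, ks_p = ks,
                       adf_stationary = adf_ok, band_power = bp)
      colnames(phis) <- paste0("phi", seq_len(p))
      df <- cbind(df, phis)
      ri <- ri + 1L
      rows[[ri]] <- df
    }
  }
  store <- do.call(rbind, rows[seq_len(ri)])

  if (has_rest) {
    for (ch in trials$channels) {
      R[ch] <- mean(store$band_power[store$condition == "rest" &
                                       store$channel == ch])
    }
    store$erd <- 100 * (store$band_power - R[store$channel]) / R[store$channel]
  } else store$erd <- NA_real_
  attr(store, "baseline") <- R
  attr(store, "config") <- config
  store
}

# trials x time matrix of one measure for one condition/channel
trace_matrix <- function(store, measure, condition, channel) {
  sub <- store[store$condition == condition & store$channel == channel, ]
  ts <- sort(unique(sub$t))
  trials <- sort(unique(sub$trial))
  M <- matrix(NA_real_, length(trials), length(ts),
              dimnames = list(trials, format(ts)))
  for (j in seq_along(ts)) {
    sj <- sub[abs(sub$t - ts[j]) < 1e-9, ]
    M[match(sj$trial, trials), j] <- sj[[measure]]
  }
  attr(M, "t") <- ts
  M
}

#' Grand averages across participants
#'
#' Per-participant trial means are averaged across participants (so every
#' participant carries equal weight, matching group-level n = participants
#' testing); movement-vs-rest Mann-Whitney masks use participants as the
#' unit of observation.
#'
#' @param stores list of per-participant feature stores
#'   ([run_participant()]).
#' @param measure column to average (e.g. `"H_smooth"`, `"d"`, `"erd"`).
#' @param channel channel label.
#' @param conditions conditions to summarize.
#' @return list with `t`, per-condition `mean` and `sd` matrices
#'   (conditions x time), `n_participants`, and `masks` (per movement
#'   condition, logical vectors vs rest).
#' @export
grand_average <- function(stores, measure = "H_smooth", channel = "C3",
                          conditions = c("right", "left", "rest")) {
  if (length(stores) < 2L) stop("grand averages need >= 2 participants")
  per_part <- lapply(stores, function(s) {
    sapply(conditions, function(cond) {
      M <- trace_matrix(s, measure, cond, channel)
      colMeans(M, na.rm = TRUE)
    })
  })
  ts <- attr(trace_matrix(stores[[1L]], measure, conditions[1L], channel), "t")
  n_t <- length(ts)
  if (!all(vapply(per_part, nrow, 0L) == n_t))
    stop("participants have mismatched window labels")
  arr <- simplify2array(per_part)   # time x condition x participant
  mean_m <- apply(arr, c(2, 1), mean)
  sd_m <- apply(arr, c(2, 1), stats::sd)
  masks <- list()
  for (cond in setdiff(conditions, "rest")) {
    A <- t(arr[, cond, ])           # participants x time
    B <- t(arr[, "rest", ])
    masks[[cond]] <- if (nrow(A) >= 3L)
      compare_conditions(A, B)$significant else rep(NA, n_t)
  }
  list(t = ts, mean = mean_m, sd = sd_m,
       n_participants = length(stores), masks = masks)
}

#' Classification time course for one participant and feature set
#'
#' Trains an independent LDA per window label and assembles the accuracy
#' time course, the binomial chance threshold, and the detection time.
#'
#' @param store feature store from [run_participant()].
#' @param feature_set see [build_features()].
#' @param movement_condition `"right"` or `"left"`.
#' @param config a [study_config()] (cross-validation geometry and seed).
#' @param alpha significance level of the chance threshold.
#' @return data.frame per window label with accuracy/sensitivity/
#'   specificity (and sds), plus attributes `threshold` and
#'   `detection_time`.
#' @export
classification_timecourse <- function(store, feature_set = "arfima+erd",
                                      movement_condition = "right",
                                      config = study_config(),
                                      alpha = 0.05) {
  ts <- sort(unique(store$t))
  out <- vector("list", length(ts))
  n_trials <- NA_integer_
  for (j in seq_along(ts)) {
    feats <- build_features(store, ts[j], feature_set, movement_condition,
                            seed = config$seed + j)
    met <- train_eval_lda(feats, folds = config$folds,
                          repeats = config$repeats,
                          seed = config$seed + 131L * j)
    n_trials <- length(feats$y)
    out[[j]] <- data.frame(t = ts[j], accuracy = met$accuracy,
                           sensitivity = met$sensitivity,
                           specificity = met$specificity,
                           accuracy_sd = met$accuracy_sd)
  }
  tc <- do.call(rbind, out)
  thr <- chance_threshold(n_trials, alpha)
  attr(tc, "threshold") <- thr
  attr(tc, "detection_time") <- detection_time(tc$accuracy, tc$t, thr)
  tc
}

#' Study report tables
#'
#' (a) Per-feature-set summary of peak accuracies (mean +/- sd across
#' participants, per movement condition), (b) per-participant detection
#' times, (c) single-trial ERD-LRTC correlation and lag summary.
#'
#' @param timecourses nested list:
#'   `timecourses[[feature_set]][[condition]][[participant]]` entries from
#'   [classification_timecourse()].
#' @param stores list of feature stores (for the lag analysis); optional.
#' @param channel channel used for the lag analysis.
#' @return list with `summary` (data.frame), `detection` (data.frame), and
#'   `lag` (list or `NULL`).
#' @export
report <- function(timecourses, stores = NULL, channel = "C3") {
  summ <- list(); det <- list()
  for (fs_name in names(timecourses)) {
    for (cond in names(timecourses[[fs_name]])) {
      tcs <- timecourses[[fs_name]][[cond]]
      peaks <- vapply(tcs, function(tc) max(tc$accuracy), numeric(1))
      peak_sen <- vapply(tcs, function(tc)
        tc$sensitivity[which.max(tc$accuracy)], numeric(1))
      peak_spe <- vapply(tcs, function(tc)
        tc$specificity[which.max(tc$accuracy)], numeric(1))
      dts <- vapply(tcs, function(tc)
        as.numeric(attr(tc, "detection_time") %||% NA_real_), numeric(1))
      summ[[length(summ) + 1L]] <- data.frame(
        feature_set = fs_name, condition = cond,
        accuracy_mean = mean(peaks), accuracy_sd = stats::sd(peaks),
        sensitivity_mean = mean(peak_sen), sensitivity_sd = stats::sd(peak_sen),
        specificity_mean = mean(peak_spe), specificity_sd = stats::sd(peak_spe))
      det[[length(det) + 1L]] <- data.frame(
        feature_set = fs_name, condition = cond,
        participant = seq_along(dts), detection_time = dts)
    }
  }
  lag <- NULL
  if (!is.null(stores)) {
    E <- do.call(rbind, lapply(stores, trace_matrix, measure = "erd",
                               condition = "right", channel = channel))
    L <- do.call(rbind, lapply(stores, trace_matrix, measure = "H_smooth",
                               condition = "right", channel = channel))
    lag <- erd_lrtc_lag_analysis(E, L)
  }
  list(summary = do.call(rbind, summ), detection = do.call(rbind, det),
       lag = lag)
}
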