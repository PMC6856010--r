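# Per-window movement-vs-rest classification with linear discriminant
# analysis, repeated stratified cross-validation, and binomial chance
# thresholds.

.FEATURE_SETS <- list(
  lrtc         = list(H = c("C3", "Cz", "C4")),
  erd          = list(erd = c("C3", "C4")),
  arfima       = list(d = c("C3", "Cz", "C4"),
                      ar = list(channels = c("C3", "Cz", "C4"),
                                orders = 1:6)),
  `lrtc+erd`   = list(H = c("C3", "Cz", "C4"), erd = c("C3", "C4")),
  `arfima+erd` = list(d = c("C3", "Cz", "C4"),
                      ar = list(channels = c("C3", "Cz", "C4"),
                                orders = 1:6),
                      erd = c("C3", "C4"))
)

#' Assemble a per-window feature matrix for movement-vs-rest LDA
#'
#' Feature sets follow the channel selections found most informative:
#' `lrtc` = Hurst exponent at C3, Cz, C4 (3 features); `erd` = percent ERD
#' at C3 and C4 (2); `arfima` = d plus AR coefficients 1-6 from all three
#' channels (21); `lrtc+erd` (5) and `arfima+erd` (23) are the hybrids.
#' Movement rows are all trials of `movement_condition`; an equal number
#' of rest rows is drawn at random (recorded seed) from the resting-state
#' trials so each class contributes the same number of samples.
#'
#' @param store per-window feature store from [run_participant()] (long
#'   data.frame with columns `trial`, `condition`, `channel`, `t`, `H`,
#'   `d`, `phi1`..`phi10`, `erd`).
#' @param t window label to build the matrix for.
#' @param feature_set one of `"lrtc"`, `"erd"`, `"arfima"`, `"lrtc+erd"`,
#'   `"arfima+erd"`.
#' @param movement_condition `"right"` or `"left"`.
#' @param seed seed for the rest-trial draw.
#' @return list with `x` (numeric matrix), `y` (factor movement/rest),
#'   `dropped` (trials removed for missing features).
#' @export
build_features <- function(store, t, feature_set = "arfima+erd",
                           movement_condition = "right", seed = 1L) {
  feature_set <- match.arg(feature_set, names(.FEATURE_SETS))
  spec <- .FEATURE_SETS[[feature_set]]
  sub <- store[abs(store$t - t) < 1e-9, ]
  if (!nrow(sub)) stop("no rows at window label t = ", t)

  wide_one <- function(trial_rows) {
    v <- c()
    for (kind in names(spec)) {
      if (kind == "ar") {
        for (ch in spec$ar$channels) {
          r <- trial_rows[trial_rows$channel == ch, ]
          for (k in spec$ar$orders)
            v[paste0("ar", k, "_", ch)] <-
              if (nrow(r)) r[[paste0("phi", k)]][1] else NA_real_
        }
      } else {
        col <- switch(kind, H = "H", d = "d", erd = "erd")
        for (ch in spec[[kind]]) {
          r <- trial_rows[trial_rows$channel == ch, ]
          v[paste0(kind, "_", ch)] <- if (nrow(r)) r[[col]][1] else NA_real_
        }
      }
    }
    v
  }

  rows_for <- function(cond) {
    trials <- sort(unique(sub$trial[sub$condition == cond]))
    m <- t(vapply(trials, function(tr)
      wide_one(sub[sub$trial == tr, ]), wide_one(sub[sub$trial == sub$trial[1], ])))
    rownames(m) <- trials
    m
  }
  Xm <- rows_for(movement_condition)
  Xr <- rows_for("rest")
  ok_m <- stats::complete.cases(Xm)
  ok_r <- stats::complete.cases(Xr)
  dropped <- sum(!ok_m) + sum(!ok_r)
  if (dropped > 0)
    warning(dropped, " trial(s) dropped for missing features at t = ", t)
  Xm <- Xm[ok_m, , drop = FALSE]
  Xr <- Xr[ok_r, , drop = FALSE]
  if (!nrow(Xm) || !nrow(Xr)) stop("no complete trials available")
  n <- min(nrow(Xm), nrow(Xr))
  Xr <- Xr[with_seed(seed, sample.int(nrow(Xr), n)), , drop = FALSE]
  Xm <- Xm[seq_len(n), , drop = FALSE]
  list(x = rbind(Xm, Xr),
       y = factor(rep(c("movement", "rest"), each = n),
                  levels = c("movement", "rest")),
       dropped = dropped)
}

# binary LDA with pooled covariance; ridge-regularized toward the diagonal
# if (near-)singular
.lda_train <- function(x, y) {
  lev <- levels(y)
  x1 <- x[y == lev[1L], , drop = FALSE]
  x2 <- x[y == lev[2L], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  n1 <- nrow(x1); n2 <- nrow(x2)
  c1 <- x1 - rep(m1, each = n1)
  c2 <- x2 - rep(m2, each = n2)
  S <- (crossprod(c1) + crossprod(c2)) / (n1 + n2 - 2)
  for (gamma in c(0, 1e-4, 1e-2, 1e-1, 0.5)) {
    Sg <- (1 - gamma) * S + gamma * diag(diag(S) + 1e-12, ncol(x))
    w <- try(solve(Sg, m1 - m2), silent = TRUE)
    if (!inherits(w, "try-error") && all(is.finite(w)))
      return(list(w = w, c = sum(w * (m1 + m2)) / 2, positive = lev[1L],
                  levels = lev))
  }
  stop("singular pooled covariance even after ridge regularization")
}

.lda_predict <- function(fit, x) {
  score <- as.numeric(x %*% fit$w) - fit$c
  factor(ifelse(score > 0, fit$levels[1L], fit$levels[2L]),
         levels = fit$levels)
}

#' Train and evaluate LDA with repeated stratified k-fold cross-validation
#'
#' Stratified `folds`-fold cross-validation repeated `repeats` times with
#' reshuffling (10 x 10 by default).  Features are z-scored with means/sds
#' estimated on the training folds only.  Sensitivity is movement recall,
#' specificity rest recall.
#'
#' @param features list with `x` and `y` as from [build_features()], or a
#'   matrix plus `y` argument.
#' @param y class factor (first level = positive/movement class) if
#'   `features` is a matrix.
#' @param folds,repeats cross-validation geometry.
#' @param seed RNG seed controlling the fold shuffles.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent,
#'   mean over folds x repeats), their `sd`s, and `n` (total samples).
#' @export
train_eval_lda <- function(features, y = NULL, folds = 10L, repeats = 10L,
                           seed = 1L) {
  if (is.list(features) && !is.null(features$x)) {
    x <- as.matrix(features$x); y <- features$y
  } else x <- as.matrix(features)
  stopifnot(is.factor(y), nlevels(y) == 2L, nrow(x) == length(y))
  if (min(table(y)) < folds)
    stop("need at least `folds` samples in each class")
  pos <- levels(y)[1L]
  acc <- sen <- spe <- numeric(0)
  with_seed(seed, for (r in seq_len(repeats)) {
    # stratified fold assignment, reshuffled each repeat
    fold_id <- integer(length(y))
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      xt <- x[tr, , drop = FALSE]
      n_tr <- nrow(xt)
      mu <- colMeans(xt)
      sdv <- sqrt(pmax(colSums(xt * xt) - n_tr * mu^2, 0) / (n_tr - 1))
      sdv[sdv == 0] <- 1
      xtr <- (xt - rep(mu, each = n_tr)) / rep(sdv, each = n_tr)
      xe <- x[te, , drop = FALSE]
      xte <- (xe - rep(mu, each = nrow(xe))) / rep(sdv, each = nrow(xe))
      fit <- .lda_train(xtr, y[tr])
      pred <- .lda_predict(fit, xte)
      truth <- y[te]
      acc <- c(acc, mean(pred == truth))
      if (any(truth == pos)) sen <- c(sen, mean(pred[truth == pos] == pos))
      if (any(truth != pos)) spe <- c(spe, mean(pred[truth != pos] != pos))
    }
  })
  list(accuracy = 100 * mean(acc), sensitivity = 100 * mean(sen),
       specificity = 100 * mean(spe),
       accuracy_sd = 100 * stats::sd(acc),
       sensitivity_sd = 100 * stats::sd(sen),
       specificity_sd = 100 * stats::sd(spe),
       n = length(y))
}

#' Binomial chance threshold for balanced binary classification
#'
#' The smallest accuracy a (in percent) such that
#' \eqn{P[\mathrm{Bin}(n, 0.5) \ge a n] < \alpha}: accuracies above it are
#' unlikely under coin-flip classification of `n_trials` trials.
#'
#' @param n_trials number of trials entering the test.
#' @param alpha significance level (default 0.05).
#' @return threshold in percent.
#' @export
#' @examples
#' chance_threshold(40)  # 65%
chance_threshold <- function(n_trials, alpha = 0.05) {
  stopifnot(is_scalar_number(n_trials), n_trials >= 1)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  n <- as.integer(n_trials)
  for (k in 0:n) {
    if (stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE) < alpha)
      return(100 * k / n)
  }
  100   # even all-correct is not significant; cap at 100%
}

#' Movement-intention detection time from an accuracy time course
#'
#' The earliest window label at which accuracy first exceeds the chance
#' threshold (strictly) and stays above it for at least `k_consecutive`
#' windows.
#'
#' @param accuracy numeric per-window accuracies in percent.
#' @param t window labels (seconds relative to onset).
#' @param threshold chance threshold in percent ([chance_threshold()]).
#' @param k_consecutive required run length (default 1 = first crossing).
#' @return detection time in seconds, or `NA` if never crossed.
#' @export
detection_time <- function(accuracy, t, threshold, k_consecutive = 1L) {
  stopifnot(length(accuracy) == length(t), k_consecutive >= 1L)
  above <- !is.na(accuracy) & accuracy > threshold
  if (!any(above)) return(NA_real_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k_consecutive)
  if (!length(hit)) return(NA_real_)
  t[starts[hit[1L]]]
}
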