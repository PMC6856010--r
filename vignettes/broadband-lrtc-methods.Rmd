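---
title: "Methods: long- and short-range temporal dependencies in broadband EEG around movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long- and short-range temporal dependencies in broadband EEG around movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broadlrtc)
```

## The problem

Voluntary movement is preceded by slow reorganization of sensorimotor
EEG.  The best-known correlate is event-related desynchronization (ERD):
a percent drop of narrowband alpha (8-13 Hz) power relative to rest.
This package quantifies a complementary, *broadband* correlate: the
strength of long-range temporal correlation (LRTC) in the 0.5-45 Hz
signal, which rises around movement onset.  Both are computed causally on
2 s windows stepped by 100 ms, so every feature is available for online
movement-intention detection with at most a 2 s history.

A signal has LRTC when its autocorrelation decays as a power law,
$\rho(t) = C t^{-\alpha}$, equivalently when its spectrum is
$S(f) = B f^{-\beta}$ with $0.5 \le \beta \le 1.5$; short-range
dependence (SRD) decays exponentially and is captured by ARMA terms.  The
two regimes are bridged by the ARFIMA(p, d, q) model
$$\left(1 - \sum_{i=1}^{p}\phi_i B^i\right)(1-B)^d X_t
  = \left(1 + \sum_{i=1}^{q}\theta_i B^i\right)\epsilon_t ,$$
where $B$ is the backshift operator and the fractional order
$d = H - \tfrac12$ carries the long memory ($H$ is the Hurst exponent).

## Pipeline

1. **Preprocessing** (`bandpass_filter()`, `notch_filter()`,
   `downsample()`, `epoch_trials()`, `sliding_windows()`): zero-phase
   4th-order Butterworth band-pass 0.5-45 Hz, 2 Hz-wide band-stop at
   50 Hz, decimation to 128 Hz behind an 8th-order anti-alias low-pass,
   trials of -3..+3 s around each onset, causal windows $[t-2, t]$.
   Filters are designed from the analog prototype through the bilinear
   transform and applied as cascaded biquads (numerically safe even for a
   0.5 Hz edge at 1024 Hz).  A window at 128 Hz holds $N = 256$ samples;
   a 6 s trial yields 41 window labels, $-1.0, -0.9, \dots, +3.0$ s.

2. **DFA** (`estimate_hurst()`): the window is Hanning-tapered (edge
   suppression on short segments), mean-subtracted and integrated; for 25
   box sizes log2-spaced in $[10, N/4]$ the RMS residual of per-box
   linear detrending is computed from the forward and the time-reversed
   direction (so the tail samples are never discarded), and $H$ is the
   slope of $\log_2 F(n)$ on $\log_2 n$.  LRTC is declared for
   $0.5 < H < 1$.  Per-trial $H$ sequences are exponentially smoothed,
   $s_t = \lambda H_t + (1-\lambda) s_{t-1}$; $\lambda$ is not specified
   by the method's sources, our default is 0.3.

3. **ML-DFA** (`validate_mldfa()`): $H$ is meaningful only if the
   scaling plot is actually linear.  Candidate models (linear,
   polynomials of degree 2-5, logarithmic, exponential) are fitted by
   Gaussian maximum likelihood and compared with AICc.  Fluctuations at
   neighbouring scales are computed from the same 256 samples, so their
   errors are strongly correlated and raw AICc differences overstate the
   evidence; we therefore pick the most parsimonious model within 2 AICc
   units of the best, breaking ties toward linear.  On noise-free or
   iid-jittered power laws this selects linear >90% of the time while a
   genuine crossover (two slopes) is still rejected reliably.  On
   *finite-size* fGn realizations the acceptance rate is markedly
   lower, because such plots are truly slightly curved at small $n$ — a
   finding about short-window DFA, not a defect of the selection rule.

4. **ARFIMA** (`fit_arfima_window()`): the two-stage scheme.  $d = H -
   \tfrac12$ is plugged in from DFA (never jointly estimated), the raw
   window is fractionally differenced by $d$ — an FFT convolution with
   the binomial coefficients $b_k = b_{k-1}(k-1-d)/k$, series treated as
   zero before its start — checked for stationarity with an augmented
   Dickey-Fuller test (constant-only regression, AIC lag choice up to
   $\lfloor (N-1)^{1/3} \rfloor$, Dickey-Fuller tau table p-values), and
   an AR(10) is fitted by exact conditional least squares.  The fit
   carries 11 parameters: $d$ and $\phi_1..\phi_{10}$.  Residuals get a
   Ljung-Box test (lag 20, df reduced by the AR order) and a one-sample
   KS test against a moment-matched normal (conservative, since the
   moments are estimated).  Windows with $H < 0.5$ get $d < 0$
   (fractional integration) — allowed and flagged.  Order selection
   itself (`select_order()`, AIC over $p \le 10$, $q \le p-1$, with
   non-invertible MA candidates discarded) is provided for the
   identification analysis but the per-window model order is fixed.

5. **ERD** (`alpha_band_power()`, `erd_timecourse()`): window demeaned,
   band-passed 8-13 Hz, amplitude from the Hilbert envelope, power = mean
   squared amplitude over the inner 90% of the window (the envelope is
   unreliable at edges; the filter runs on reflection padding).  The
   baseline $R$ is the mean over *all* windows of *all* rest trials, per
   participant and channel; $ERD_t = 100\,(A_t - R)/R$.  The mean rest
   ERD is therefore identically zero, and ERD is invariant to rescaling
   the recording.

6. **Complementarity** (`remove_lrtc()`, `suppress_erd()`): LRTC is
   removed by differencing each window by its own $\hat d$; ERD is
   suppressed by giving every window of a trial the alpha-bin Fourier
   *magnitudes* of one randomly chosen donor window while keeping each
   window's own phases (conjugate symmetry enforced; out-of-band bins
   untouched — for 2 s windows the band holds exactly 11 bins at 0.5 Hz
   spacing).  Group contrasts use two-sided Mann-Whitney tests per window
   label, with a configurable unit of observation (trials within a
   participant, participants for grand averages).  `erd_lrtc_lag()`
   reports the per-trial Pearson correlation and the lag of maximum
   absolute cross-correlation between the two traces.

7. **Classification** (`build_features()`, `train_eval_lda()`): one
   binary LDA per window label, movement vs rest, with feature sets LRTC
   (H at C3, Cz, C4: 3), ERD (C3, C4: 2 — the midline channel
   discriminates poorly), ARFIMA ($d$ + AR1-6 from all channels: 21, the
   higher-order AR terms are small and noisy), and the hybrids (5 and 23
   features).  Rest rows are drawn with a recorded seed so classes stay
   balanced at 40 per class.  10x10-fold stratified cross-validation with
   within-fold z-scoring; pooled covariance with a ridge fallback.  The
   chance threshold is the smallest accuracy whose Binomial(n, 0.5) tail
   probability is below 0.05 — we read the method's "binomial
   distribution with n = number of EEG trials and p = 0.05" as success
   probability 0.5 at significance 0.05, since a success probability of
   0.05 is meaningless for a balanced binary task.  Detection time is the
   first window whose accuracy strictly exceeds the threshold (a
   sustained-run length is configurable; the default is the literal first
   crossing).

## The synthetic world

`synthesize_movement_dataset()` generates the full experiment: 3
channels (C3, Cz, C4) at 128 Hz, 40 trials per condition (right, left,
rest), 6 s trials in individually guarded slots.  Per trial and channel:

* **Broadband background**: one innovation stream is fractionally
  integrated by `d_baseline` and by `d_peak`; the two series are
  cross-faded with the programmed ramp weight.  Because both come from
  the same innovations there are no seams, and the local scaling tracks
  the programmed $d(t)$.  The high-$d$ series is rescaled so both carry
  identical theoretical alpha-band power — otherwise the spectral tilt
  of stronger long memory would leak into band power and the "broadband"
  and "narrowband" programmed effects would not be independent.
* **Alpha**: a phase-jittered 10 Hz oscillator whose amplitude is scaled
  by $1 - \text{suppression}$ inside the ERD ramp.

Defaults (chosen once): $d$ 0.12 at rest rising to 0.25 over
$[-1.5, -0.5]$ s (rest $H \approx 0.62$, movement $\approx 0.75$);
suppression 0.3 over $[-1, 0]$ s — the broadband change leads the
narrowband one by 0.5 s; alpha amplitude 0.5 on unit innovations, i.e.
roughly 10% of broadband power in the alpha band, giving a measured ERD
trough near -30%.  A much louder oscillator would dominate the DFA
scales (a sinusoid's detrended fluctuations saturate beyond its period)
and mask the programmed scaling; oscillator-dominated configurations are
still available explicitly and recover the analytic ERD floor
$(s^2 - 1) \times 100$ within a few points.  Optional between-participant
heterogeneity (log-normal alpha amplitude, jittered suppression and $d$
levels) emulates a realistic cohort and is used for grand-average
analyses; it is off by default so single-participant properties are
exact.  Everything is a pure function of the config seed, and the
per-participant parameters are recorded in the ground truth.

What a green test on this world does *not* establish: robustness to
artifacts (blinks, EMG), volume conduction and channel correlation,
non-sinusoidal alpha, participant-specific alpha bands, or the
archived-data accuracies — those require the real recordings.

## Numerical choices and edge cases

* Box sizes are rounded to integers and deduplicated (25 requested, ~22
  distinct at $N=256$); the slope fit weights all retained sizes equally.
* Constant windows are degenerate: $F(n) = 0$, $H$ reported missing, the
  window's ARFIMA record is emitted with a reason instead of a fit.
* `fractional_difference(x, 1)` reduces exactly to the first difference
  with $x_1$ retained; $d = 0$ is the identity.
* fGn comes from circulant embedding (exact target autocovariance —
  eigenvalues are clamped only below $-10^{-8}$ relative, which does not
  occur for $H \in (0,1)$); it is the ground truth for all Hurst
  estimator checks.
* ADF on a constant series, Ljung-Box with too few residuals, ERD with a
  non-positive baseline, and band edges at or above Nyquist all error
  with explicit messages.
* Functions that accept a seed leave the caller's RNG stream untouched.

## Known limitations

* The two-stage $d = \hat H - \tfrac12$ estimate inherits DFA's
  small-window bias: with strong AR structure ($\phi_1 = 0.8$) the scales
  $[10, 64]$ see the short-range correlation as extra persistence and
  $\hat d$ is inflated by up to $\approx 0.4$ at $N = 256$ (shrinking
  with window length).  This is a property of the published scheme, which
  the test suite documents rather than hides; the classifier is
  unaffected since it consumes the biased-but-informative features
  consistently across conditions.
* Fractional differencing is not band-neutral: it attenuates 10 Hz
  amplitude by $|1-e^{-i\omega}|^{\hat d}$.  When movement windows carry a
  larger $\hat d$ than the rest windows behind the baseline, ERD measured
  after "LRTC removal" is systematically deeper at the trough.  The
  corresponding published no-difference claim is reproducible only as a
  low-power group-level non-rejection, not as a pointwise invariance.
* First-crossing detection times are sensitive to sampling flukes of a
  40-trial cohort near the chance threshold (a sustained-run criterion,
  `k_consecutive > 1`, is more robust but changes the literal
  definition), and a feature set with higher per-window SNR can compress
  a genuine temporal lead of a lower-SNR competitor: detection *order*
  between feature sets is therefore less reproducible than the detection
  times themselves.

## A small worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_trials_per_condition = 10, seed = 7)
ds <- synthesize_movement_dataset(cfg)
store <- run_participant(ds[[1]]$recording,
                         study_config(diagnostics = FALSE))
tc <- classification_timecourse(store, "arfima+erd", "right",
                                study_config(folds = 5, repeats = 2))
attr(tc, "detection_time")
```
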