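# broadlrtc

Long- and short-range temporal dependencies in broadband EEG around
voluntary movement — and their use for single-trial movement-intention
detection.

## What it does, for whom

Brain-computer interface and motor-neuroscience work usually detects
upcoming movement from the event-related desynchronization (ERD) of
narrowband alpha (8–13 Hz) power.  `broadlrtc` quantifies a second,
*broadband* signature on the same 2 s causal sliding windows: the
strength of long-range temporal correlation (LRTC), which rises around
movement onset, together with the short-range dependence (SRD) left after
the long memory is removed.  The package provides, as tested R functions:

* **DFA Hurst estimation** on short (256-sample) windows — integrate,
  detrend in 25 log2-spaced boxes over `[10, N/4]`, regress
  `log2 F(n)` on `log2 n` — with **ML-DFA** validation that the scaling
  plot is actually linear, and exponential smoothing of the `H` time
  course;
* **ARFIMA(10, d, 0)** per-window modelling via the two-stage scheme
  `d = H − 0.5`, FFT-based fractional differencing
  `(1 − B)^d` (`b_k = b_{k−1}(k−1−d)/k`), ADF stationarity check, least-
  squares AR estimation, Ljung-Box / KS residual diagnostics, and
  AIC order identification;
* **Percent ERD** from the Hilbert envelope of the alpha band against a
  resting-state baseline, `ERD_t = 100 (A_t − R)/R`;
* **Complementarity ablations**: remove LRTC by fractional differencing,
  or freeze the ERD by transplanting alpha-bin Fourier magnitudes from a
  random donor window, plus Mann-Whitney condition masks and ERD–LRTC
  cross-correlation lag analysis;
* **Per-window LDA classification** (movement vs rest) for five feature
  sets (LRTC: 3, ERD: 2, ARFIMA: 21, and hybrids: 5 / 23 features) with
  10×10-fold cross-validation, exact binomial chance thresholds, and
  detection times;
* **Ground-truth generators**: exact fractional Gaussian noise (circulant
  embedding), ARFIMA simulation, and a full synthetic movement experiment
  (3 channels at 128 Hz, 40 six-second trials per condition, programmed
  d ramp and alpha suppression) so the entire pipeline is testable
  without any data download;
* **I/O and CLI**: minimal EDF reader/writer, event TSVs, and a
  command-line front end (`inst/cli/broadlrtc.R`) with
  `simulate`/`preprocess`/`features`/`classify`/`pipeline` subcommands.

## Worked example

```r
library(broadlrtc)

## Hurst exponent of exact fGn with H = 0.8 on one 2 s window
r <- validate_mldfa(estimate_hurst(generate_fgn(0.8, 256, seed = 3)))
r
#> DFA result: H = 0.8381 | scales 10 - 64 | valid: TRUE | ML-DFA: linear

## two-stage ARFIMA fit of a simulated ARFIMA(1, 0.2, 0) window
fit_arfima_window(simulate_arfima(ar_coeffs = 0.4, d = 0.2,
                                  n_samples = 256, seed = 42))
#> ARFIMA(10, 0.155, 0) fit: d = 0.155, AIC = 9.67
#> phi:  0.44369  0.00570  0.01504 -0.08143  0.03322 -0.06334 ...
#> Ljung-Box p = 0.391, KS p = 0.642, ADF stationary: TRUE

## a synthetic participant end to end
cfg <- synthetic_config(n_trials_per_condition = 10, seed = 7)
ds  <- synthesize_movement_dataset(cfg)
store <- run_participant(ds[[1]]$recording,
                         study_config(diagnostics = FALSE))
aggregate(cbind(H_smooth, erd) ~ condition,
          store[store$channel == "C3" & store$t >= 0.5, ], mean)
#>   condition H_smooth    erd
#> 1      left    0.670 -33.37
#> 2      rest    0.562  -4.01
#> 3     right    0.680 -20.25

tc <- classification_timecourse(store, "arfima+erd", "right",
                                study_config(folds = 5, repeats = 2,
                                             diagnostics = FALSE))
#> peak accuracy 90.0%, chance threshold 75.0%, detection at 0.1 s
```

Reading the numbers: after movement onset the smoothed Hurst exponent of
movement trials sits ≈ 0.11 above rest (the programmed LRTC increase,
d 0.12 → 0.25) while alpha power drops by ≈ 20–33% (the programmed ERD);
rest stays near its own baseline.  With only 10 trials per class the
binomial chance level is 75% and the hybrid classifier still clears it
just after onset; with the full 40 trials per condition the threshold
drops to 60% and detection moves before onset (see the acceptance tests).

## CLI

```sh
Rscript inst/cli/broadlrtc.R simulate --out data/ --participants 2 --trials 40 --seed 1
Rscript inst/cli/broadlrtc.R features --in data/participant01.edf --out p01.tsv
Rscript inst/cli/broadlrtc.R classify --in p01.tsv --features arfima+erd --out p01_cls.tsv
```
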