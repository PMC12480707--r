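# circhrv

Circadian analysis of cardiac autonomic function from 24-hour RR-interval
recordings.

Heart rate variability (HRV) — the beat-to-beat fluctuation of normal RR
(NN) intervals — tracks the balance of sympathetic and parasympathetic
cardiac control, and that balance oscillates over the 24-hour day. circhrv
is for physiologists and chronobiologists who have ambulatory RR recordings
(or want fully synthetic ones with known ground truth) and need the whole
chain: artifact correction, hourly HRV metrics, rhythm detection, cosinor
rhythmometry, and sex/age group statistics.

The core quantity is the single-component cosinor

> Y(t) = M + A · cos(2πt/T + φ),  T = 24 h

fitted per subject and per metric to hourly values: **M** (MESOR, the
rhythm-adjusted mean), **A** (amplitude, half the peak-to-trough swing) and
**φ** (acrophase, reported as the clock time of the fitted peak). Around it
the package implements:

- RR-series I/O, subject manifests and a typed run configuration
  (`read_rr()`, `subject_record()`, `hrv_config()`);
- threshold artifact detection against a local median, cubic-spline beat
  correction with a > 5% exclusion rule, smoothness-priors detrending, and
  per-hour 5-minute window selection (`detect_artifacts()`,
  `correct_beats()`, `select_hourly_windows()`);
- time-domain (SDNN, SDANN, RMSSD, pNN50), spectral
  (Welch/Blackman–Harris VLF–LF–HF band powers), nonlinear (Poincaré
  SD1/SD2, DFA α1/α2, ApEn/SampEn/ShanEn, correlation dimension, REC/DET)
  and autonomic (Baevsky stress index, PNS/SNS/stress composites) metrics;
- rhythmicity screening (repeated-measures ANOVA cross-validated with an
  FFT-NNLS period scan), per-subject cosinor fits with zero-amplitude
  tests, and group comparisons (KS-routed t / Mann–Whitney, circular
  Watson–Williams for acrophases, Cliff's delta, BH multiplicity, logistic
  regression of rhythmicity, type-II interaction ANOVA);
- a synthetic-cohort generator (`generate_cohort()`) whose 24-h cosine,
  HF/LF oscillations and injected ectopic beats give every stage a known
  target.

All user-facing functions take and return tibbles and compose with the
pipe; fitted cosinor objects support `tidy()`, `glance()` and `autoplot()`.

## A worked example

```r
library(circhrv)

spec <- synth_subject_spec(subject_id = "s1", rr_mesor = 900,
                           rr_circ_amplitude = 60, rr_acrophase = 3,
                           noise_sd = 10, ectopic_rate = 0.02, seed = 7L)
s <- generate_rr(spec)
s
#> <rr_series> subject s1: 96270 beats, 24.00 h, mean RR 897 ms

flags <- detect_artifacts(s)                 # 20% local-median rule
corr  <- correct_beats(s, flags)
corr$report$corrected_fraction
#> [1] 0.020214

plan   <- select_hourly_windows(corr$series) # one clean 5-min window/hour
hourly <- vapply(seq_len(24), function(i)
  mean(window_rr(corr$series, plan$start_s[i], plan$end_s[i])), numeric(1))
fit <- cosinor_fit(hourly, (plan$start_s + plan$end_s) / 2 / 3600)
fit
#> <cosinor_fit> T=24 h, n=24
#>   MESOR 899.5  amplitude 59.96  acrophase 03:00  (zero-amplitude p=1.52e-40)
```

The fitted MESOR (899.5 ms), amplitude (59.96 ms) and acrophase (03:00)
recover the generator's ground truth (900 ms, 60 ms, 03:00) after the
injected ectopics have been corrected; the zero-amplitude test rejects "no
rhythm" decisively. A whole cohort runs through `pipeline_demo(n_per_group
= 5, seed = 1)` or, from a shell, `Rscript inst/cli/pipeline.R demo --seed 1
--out results/`, producing cosinor, rhythm-decision and group-comparison
tables shaped like the usual metric × {MESOR, amplitude, acrophase} × group
reports.

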