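---
title: "Circadian HRV rhythmometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian HRV rhythmometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

circhrv turns a 24-hour RR-interval recording into circadian parameters of
cardiac autonomic function. This vignette explains the models and procedures
the package implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer should know about.

## The analysis pipeline

A recording enters as a beat-by-beat series of RR intervals (milliseconds)
with cumulative timestamps. The pipeline then runs, in order:

1. **Artifact detection** (`detect_artifacts()`): a beat is flagged when its
   relative deviation from the median of its 11 nearest not-yet-flagged
   neighbours exceeds 20%. The 20% default mirrors the maximal correction
   factor used in threshold-based beat correction; the neighbourhood size
   and single-pass sequential scan are our choices, made so that an already
   flagged ectopic cannot contaminate the reference median of its
   neighbours.
2. **Beat correction** (`correct_beats()`): flagged RR values are replaced
   by a cubic spline through the unflagged `(t, rr)` points; flagged runs at
   the recording boundary fall back to linear extrapolation from the two
   nearest unflagged beats (and are reported as such). Correction never
   changes the number of beats. Recordings in which more than 5% of beats
   needed correction are excluded (strict inequality).
3. **Detrending** (`detrend_smoothness_priors()`): slow nonstationary trends
   are removed by subtracting the smoothness-priors smoother
   \((I + \lambda^2 D_2^\top D_2)^{-1} z\), with \(\lambda = 500\), the
   method's customary value for 4 Hz-resampled RR data. Constants and lines
   lie in the smoother's null space; a 0.25 Hz respiratory oscillation
   sampled at 4 Hz passes with < 0.1% attenuation, so HF content is intact.
4. **Window selection** (`select_hourly_windows()`): per clock hour, a
   300-second window is chosen by sliding in 30-second steps and minimizing
   (artifact count, then a stationarity score, then earliest start). The
   stationarity score is \(|\bar{x}_{first half} - \bar{x}_{second half}| /
   SD\); it is an explicit, deterministic stand-in for software-guided
   stationarity screening. Hours with less than 300 s of data are reported
   missing.
5. **Per-window metrics**: time-domain (SDNN, RMSSD, pNN50, mean RR/HR),
   spectral (VLF/LF/HF band powers from a Welch estimate with 4-term
   Blackman–Harris tapers), nonlinear (Poincaré SD1/SD2, DFA α1/α2,
   ApEn/SampEn/ShanEn, correlation dimension, REC/DET), and autonomic
   composites (Baevsky stress index; PNS/SNS/stress indices as means of
   z-scored components).
6. **Rhythmometry** (`fit_cohort()`): per subject and metric, a
   single-component cosinor \(Y(t) = M + A\cos(2\pi t/T + \phi)\) with
   \(T = 24\) h is fitted to the hourly values by OLS on the linearized
   design \((1, \cos\omega t, \sin\omega t)\). A rhythmicity screen
   cross-validates a repeated-measures ANOVA (hour as within-subject
   factor) with a non-negative least-squares amplitude fit over candidate
   periods {48, 24, 12, 8, 6, 4.8, 4 h}; a metric is called rhythmic when
   the ANOVA rejects uniformity at 0.05 *and* the dominant period is within
   24 ± 2 h. Metrics failing the screen are flagged but still fitted, for
   transparency.
7. **Group statistics** (`compare_groups()`, `interaction_anova()`,
   `rhythmicity_logistic()`): sex and age-group contrasts of MESOR,
   amplitude and acrophase; a Kolmogorov–Smirnov normality screen routes
   linear parameters to Student's t or Mann–Whitney U (exact enumeration up
   to combined n = 20, normal approximation with tie correction above);
   acrophases are compared circularly (Watson–Williams) because clock times
   wrap at midnight — a linear route is retained for strict replication.
   Cliff's delta accompanies every comparison; multiplicity is handled by
   Benjamini–Hochberg by default (configurable, since "post hoc correction
   by the Cliff method" admits several readings). Odds of rhythmicity are
   modelled by multivariable logistic regression (age, sex, BMI), and
   sex × age interactions by type-II ANOVA.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `correction.threshold` | 0.20 | – | maximal correction factor of the beat filter |
| `correction.max_fraction` | 0.05 | – | exclusion rule: > 5% corrected beats |
| `detrend.lambda` | 500 | – | smoothness prior; passes ≥ 0.04 Hz nearly unchanged |
| `windows.length_s` | 300 | s | 5-min analysis standard for short-term HRV |
| `spectral.rate_hz` | 4 | Hz | cubic-spline resampling rate |
| `spectral.subsegment_s` / `overlap` | 150 / 0.5 | s / – | Welch segments inside a 5-min window; resolves 0.0067 Hz |
| `spectral.pad_points_per_hz` | 300 | 1/Hz | frequency-grid density |
| bands | 0.0033–0.04–0.15–0.5 | Hz | VLF / LF / HF edges |
| `nonlinear.sampen_m` / `sampen_r` | 2 / 0.2·SD | – | canonical entropy template settings |
| `nonlinear.dfa_range1/2` | 4–16 / 16–64 | beats | short/long DFA scaling ranges |
| `nonlinear.embed_m`, threshold | 10, √m·SD | – | embedding and recurrence threshold |
| `cosinor.period_h` | 24 | h | fixed circadian period |
| `cosinor.min_hours` | 20 | h | minimum non-missing hours per fit |
| `age_cut` | 50 | years | young/old boundary (≈ mean menopausal age); inclusive on the old side |

Normalized spectral powers use the LF+HF denominator, so LFn + HFn = 100 by
construction; this is the convention consistent with reported normalized
pairs summing to ~100. Because the hourly analysis uses the one selected
window per hour, the alternative of averaging twelve 5-min segments per
hour is available in principle but not the default; the selected-window
mode is what the preprocessing stage defines.

The heart-rate correction of millisecond-scale metrics is division by the
window's mean RR. The literature correction it stands in for is cited
rather than printed in most reports; division reproduces the expected
magnitudes (SDNN 32.9 ms at mean RR 914 ms → 0.036) and the correction
function is pluggable for users who prefer another form.

The composite autonomic indices weight their component z-scores equally
(mean RR, RMSSD, SD1 for the parasympathetic index; mean HR, √SI, SD2 for
the sympathetic index, with a configurable sign vector defaulting to all
positive). Equal weighting is the minimal assumption where no weights are
published. The package ships no population norms: `synthetic_norms()`
derives a clearly tagged stand-in from synthetic data, and real analyses
must supply their own `normative_reference()`.

## The synthetic generator

`generate_rr()` builds each beat as

\[ rr_n = M_{rr} + A_{rr}\cos\!\frac{2\pi (t_n - \phi_{rr})}{86400}
   + a_{HF}(t_n)\sin(2\pi f_{HF} t_n) + a_{LF}(t_n)\sin(2\pi f_{LF} t_n)
   + \varepsilon_n, \]

with \(a_X(t) = X_{amp}(1 + g\cos 2\pi (t-\phi_{band})/86400)\),
\(\varepsilon_n \sim N(0, \sigma)\), and \(t_{n+1} = t_n + rr_{n+1}/1000\).
With probability `ectopic_rate/2` a beat pair is replaced by a
short/compensatory ectopic pair (0.6 and 1.4 times the original interval),
ground-truth flagged. Defaults portray a healthy ambulatory adult: mean RR
900 ms, circadian swing 60 ms peaking at 03:00, respiratory oscillation at
0.25 Hz (25 ms), LF oscillation at 0.1 Hz (20 ms), 30% day/night modulation
of both, 10 ms observation noise, 1% ectopics. The 0.6/1.4 ectopic
morphology is deliberately detectable by a 20% threshold rule, so the
generator exercises the correction stage the way real ectopy would.

The generator is an additive-sinusoid model, not an
integral-pulse-frequency-modulation model: it gives every downstream metric
a known target but does **not** reproduce sleep staging, activity bursts,
respiratory frequency drift, or the asymmetric RR distributions of real
recordings. Passing parameter-recovery tests therefore demonstrates the
correctness of the estimation chain, not field performance on pathological
data.

## Numerical choices and degenerate inputs

- Cosinor acrophase is stored in radians in \((-2\pi, 0]\) and reported as
  clock time \(((-\phi)T/2\pi) \bmod T\), floored to the minute for
  display. Fits need ≥ 4 points at ≥ 3 distinct times; constant profiles
  return amplitude ≈ 0 with a zero-amplitude p near 1.
- The zero-amplitude test is \(F = ((TSS-RSS)/2)/(RSS/(n-3))\) on
  \(F(2, n-3)\); its size is verified at α = 0.05 on 1000 null profiles.
  The repeated-measures ANOVA uses hour as the within-subject factor on
  complete cases, giving (23, 23(n−1)) degrees of freedom.
- Poincaré uses population variances so SD1/SD2 identities are exact;
  sample (n−1) SDs are used for SDNN/SDANN, the dominant convention.
- DFA fits all integer box sizes in each range. The white-noise α1 over
  boxes 4–16 carries the well-known small-box positive bias (≈ 0.58 rather
  than 0.5); the Brownian calibration is unbiased (≈ 1.50).
- Correlation dimension keeps its n ≥ 500 precondition. Five-minute windows
  at physiological mean RR hold ~330 beats, so in the hourly pipeline
  CorrDim cells are reported missing rather than computed on windows that
  cannot support the embedding; its rhythm decision then reads
  "insufficient data".
- SampEn is reported missing when no template pair matches at length m+1;
  constant windows are errors for entropy and stress-index routines
  (degenerate distributions).
- Welch PSD normalization satisfies Parseval: the integral of the PSD
  equals the variance of the detrended input within 1% (5% on white-noise
  Monte Carlo); band integration is trapezoidal with edge interpolation so
  VLF+LF+HF tiles the full range to 0.1%.
- All randomness flows through R's RNG; per-subject substreams are derived
  by a stable string hash of the subject id offset by the master seed, so
  cohorts are reproducible file-for-file and an artifact-contaminated
  series has an exactly beat-aligned artifact-free twin (same seed,
  `ectopic_rate = 0`).

## Validation strategy and problem sizes

The test suite validates every stage against independent oracles: cosinor
against a hand-rolled three-column least-squares solve; ApEn/SampEn against
brute-force O(n²) template counting; DFA against a literal per-box `lm`
reference; correlation sums against a double-loop implementation;
Mann–Whitney against full enumeration; balanced ANOVA against mean
projections. Cohort-level checks use 20–50 synthetic subjects with full
24-h recordings; directional-fidelity checks (smaller amplitude and earlier
acrophase with age; later sympathetic-proxy acrophase in females, read out
through hourly SD2) use 25 subjects per group over 40 seeds. These sizes
were chosen to make Monte-Carlo conclusions stable at desk scale while
keeping a full run in minutes.

## Known limitations

- A single-component cosinor cannot represent 12-h harmonics; profiles with
  strong ultradian structure get a dominant-period flag instead.
- The uniformity screen's natural reading (rejecting uniformity = evidence
  of a time-of-day effect) is implemented; reports that proceed to cosinor
  *because* a metric looked uniform invert this logic, and the package
  deliberately does not reproduce that inversion.
- Group summaries are emitted both as median [IQR] and mean ± SD, since
  published tables are not consistent about which is shown.
- The acrophase comparison defaults to circular statistics; linear
  comparisons (available via `circular = FALSE`) can be badly wrong for
  peaks near midnight and exist only for replication of linear reports.
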