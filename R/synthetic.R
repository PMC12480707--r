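#' Specification of one synthetic subject
#'
#' Defines the ground-truth circadian structure of a simulated 24-h RR
#' recording: a 24-h cosine modulation of mean RR (mesor/amplitude/acrophase),
#' a high-frequency respiratory oscillation and a low-frequency oscillation
#' whose amplitudes are themselves modulated over 24 h, white observation
#' noise, and ectopic-beat contamination.
#'
#' Defaults portray a healthy ambulatory adult: mean RR 900 ms (about 67 bpm)
#' peaking at 03:00 (night-time heart-rate minimum) with a 60 ms circadian
#' swing, respiratory sinus arrhythmia at 0.25 Hz, an LF oscillation at
#' 0.1 Hz, and a 30% day/night modulation of beat-to-beat variability.
#'
#' @param subject_id Identifier.
#' @param sex,age Covariates (see [subject_record()]).
#' @param rr_mesor Mean RR level, ms.
#' @param rr_circ_amplitude 24-h cosine amplitude of RR, ms.
#' @param rr_acrophase Clock hour of the RR peak.
#' @param hf_amp,hf_freq High-frequency oscillation amplitude (ms) and
#'   frequency (Hz, in 0.15-0.5).
#' @param lf_amp,lf_freq Low-frequency oscillation amplitude (ms) and
#'   frequency (Hz, in 0.04-0.15).
#' @param band_circ_gain Unitless 24-h modulation depth of both oscillation
#'   amplitudes.
#' @param band_acrophase Clock hour at which the oscillation amplitudes peak
#'   (0 reduces the modulation to `1 + gain*cos(2*pi*t/86400)`).
#' @param noise_sd White observation noise SD, ms.
#' @param ectopic_rate Expected fraction of beats belonging to an injected
#'   ectopic pair, in `[0, 0.5)`.
#' @param duration Recording length, hours.
#' @param seed Per-subject RNG seed (integer) or `NA` to derive one from the
#'   subject id.
#' @return One-row tibble of class `synth_subject_spec`.
#' @export
synth_subject_spec <- function(subject_id = "synth01", sex = "female",
                               age = 40,
                               rr_mesor = 900, rr_circ_amplitude = 60,
                               rr_acrophase = 3,
                               hf_amp = 25, hf_freq = 0.25,
                               lf_amp = 20, lf_freq = 0.10,
                               band_circ_gain = 0.3, band_acrophase = 0,
                               noise_sd = 10, ectopic_rate = 0.01,
                               duration = 24, seed = NA_integer_) {
  spec <- tibble::tibble(
    subject_id = as.character(subject_id), sex = sex, age = age,
    rr_mesor = rr_mesor, rr_circ_amplitude = rr_circ_amplitude,
    rr_acrophase = rr_acrophase, hf_amp = hf_amp, hf_freq = hf_freq,
    lf_amp = lf_amp, lf_freq = lf_freq,
    band_circ_gain = band_circ_gain, band_acrophase = band_acrophase,
    noise_sd = noise_sd, ectopic_rate = ectopic_rate,
    duration = duration, seed = as.integer(seed))
  class(spec) <- c("synth_subject_spec", class(spec))
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  with(spec, {
    if (rr_mesor <= rr_circ_amplitude + hf_amp * (1 + band_circ_gain) +
          lf_amp * (1 + band_circ_gain) + 5 * noise_sd)
      abort("spec admits non-positive RR: mesor too small for the amplitudes")
    if (ectopic_rate < 0 || ectopic_rate >= 0.5)
      abort("ectopic_rate must be in [0, 0.5)")
    if (hf_freq < 0.15 || hf_freq > 0.5) abort("hf_freq outside 0.15-0.5 Hz")
    if (lf_freq < 0.04 || lf_freq > 0.15) abort("lf_freq outside 0.04-0.15 Hz")
    if (duration <= 0) abort("duration must be positive")
  })
  invisible(spec)
}

# stable 31-bit hash of a string, for per-subject RNG substreams
stable_hash <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

#' Generate one synthetic 24-h RR series
#'
#' Beat-by-beat construction: each interval is the circadian mesor plus a
#' 24-h cosine, amplitude-modulated HF and LF sinusoids, and Gaussian noise,
#' evaluated at the running cumulative time; with probability
#' `ectopic_rate/2` a beat pair (i, i+1) is replaced by a short/compensatory
#' ectopic pair (0.6 and 1.4 times the original interval) and ground-truth
#' flagged as artifact. Deterministic given the seed; the artifact-free twin
#' of a contaminated series is obtained by regenerating with
#' `ectopic_rate = 0` and the same seed.
#'
#' @param spec A [synth_subject_spec()].
#' @param require_full_day Error if `duration < 24` h (default `TRUE`).
#' @return An [rr_series()]; ground-truth artifact beats carry
#'   `flag == "artifact"` and the true parameters are attached as attribute
#'   `"truth"`.
#' @export
generate_rr <- function(spec, require_full_day = TRUE) {
  validate_synth_spec(spec)
  if (require_full_day && spec$duration < 24)
    abort("duration < 24 h but a full day is required")
  seed <- if (is.na(spec$seed)) stable_hash(spec$subject_id) else spec$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  raw <- gen_rr_cpp(spec$rr_mesor, spec$rr_circ_amplitude, spec$rr_acrophase,
                    spec$hf_amp, spec$hf_freq, spec$lf_amp, spec$lf_freq,
                    spec$band_circ_gain, spec$band_acrophase,
                    spec$noise_sd, spec$duration * 3600)
  rr <- raw$rr
  n <- length(rr)
  flag <- rep("normal", n)
  if (spec$ectopic_rate > 0 && n > 3) {
    starts <- which(runif(n) < spec$ectopic_rate / 2)
    starts <- starts[starts >= 2 & starts <= n - 1]
    # drop overlapping pair starts, keeping the earlier one
    if (length(starts) > 1)
      starts <- starts[c(TRUE, diff(starts) > 1)]
    for (i in starts) {
      base <- rr[i]
      rr[i] <- 0.6 * base
      rr[i + 1] <- 1.4 * base
      flag[c(i, i + 1)] <- "artifact"
    }
  }
  t <- cumsum(rr) / 1000 - rr[1] / 1000
  out <- rr_series(t = t, rr = rr, flag = flag,
                   subject_id = spec$subject_id,
                   meta = subject_record(spec$subject_id, spec$sex, spec$age),
                   validate = FALSE)
  attr(out, "truth") <- spec
  out
}

#' Specification of a synthetic cohort
#'
#' Group-level parameter distributions, one row per sex-by-age-group cell.
#' Each cell draws its subjects' circadian parameters from normal
#' distributions with the given means and SDs.
#'
#' @param n_per_group Subjects per cell.
#' @param groups Tibble with columns `sex`, `age_group` and any of the
#'   `<param>_mean` / `<param>_sd` columns for [synth_subject_spec()]
#'   parameters (`rr_mesor`, `rr_circ_amplitude`, `rr_acrophase`, `hf_amp`,
#'   `lf_amp`, `band_circ_gain`, `band_acrophase`, `noise_sd`). Missing
#'   entries fall back to the subject-spec defaults with SD 0.
#' @param ectopic_rate,duration Shared across subjects.
#' @param seed Master seed; per-subject substreams are derived by stable
#'   hashing of the subject id offset by this seed.
#' @return List of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_per_group = 5,
                              groups = default_cohort_groups(),
                              ectopic_rate = 0.01, duration = 24,
                              seed = 1L) {
  structure(list(n_per_group = n_per_group, groups = tibble::as_tibble(groups),
                 ectopic_rate = ectopic_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "synth_cohort_spec")
}

#' Default group parameter distributions
#'
#' Encodes the qualitative structure the analysis is designed to detect:
#' older subjects have a smaller circadian RR amplitude peaking earlier, and
#' females a later peak of the variability (band-amplitude) modulation.
#'
#' @return Tibble with one row per sex-by-age-group cell.
#' @export
default_cohort_groups <- function() {
  tibble::tribble(
    ~sex,     ~age_group, ~rr_mesor_mean, ~rr_circ_amplitude_mean,
    ~rr_acrophase_mean, ~band_acrophase_mean,
    "female", "young",  900, 60, 3.0, 16,
    "female", "old",    880, 45, 1.0, 16,
    "male",   "young",  920, 60, 3.0, 14,
    "male",   "old",    900, 45, 1.0, 14) |>
    dplyr::mutate(rr_mesor_sd = 40, rr_circ_amplitude_sd = 10,
                  rr_acrophase_sd = 1, band_acrophase_sd = 1)
}

#' Expand a cohort spec and generate all RR series
#'
#' @param cohort_spec A [synth_cohort_spec()].
#' @param out_dir Optional directory; when given, per-subject RR CSVs, a
#'   cohort `manifest.csv` and a `ground_truth.csv` are written there.
#' @return List with elements `series` (named list of [rr_series()]),
#'   `manifest` (subject covariates) and `ground_truth` (true per-subject
#'   parameters).
#' @export
generate_cohort <- function(cohort_spec, out_dir = NULL) {
  stopifnot(inherits(cohort_spec, "synth_cohort_spec"))
  g <- cohort_spec$groups
  params <- c("rr_mesor", "rr_circ_amplitude", "rr_acrophase", "hf_amp",
              "lf_amp", "band_circ_gain", "band_acrophase", "noise_sd")
  base <- synth_subject_spec()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cohort_spec$seed)
  specs <- purrr::pmap(list(seq_len(nrow(g))), function(i) {
    row <- g[i, ]
    purrr::map(seq_len(cohort_spec$n_per_group), function(k) {
      id <- sprintf("%s_%s_%02d", substr(row$sex, 1, 1), row$age_group, k)
      args <- list(subject_id = id, sex = row$sex,
                   age = if (row$age_group == "old") runif(1, 50, 70)
                         else runif(1, 20, 49),
                   ectopic_rate = cohort_spec$ectopic_rate,
                   duration = cohort_spec$duration,
                   seed = (cohort_spec$seed + stable_hash(id)) %% 2147483647L)
      for (p in params) {
        mcol <- paste0(p, "_mean"); scol <- paste0(p, "_sd")
        m <- if (mcol %in% names(row)) row[[mcol]] else base[[p]]
        s <- if (scol %in% names(row)) row[[scol]] else 0
        args[[p]] <- rnorm(1, m, s)
      }
      args$rr_circ_amplitude <- max(args$rr_circ_amplitude, 0)
      do.call(synth_subject_spec, args)
    })
  })
  specs <- purrr::flatten(specs)
  ids <- purrr::map_chr(specs, "subject_id")
  if (anyDuplicated(ids)) abort("duplicate subject_id in cohort")
  series <- purrr::map(specs, generate_rr,
                       require_full_day = cohort_spec$duration >= 24)
  names(series) <- ids
  ground_truth <- dplyr::bind_rows(specs)
  manifest <- dplyr::bind_rows(purrr::map(series, attr, "meta"))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    purrr::iwalk(series, function(s, id)
      write_rr(s, file.path(out_dir, paste0(id, ".csv"))))
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
                     progress = FALSE)
    readr::write_csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                     progress = FALSE)
  }
  list(series = series, manifest = manifest, ground_truth = ground_truth)
}
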