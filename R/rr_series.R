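#' Construct an RR-interval series
#'
#' The substrate of the whole pipeline: a tibble with one row per beat,
#' columns `t` (seconds since recording start, strictly increasing), `rr`
#' (interval in milliseconds) and `flag` (one of `"normal"`, `"artifact"`,
#' `"corrected"`), carrying the subject id as an attribute.
#'
#' For consecutive beats flagged `normal` the timestamps are required to be
#' consistent with the intervals: `t[i+1] - t[i] == rr[i+1]/1000` (to 1e-6 s).
#'
#' @param t Numeric vector of beat times in seconds, strictly increasing.
#' @param rr Numeric vector of RR intervals in milliseconds, all positive.
#' @param flag Character vector of per-beat labels; recycled if length 1.
#' @param subject_id Subject identifier string.
#' @param meta Optional single-row tibble of subject covariates
#'   (see [subject_record()]).
#' @param validate Check invariants (default `TRUE`).
#' @return A tibble of class `rr_series` with columns `t`, `rr`, `flag`.
#' @examples
#' rr_series(rr = c(1000, 990, 1010), subject_id = "s1")
#' @export
rr_series <- function(t = NULL, rr, flag = "normal", subject_id = "anon",
                      meta = NULL, validate = TRUE) {
  rr <- as.numeric(rr)
  if (is.null(t)) t <- cumsum(rr) / 1000 - rr[1] / 1000
  flag <- rep_len(as.character(flag), length(rr))
  out <- tibble::tibble(t = as.numeric(t), rr = rr, flag = flag)
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "meta") <- meta
  class(out) <- c("rr_series", class(out))
  if (validate) validate_rr_series(out)
  out
}

#' @exportS3Method base::print
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> subject %s: %d beats, %.2f h, mean RR %.0f ms\n",
              attr(x, "subject_id"), nrow(x), diff(range(x$t)) / 3600,
              mean(x$rr)))
  NextMethod()
}

validate_rr_series <- function(x) {
  if (nrow(x) < 2) abort("an rr_series needs at least 2 beats")
  if (any(!is.finite(x$rr)) || any(x$rr <= 0))
    abort("all RR intervals must be positive and finite")
  if (any(diff(x$t) <= 0)) abort("beat times must be strictly increasing")
  bad_flag <- setdiff(unique(x$flag), c("normal", "artifact", "corrected"))
  if (length(bad_flag))
    abort(paste0("unknown beat flag(s): ", paste(bad_flag, collapse = ", ")))
  norm <- x$flag == "normal"
  both <- which(norm[-1] & norm[-length(norm)])
  if (length(both)) {
    dt <- x$t[both + 1] - x$t[both]
    if (max(abs(dt - x$rr[both + 1] / 1000)) > 1e-6)
      abort("timestamps inconsistent with RR intervals for normal beats")
  }
  invisible(x)
}

#' Read an RR recording from disk
#'
#' Two minimal dialects are supported: `"rr_only"` (one RR interval in ms per
#' line; beat times reconstructed by cumulative sum) and `"time_rr_csv"` (CSV
#' with columns `t_s`, `rr_ms`; times taken verbatim and checked against the
#' intervals).
#'
#' @param path File path.
#' @param dialect `"rr_only"` or `"time_rr_csv"`.
#' @param subject_id Subject id; defaults to the file stem.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, dialect = c("rr_only", "time_rr_csv"),
                    subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "rr_only") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) abort(paste0("empty RR file: ", path))
    rr <- suppressWarnings(as.numeric(lines))
    bad <- which(!is.finite(rr) | rr <= 0)
    if (length(bad))
      abort(sprintf("non-positive or non-numeric RR at line %d of %s",
                    bad[1], path))
    rr_series(rr = rr, subject_id = subject_id)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("t_s", "rr_ms") %in% names(df)))
      abort("time_rr_csv dialect needs columns t_s, rr_ms")
    if (!nrow(df)) abort(paste0("empty RR file: ", path))
    bad <- which(!is.finite(df$rr_ms) | df$rr_ms <= 0)
    if (length(bad))
      abort(sprintf("non-positive or non-numeric RR at line %d of %s",
                    bad[1] + 1L, path))
    fl <- if ("flag" %in% names(df)) df$flag else "normal"
    rr_series(t = df$t_s, rr = df$rr_ms, flag = fl, subject_id = subject_id)
  }
}

#' Write an RR series to CSV
#'
#' Writes columns `t_s`, `rr_ms`, `flag`; [read_rr()] with the
#' `"time_rr_csv"` dialect round-trips it exactly.
#'
#' @param x An [rr_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(x, path) {
  readr::write_csv(
    tibble::tibble(t_s = x$t, rr_ms = x$rr, flag = x$flag), path,
    progress = FALSE)
  invisible(path)
}

#' Subject covariate record
#'
#' @param subject_id Identifier.
#' @param sex `"female"` or `"male"`.
#' @param age Age in years (> 0).
#' @param bmi Body-mass index, kg/m^2.
#' @param smoker Logical.
#' @param sbp,dbp Systolic/diastolic blood pressure, mmHg.
#' @param age_cut Boundary (years) between the young and old groups; the old
#'   group starts at the population's mean menopausal age, about 50 years.
#' @return One-row tibble with an `age_group` column.
#' @export
subject_record <- function(subject_id, sex, age, bmi = NA_real_,
                           smoker = NA, sbp = NA_real_, dbp = NA_real_,
                           age_cut = 50) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.finite(age) || age <= 0) abort("age must be positive")
  tibble::tibble(
    subject_id = as.character(subject_id), sex = sex, age = age,
    age_group = assign_age_group(age, age_cut),
    bmi = bmi, smoker = smoker, sbp = sbp, dbp = dbp)
}

#' Assign the young/old age group
#'
#' Subjects at or above the cut (default 50 years, the cohort's approximate
#' mean menopausal age) are `"old"`; the boundary is inclusive.
#'
#' @param age_years Numeric vector of ages, all > 0.
#' @param cut Boundary in years.
#' @return Character vector in `{"young", "old"}`.
#' @examples
#' assign_age_group(c(20, 49, 50, 72))
#' @export
assign_age_group <- function(age_years, cut = 50) {
  if (any(!is.finite(age_years) | age_years <= 0))
    abort("ages must be positive")
  ifelse(age_years >= cut, "old", "young")
}

#' Render an acrophase (clock hours) as hh:mm
#'
#' Floors to the minute, matching how peak times are reported.
#'
#' @param hours Numeric vector of clock hours in `[0, 24)`.
#' @return Character vector like `"18:42"`.
#' @examples
#' format_clock(18.7)
#' @export
format_clock <- function(hours) {
  hours <- hours %% 24
  mins <- floor(round(hours * 60, 6))
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}

#' Write result tables to CSV
#'
#' One CSV per table; any `acro_clock`/`acrophase_h` column is rendered
#' hh:mm. Output is byte-stable for identical inputs.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- purrr::imap_chr(tables, function(tab, nm) {
    tab <- tibble::as_tibble(tab)
    for (col in intersect(c("acrophase_h", "acro_clock", "acro_clock_h"),
                          names(tab))) {
      if (is.numeric(tab[[col]])) tab[[col]] <- format_clock(tab[[col]])
    }
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tab, p, progress = FALSE)
    p
  })
  invisible(unname(paths))
}

#' Default run configuration
#'
#' All pipeline tunables with their defaults, overridable by name. Units:
#' seconds for window/segment lengths, Hz for rates and band edges,
#' milliseconds where noted.
#'
#' @param ... Named overrides, e.g. `correction.threshold = 0.25`.
#' @return A named list of class `hrv_config`.
#' @export
hrv_config <- function(...) {
  cfg <- list(
    correction.threshold = 0.20,   # relative deviation flagging a beat
    correction.max_fraction = 0.05,  # reject recording above this corrected share
    correction.neighbors = 11L,
    detrend.lambda = 500,
    windows.length_s = 300,
    windows.stride_s = 30,
    spectral.rate_hz = 4,
    spectral.subsegment_s = 150,
    spectral.overlap = 0.5,
    spectral.pad_points_per_hz = 300,
    bands.vlf = c(0.0033, 0.04),
    bands.lf = c(0.04, 0.15),
    bands.hf = c(0.15, 0.5),
    nonlinear.sampen_m = 2L,
    nonlinear.sampen_r = 0.2,      # times the window SD
    nonlinear.dfa_range1 = c(4L, 16L),
    nonlinear.dfa_range2 = c(16L, 64L),
    nonlinear.embed_m = 10L,
    nonlinear.embed_delay = 1L,
    nonlinear.rqa_lmin = 2L,
    nonlinear.shannon_bin_ms = 50,
    autonomic.signs = c(1, 1, 1),  # mean HR, sqrt(SI), SD2 in the SNS index
    cosinor.period_h = 24,
    cosinor.min_hours = 20L,
    rhythm.alpha = 0.05,
    rhythm.period_band_h = 2,
    stats.multiplicity = "benjamini_hochberg",
    age_cut = 50,
    seed = 1L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg[names(ov)] <- ov
  for (b in c("bands.vlf", "bands.lf", "bands.hf"))
    if (diff(cfg[[b]]) <= 0) abort(paste0(b, " edges must be increasing"))
  if (cfg$bands.vlf[2] > cfg$bands.lf[1] || cfg$bands.lf[2] > cfg$bands.hf[1])
    abort("frequency bands must be ordered and non-overlapping")
  if (cfg$windows.length_s > 3600)
    abort("windows.length_s must be at most 3600")
  structure(cfg, class = c("hrv_config", "list"))
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose top-level keys are `hrv_config()` names.
#' @return An `hrv_config` list.
#' @export
read_config <- function(path) {
  do.call(hrv_config, yaml::read_yaml(path))
}
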