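#' Registered HRV metrics analyzed for circadian rhythmicity
#'
#' The 19 per-hour variables carried through cosinor rhythmometry: three
#' time-domain, four frequency-domain, nine nonlinear and three autonomic
#' indices.
#'
#' @return Tibble with columns `metric` and `unit`.
#' @export
metric_registry <- function() {
  tibble::tribble(
    ~metric,   ~unit,
    "sdnn",    "ms",
    "rmssd",   "ms",
    "pnn50",   "%",
    "hfn",     "%",
    "lfn",     "%",
    "vlf",     "ms2",
    "lf_hf",   "ratio",
    "sd1",     "ms",
    "sd2",     "ms",
    "sd2_sd1", "ratio",
    "apen",    "unitless",
    "alf1",    "unitless",
    "alf2",    "unitless",
    "corrdim", "unitless",
    "rec",     "%",
    "det",     "%",
    "snsi",    "z",
    "pnsi",    "z",
    "sti",     "z")
}

#' Assemble the hourly subject-by-hour-by-metric matrix
#'
#' Long-format container: one value per subject, hour and metric, taken from
#' the selected per-hour window. Missing windows propagate as missing rows.
#'
#' @param per_window_metrics Tibble with columns `subject_id`, `hour` and one
#'   column per metric.
#' @return Long tibble of class `hourly_matrix` with columns `subject_id`,
#'   `hour`, `metric`, `value` (plus `hour_mid`, the window midpoint in clock
#'   hours, when a `hour_mid` column is supplied).
#' @export
hourly_aggregate <- function(per_window_metrics) {
  stopifnot(all(c("subject_id", "hour") %in% names(per_window_metrics)))
  if (any(duplicated(per_window_metrics[c("subject_id", "hour")])))
    abort("duplicate (subject, hour) rows")
  id_cols <- intersect(c("subject_id", "hour", "hour_mid"),
                       names(per_window_metrics))
  out <- tidyr::pivot_longer(per_window_metrics,
                             cols = -dplyr::all_of(id_cols),
                             names_to = "metric", values_to = "value")
  class(out) <- c("hourly_matrix", class(out))
  out
}

#' Uniformity / rhythmicity screen for one metric
#'
#' Cross-validates two detectors on the hourly values of one metric:
#' a repeated-measures ANOVA with hour as the within-subject factor (a small
#' p rejects a uniform time-of-day distribution) and a non-negative
#' least-squares fit of cosine amplitudes over a candidate period grid
#' (48, 24, 12, 8, 6, 4.8, 4 h) to the subject-mean 24-point profile, whose
#' largest fitted amplitude names the dominant period. The metric is called
#' rhythmic when the ANOVA rejects uniformity at `alpha` and the dominant
#' period lies within `period_band_h` of 24 h.
#'
#' @param df Tibble with columns `subject_id`, `hour`, `value` for one metric.
#' @param alpha Significance level (default 0.05).
#' @param period_band_h Acceptance half-width around 24 h (default 2).
#' @return One-row tibble: `uniform_p`, `dominant_period_h`, `rhythmic`,
#'   `rationale`.
#' @export
uniformity_test <- function(df, alpha = 0.05, period_band_h = 2) {
  df <- df[is.finite(df$value), ]
  wide <- tidyr::pivot_wider(df[c("subject_id", "hour", "value")],
                             names_from = "hour", values_from = "value")
  complete <- wide[complete.cases(wide), ]
  if (nrow(complete) < 2 || sd(df$value) == 0) {
    return(tibble::tibble(uniform_p = 1, dominant_period_h = NA_real_,
                          rhythmic = FALSE,
                          rationale = "constant or insufficient data"))
  }
  long <- tidyr::pivot_longer(complete, -"subject_id",
                              names_to = "hour", values_to = "value")
  long$hour <- factor(long$hour)
  long$subject_id <- factor(long$subject_id)
  fit <- aov(value ~ hour + Error(subject_id), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  uniform_p <- tab["hour", "Pr(>F)"]
  # FFT-NNLS on the subject-mean profile
  prof <- dplyr::summarise(dplyr::group_by(df, .data$hour),
                           value = mean(.data$value), .groups = "drop")
  t <- prof$hour
  y <- prof$value - mean(prof$value)
  periods <- c(48, 24, 12, 8, 6, 4.8, 4)
  cols <- purrr::map(periods, function(p) {
    b <- coef(lm(y ~ cos(2 * pi * t / p) + sin(2 * pi * t / p) - 1))
    phi <- atan2(b[2], b[1])
    cos(2 * pi * t / p - phi)   # unit-amplitude, phase-aligned regressor
  })
  X <- do.call(cbind, cols)
  amps <- pracma::lsqnonneg(X, y)$x
  dom <- if (all(amps <= 0)) NA_real_ else periods[which.max(amps)]
  rhythmic <- is.finite(uniform_p) && uniform_p < alpha &&
    !is.na(dom) && abs(dom - 24) <= period_band_h
  tibble::tibble(
    uniform_p = uniform_p, dominant_period_h = dom, rhythmic = rhythmic,
    rationale = sprintf("RM-ANOVA p=%.3g; dominant period %s h",
                        uniform_p, format(dom)))
}

#' Single-component cosinor fit
#'
#' Fits `Y(t) = M + A*cos(2*pi*t/T + phi)` by the standard linearization
#' `Y = M + beta*cos(2*pi*t/T) + gamma*sin(2*pi*t/T)` solved by ordinary
#' least squares, with `A = sqrt(beta^2 + gamma^2)` and
#' `phi = atan2(-gamma, beta)` mapped into `(-2*pi, 0]`. The zero-amplitude
#' F test compares against the intercept-only model; confidence intervals
#' for M, A and phi come from the delta method.
#'
#' @param values Response values (one metric's hourly means).
#' @param hours Time of each value in clock hours, in `[0, 24)` (fractions
#'   allowed; window midpoints recommended).
#' @param period Fixed period T in hours (default 24).
#' @param level Confidence level (default 0.95).
#' @return Object of class `cosinor_fit`: a list with `mesor`, `amplitude`,
#'   `phi_rad`, `acro_clock_h`, `beta`, `gamma`, `period`, `n`, `rss`,
#'   `F_zero_amp`, `p_zero_amp`, `se` and `ci` components.
#' @examples
#' h <- 0:23
#' y <- 10 + 3 * cos(2 * pi * (h - 18) / 24)
#' cosinor_fit(y, h)
#' @export
cosinor_fit <- function(values, hours, period = 24, level = 0.95) {
  ok <- is.finite(values) & is.finite(hours)
  y <- values[ok]; t <- hours[ok]
  n <- length(y)
  if (n < 4) abort("need at least 4 non-missing points for a cosinor fit")
  if (length(unique(t)) < 3) abort("need at least 3 distinct time points")
  x <- cos(2 * pi * t / period)
  z <- sin(2 * pi * t / period)
  fit <- lm(y ~ x + z)
  b <- coef(fit)
  M <- unname(b[1]); beta <- unname(b[2]); gamma <- unname(b[3])
  A <- sqrt(beta^2 + gamma^2)
  phi <- atan2(-gamma, beta)
  if (phi > 0) phi <- phi - 2 * pi          # canonical range (-2*pi, 0]
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  Fz <- if (tss <= 0) 0                     # constant profile: no rhythm
        else if (rss > 0) ((tss - rss) / 2) / (rss / (n - 3))
        else Inf                            # perfect rhythmic fit
  pz <- pf(Fz, 2, n - 3, lower.tail = FALSE)
  V <- tryCatch(suppressWarnings(stats::vcov(fit)),
                error = function(e) matrix(NA, 3, 3))
  se_M <- sqrt(V[1, 1])
  gA <- if (A > 0) c(0, beta / A, gamma / A) else c(0, 1, 0)
  se_A <- sqrt(drop(t(gA) %*% V %*% gA))
  gP <- if (A > 0) c(0, gamma / A^2, -beta / A^2) else c(0, 0, 1)
  se_phi <- sqrt(drop(t(gP) %*% V %*% gP))
  zq <- qnorm(1 - (1 - level) / 2)
  out <- list(
    mesor = M, amplitude = A, phi_rad = phi,
    acro_clock_h = acrophase_to_clock(phi, period),
    beta = beta, gamma = gamma, period = period, n = n,
    rss = rss, F_zero_amp = Fz, p_zero_amp = pz,
    se = c(mesor = se_M, amplitude = se_A, phi_rad = se_phi),
    ci = tibble::tibble(
      term = c("mesor", "amplitude", "phi_rad"),
      estimate = c(M, A, phi),
      conf.low = c(M - zq * se_M, A - zq * se_A, phi - zq * se_phi),
      conf.high = c(M + zq * se_M, A + zq * se_A, phi + zq * se_phi)),
    data = tibble::tibble(hours = t, values = y))
  class(out) <- "cosinor_fit"
  out
}

#' @exportS3Method base::print
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(paste0("<cosinor_fit> T=%g h, n=%d\n",
                     "  MESOR %.4g  amplitude %.4g  acrophase %s",
                     "  (zero-amplitude p=%.3g)\n"),
              x$period, x$n, x$mesor, x$amplitude,
              format_clock(x$acro_clock_h), x$p_zero_amp))
  invisible(x)
}

#' Convert an acrophase angle to clock hours
#'
#' @param phi_rad Acrophase in radians (any finite value; normalized
#'   internally).
#' @param period Period in hours (default 24).
#' @return Clock time of the fitted peak in hours, in `[0, period)`.
#' @examples
#' acrophase_to_clock(-3 * pi / 2)  # 18
#' @export
acrophase_to_clock <- function(phi_rad, period = 24) {
  out <- ((-phi_rad) * period / (2 * pi)) %% period
  ifelse(out >= period, 0, out)   # floating-point wrap guard
}

#' @rdname cosinor_fit
#' @param x A `cosinor_fit` object.
#' @param ... Unused.
#' @export
tidy.cosinor_fit <- function(x, ...) {
  dplyr::mutate(x$ci, std.error = unname(x$se[x$ci$term]))
}

#' @rdname cosinor_fit
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(mesor = x$mesor, amplitude = x$amplitude,
                 acro_clock_h = x$acro_clock_h, period = x$period,
                 n = x$n, rss = x$rss, statistic = x$F_zero_amp,
                 p.value = x$p_zero_amp)
}

#' @rdname cosinor_fit
#' @param object A `cosinor_fit` object.
#' @export
autoplot.cosinor_fit <- function(object, ...) {
  grid <- tibble::tibble(hours = seq(0, object$period, length.out = 241))
  grid$fit <- object$mesor + object$amplitude *
    cos(2 * pi * grid$hours / object$period + object$phi_rad)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$hours, y = .data$values)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$acro_clock_h, linetype = 2) +
    ggplot2::labs(x = "clock hour", y = "value",
                  title = sprintf("Cosinor fit: M=%.3g, A=%.3g, peak %s",
                                  object$mesor, object$amplitude,
                                  format_clock(object$acro_clock_h))) +
    ggplot2::theme_minimal()
}

#' Fit cosinor models across a cohort
#'
#' Per-subject, per-metric cosinor fits of the hourly matrix, plus one
#' rhythmicity decision per metric. Metrics failing the rhythmicity screen
#' are flagged but still fitted; per-cell failures (too few valid hours) are
#' recorded as missing.
#'
#' @param hm Long hourly matrix from [hourly_aggregate()].
#' @param period Cosinor period, h (default 24).
#' @param min_hours Minimum non-missing hours per (subject, metric) cell
#'   (default 20).
#' @param alpha,period_band_h Passed to [uniformity_test()].
#' @return List with `fits` (tibble: subject, metric, mesor, amplitude,
#'   acrophase etc.) and `decisions` (one row per metric).
#' @export
fit_cohort <- function(hm, period = 24, min_hours = 20, alpha = 0.05,
                       period_band_h = 2) {
  tcol <- if ("hour_mid" %in% names(hm)) "hour_mid" else "hour"
  metrics <- unique(hm$metric)
  decisions <- purrr::map_dfr(metrics, function(m) {
    sub <- hm[hm$metric == m, ]
    dplyr::bind_cols(tibble::tibble(metric = m),
                     uniformity_test(sub, alpha, period_band_h))
  })
  fits <- purrr::map_dfr(metrics, function(m) {
    sub <- hm[hm$metric == m, ]
    purrr::map_dfr(split(sub, sub$subject_id), function(d) {
      ok <- sum(is.finite(d$value))
      base <- tibble::tibble(subject_id = d$subject_id[1], metric = m)
      if (ok < max(4, min_hours))
        return(dplyr::mutate(base, mesor = NA_real_, amplitude = NA_real_,
                             acro_clock_h = NA_real_, phi_rad = NA_real_,
                             p_zero_amp = NA_real_, n = ok))
      f <- tryCatch(cosinor_fit(d$value, d[[tcol]], period),
                    error = function(e) NULL)
      if (is.null(f))
        return(dplyr::mutate(base, mesor = NA_real_, amplitude = NA_real_,
                             acro_clock_h = NA_real_, phi_rad = NA_real_,
                             p_zero_amp = NA_real_, n = ok))
      dplyr::mutate(base, mesor = f$mesor, amplitude = f$amplitude,
                    acro_clock_h = f$acro_clock_h, phi_rad = f$phi_rad,
                    p_zero_amp = f$p_zero_amp, n = f$n)
    })
  })
  fits <- dplyr::left_join(fits, decisions[c("metric", "rhythmic")],
                           by = "metric")
  list(fits = fits, decisions = decisions)
}
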