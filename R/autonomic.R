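#' Baevsky's stress index
#'
#' From the RR histogram with fixed 50 ms bins anchored at 0:
#' `SI = AMo / (2 * Mo * MxDMn)`, with the mode `Mo` (center of the modal
#' bin) and the range `MxDMn` in seconds and `AMo` the modal bin's share of
#' beats in percent.
#'
#' @param rr NN intervals (ms), at least 50 beats.
#' @param bin_width_ms Histogram bin width (default 50 ms).
#' @return One-row tibble: `mo` (s), `amo` (%), `mxdmn` (s), `si`.
#' @examples
#' baevsky_si(rep(c(900, 950, 950, 1000), 25))
#' @export
baevsky_si <- function(rr, bin_width_ms = 50) {
  n <- length(rr)
  if (n < 50) abort("need at least 50 beats")
  mxdmn <- (max(rr) - min(rr)) / 1000
  if (mxdmn == 0) abort("degenerate distribution: constant RR")
  bin <- floor(rr / bin_width_ms)            # bins anchored at 0
  counts <- table(bin)
  modal <- as.integer(names(counts)[which.max(counts)])
  mo <- (modal + 0.5) * bin_width_ms / 1000  # bin center, seconds
  amo <- 100 * max(counts) / n
  tibble::tibble(mo = mo, amo = amo, mxdmn = mxdmn,
                 si = amo / (2 * mo * mxdmn))
}

#' Normative reference for the autonomic indices
#'
#' Means and SDs of the six components entering the composite indices. Real
#' analyses must supply population norms; [synthetic_norms()] provides a
#' clearly tagged stand-in estimated from the packaged synthetic cohort.
#'
#' @param mean_rr,rmssd,sd1,mean_hr,sqrt_si,sd2 Length-2 numeric vectors
#'   `c(mean, sd)`; all SDs must be positive.
#' @param provenance Free-text provenance tag.
#' @return Tibble with columns `component`, `mean`, `sd` and a `provenance`
#'   attribute.
#' @export
normative_reference <- function(mean_rr, rmssd, sd1, mean_hr, sqrt_si, sd2,
                                provenance = "user") {
  vals <- list(mean_rr = mean_rr, rmssd = rmssd, sd1 = sd1,
               mean_hr = mean_hr, sqrt_si = sqrt_si, sd2 = sd2)
  out <- tibble::tibble(component = names(vals),
                        mean = purrr::map_dbl(vals, 1),
                        sd = purrr::map_dbl(vals, 2))
  if (any(out$sd <= 0)) abort("all normative SDs must be positive")
  attr(out, "provenance") <- provenance
  out
}

#' Synthetic stand-in normative reference
#'
#' Estimates component means and SDs from per-window metrics of a small
#' synthetic cohort generated at a fixed seed. Tagged `"synthetic"`; not a
#' population norm.
#'
#' @param windows Per-window metric tibble (as produced by the pipeline)
#'   with columns `mean_rr`, `rmssd`, `sd1`, `mean_hr`, `si`, `sd2`. When
#'   `NULL`, a tiny internal cohort is generated and summarised.
#' @return A [normative_reference()] tibble tagged `"synthetic"`.
#' @export
synthetic_norms <- function(windows = NULL) {
  if (is.null(windows)) {
    spec <- synth_cohort_spec(n_per_group = 1, ectopic_rate = 0, duration = 24,
                              seed = 20260101L)
    coh <- generate_cohort(spec)
    windows <- purrr::map_dfr(coh$series, function(s) {
      wp <- select_hourly_windows(s)
      wp <- wp[!wp$missing, ][seq(1, 24, by = 4), ]  # 6 windows per subject
      purrr::pmap_dfr(wp, function(start_s, end_s, ...) {
        rr <- window_rr(s, start_s, end_s)
        dplyr::bind_cols(time_domain(rr), poincare(rr)[, c("sd1", "sd2")],
                         baevsky_si(rr)[, "si"])
      })
    })
  }
  ms <- function(v) c(mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))
  normative_reference(mean_rr = ms(windows$mean_rr), rmssd = ms(windows$rmssd),
                      sd1 = ms(windows$sd1), mean_hr = ms(windows$mean_hr),
                      sqrt_si = ms(sqrt(windows$si)), sd2 = ms(windows$sd2),
                      provenance = "synthetic")
}

.classify_pm1 <- function(z) {
  dplyr::case_when(is.na(z) ~ NA_character_, z > 1 ~ "high", z < -1 ~ "low",
                   TRUE ~ "normal")
}

#' Composite autonomic indices (PNS, SNS, stress)
#'
#' Each component is z-scored against the normative reference. The
#' parasympathetic index averages z(mean RR), z(RMSSD) and z(SD1); the
#' sympathetic index averages z(mean HR), z(sqrt(SI)) and z(SD2) with a
#' configurable sign vector (all +1 by default); the stress index is
#' z(sqrt(SI)). Values beyond one SD of the norm are classified
#' `"high"`/`"low"`.
#'
#' @param mean_rr,rmssd,sd1,mean_hr,si,sd2 Component values for one window
#'   (ms / bpm / unitless as appropriate; `si` is the raw Baevsky index).
#' @param norms A [normative_reference()].
#' @param signs Length-3 sign vector for the SNS components
#'   (mean HR, sqrt(SI), SD2).
#' @return One-row tibble: `pnsi`, `snsi`, `sti` (z units) and
#'   `pnsi_class`, `snsi_class`, `sti_class`.
#' @export
autonomic_indices <- function(mean_rr, rmssd, sd1, mean_hr, si, sd2,
                              norms, signs = c(1, 1, 1)) {
  nm <- setNames(norms$mean, norms$component)
  ns <- setNames(norms$sd, norms$component)
  z <- function(x, comp) (x - nm[[comp]]) / ns[[comp]]
  pnsi <- mean(c(z(mean_rr, "mean_rr"), z(rmssd, "rmssd"), z(sd1, "sd1")))
  snsi <- mean(c(signs[1] * z(mean_hr, "mean_hr"),
                 signs[2] * z(sqrt(si), "sqrt_si"),
                 signs[3] * z(sd2, "sd2")))
  sti <- z(sqrt(si), "sqrt_si")
  tibble::tibble(pnsi = pnsi, snsi = snsi, sti = sti,
                 pnsi_class = .classify_pm1(pnsi),
                 snsi_class = .classify_pm1(snsi),
                 sti_class = .classify_pm1(sti))
}
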