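#' Time-domain HRV metrics for one window
#'
#' Sample (n-1) standard deviations throughout; pNN50 counts successive
#' differences strictly greater than 50 ms.
#'
#' @param rr Numeric vector of NN intervals (ms), length >= 2.
#' @return One-row tibble: `mean_rr` (ms), `mean_hr` (bpm), `sdnn` (ms),
#'   `rmssd` (ms), `pnn50` (%).
#' @examples
#' time_domain(c(1000, 1100))
#' @export
time_domain <- function(rr) {
  n <- length(rr)
  if (n < 2) abort("need at least 2 NN intervals")
  d <- diff(rr)
  tibble::tibble(
    mean_rr = mean(rr),
    mean_hr = 60000 / mean(rr),
    sdnn = sd(rr),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * sum(abs(d) > 50) / (n - 1))
}

#' SDANN: standard deviation of segment-mean NN intervals
#'
#' Computed over the mean NN of the selected per-hour windows (sample SD).
#'
#' @param segment_means Numeric vector of per-segment mean NN (ms); `NA`s
#'   (missing hours) are dropped.
#' @return SDANN in ms.
#' @export
sdann <- function(segment_means) {
  v <- segment_means[!is.na(segment_means)]
  if (length(v) < 2) abort("need at least 2 segment means")
  sd(v)
}

#' Heart-rate correction of a variability metric
#'
#' Divides a millisecond-scale metric by the window's mean RR, removing the
#' mechanical dependence of variability magnitude on heart rate. The exact
#' published correction is not uniquely determined, so the correction
#' function is pluggable; division by mean RR reproduces the expected
#' magnitudes (e.g. SDNN 32.9 ms at mean RR 914 ms gives 0.036).
#'
#' @param metric_ms Metric value in ms.
#' @param mean_rr_ms Window mean RR in ms (> 0).
#' @param fun Correction function `(metric, mean_rr) -> corrected`; default
#'   division.
#' @return Dimensionless corrected value.
#' @export
hr_correct <- function(metric_ms, mean_rr_ms,
                       fun = function(m, mrr) m / mrr) {
  if (any(mean_rr_ms <= 0)) abort("mean_rr_ms must be positive")
  fun(metric_ms, mean_rr_ms)
}
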