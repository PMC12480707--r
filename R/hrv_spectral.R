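#' Evenly resample an RR window by cubic-spline interpolation
#'
#' @param rr NN intervals (ms) of one window.
#' @param t Beat times (s); defaults to the cumulative sum of `rr`.
#' @param rate Sampling rate in Hz (default 4).
#' @return Tibble with columns `t` (s) and `rr` (ms), `floor(span * rate)`
#'   samples spaced `1/rate` s.
#' @export
interpolate_rr <- function(rr, t = NULL, rate = 4) {
  if (rate <= 0) abort("rate must be positive")
  if (is.null(t)) t <- cumsum(rr) / 1000 - rr[1] / 1000
  if (length(rr) < 4 || diff(range(t)) < 60)
    abort("window must have >= 4 beats spanning >= 60 s")
  span <- t[length(t)] - t[1]
  m <- floor(span * rate)
  grid <- t[1] + (seq_len(m) - 1) / rate
  sf <- splinefun(t, rr, method = "fmm")
  tibble::tibble(t = grid, rr = sf(grid))
}

# 4-term Blackman-Harris taper (-92 dB sidelobes)
blackman_harris <- function(n) {
  k <- seq_len(n) - 1
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  a[1] - a[2] * cos(2 * pi * k / (n - 1)) +
    a[3] * cos(4 * pi * k / (n - 1)) - a[4] * cos(6 * pi * k / (n - 1))
}

#' Welch power spectral density with Blackman-Harris tapering
#'
#' Averages FFT periodograms over `subsegment_s`-second sub-segments with
#' `overlap` fractional overlap. Each sub-segment is detrended with the
#' smoothness-priors smoother, tapered with a 4-term Blackman-Harris window,
#' and zero-padded so the one-sided frequency grid has at least
#' `pad_points_per_hz` points per Hz. The taper-power normalisation makes
#' the PSD integral equal the variance of the detrended input (Parseval).
#'
#' @param samples Evenly sampled RR (ms), e.g. `interpolate_rr()$rr`;
#'   at least 256 samples.
#' @param rate Sampling rate, Hz (default 4).
#' @param subsegment_s Sub-segment length, s (default 150).
#' @param overlap Fractional overlap between sub-segments (default 0.5).
#' @param pad_points_per_hz Minimum frequency-grid density (default 300).
#' @param detrend_lambda Smoothness-priors lambda (default 500); 0 removes
#'   only the mean.
#' @return Tibble with columns `freq` (Hz) and `psd` (ms^2/Hz), one-sided.
#' @export
estimate_psd <- function(samples, rate = 4, subsegment_s = 150,
                         overlap = 0.5, pad_points_per_hz = 300,
                         detrend_lambda = 500) {
  n <- length(samples)
  if (n < 256) abort("need at least 256 samples")
  seg_len <- round(subsegment_s * rate)
  if (seg_len > n) {
    warn("fewer samples than one sub-segment; single-segment periodogram")
    seg_len <- n
  }
  step <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  nfft <- 2^ceiling(log2(max(seg_len, pad_points_per_hz * rate)))
  w <- blackman_harris(seg_len)
  wpow <- sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s0 in starts) {
    seg <- samples[s0:(s0 + seg_len - 1)]
    seg <- if (detrend_lambda > 0) detrend_smoothness_priors(seg, detrend_lambda)
           else seg - mean(seg)
    X <- fft(c(seg * w, numeric(nfft - seg_len)))
    P <- (Mod(X)^2 / (rate * wpow))[1:(nfft %/% 2 + 1)]
    P[2:(nfft %/% 2)] <- 2 * P[2:(nfft %/% 2)]  # one-sided
    acc <- acc + P
  }
  tibble::tibble(freq = (0:(nfft %/% 2)) * rate / nfft,
                 psd = acc / length(starts))
}

# trapezoidal integral of the psd over [lo, hi], with linear interpolation
# of the density at the exact band edges so adjacent bands tile exactly
.band_integral <- function(freq, psd, lo, hi) {
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  p <- c(approx(freq, psd, lo, rule = 2)$y, psd[inside],
         approx(freq, psd, hi, rule = 2)$y)
  pracma::trapz(f, p)
}

#' Integrate band powers from a PSD
#'
#' Absolute powers by trapezoidal integration over the very-low (0.0033-0.04
#' Hz), low (0.04-0.15 Hz) and high (0.15-0.5 Hz) frequency bands; normalized
#' powers use the LF+HF denominator (so `lfn + hfn = 100`).
#'
#' @param psd Tibble from [estimate_psd()].
#' @param bands List with elements `vlf`, `lf`, `hf`, each `c(lo, hi)` in Hz.
#' @return One-row tibble: `vlf`, `lf`, `hf` (ms^2), `lfn`, `hfn` (%),
#'   `lf_hf` (ratio; `NA` when HF power is zero).
#' @export
band_powers <- function(psd, bands = .default_bands) {
  if (min(psd$freq) > bands$vlf[1] || max(psd$freq) < bands$hf[2])
    abort("psd grid does not cover the requested bands")
  vlf <- .band_integral(psd$freq, psd$psd, bands$vlf[1], bands$vlf[2])
  lf <- .band_integral(psd$freq, psd$psd, bands$lf[1], bands$lf[2])
  hf <- .band_integral(psd$freq, psd$psd, bands$hf[1], bands$hf[2])
  tot <- lf + hf
  tibble::tibble(
    vlf = vlf, lf = lf, hf = hf,
    lfn = if (tot > 0) 100 * lf / tot else NA_real_,
    hfn = if (tot > 0) 100 * hf / tot else NA_real_,
    lf_hf = if (hf > 0) lf / hf else NA_real_)
}

#' Spectral HRV metrics for one RR window
#'
#' Convenience wrapper: resample, estimate the Welch/Blackman-Harris PSD and
#' integrate band powers.
#'
#' @inheritParams interpolate_rr
#' @inheritParams estimate_psd
#' @param bands Band edges as in [band_powers()].
#' @return One-row tibble as returned by [band_powers()].
#' @export
spectral_metrics <- function(rr, t = NULL, rate = 4, subsegment_s = 150,
                             overlap = 0.5, pad_points_per_hz = 300,
                             detrend_lambda = 500, bands = .default_bands) {
  s <- interpolate_rr(rr, t, rate)
  psd <- estimate_psd(s$rr, rate, subsegment_s, overlap, pad_points_per_hz,
                      detrend_lambda)
  band_powers(psd, bands)
}
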