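#' Poincare plot descriptors
#'
#' Population-variance convention, so the identities
#' `sd1^2 = Var(diff(rr))/2` and `sd1^2 + sd2^2 = 2*Var(rr)` hold exactly.
#'
#' @param rr NN intervals (ms), length >= 3.
#' @return One-row tibble: `sd1`, `sd2` (ms), `sd2_sd1`.
#' @export
poincare <- function(rr) {
  n <- length(rr)
  if (n < 3) abort("need at least 3 intervals")
  popvar <- function(v) mean((v - mean(v))^2)
  sd1sq <- popvar(diff(rr)) / 2
  sd2sq <- max(2 * popvar(rr) - sd1sq, 0)
  sd1 <- sqrt(sd1sq); sd2 <- sqrt(sd2sq)
  tibble::tibble(sd1 = sd1, sd2 = sd2,
                 sd2_sd1 = if (sd1 > 0) sd2 / sd1 else NA_real_)
}

# root-mean-square residual around per-box linear trends, one box size
.dfa_fluct <- function(y, s) {
  n <- length(y)
  m <- n %/% s
  if (m < 1) return(NA_real_)
  yb <- matrix(y[seq_len(m * s)], nrow = s)
  i <- seq_len(s) - (s + 1) / 2          # centered index within a box
  sii <- sum(i^2)
  cm <- colMeans(yb)
  slope <- colSums(yb * i) / sii
  ssr <- colSums(yb^2) - s * cm^2 - slope^2 * sii
  sqrt(mean(pmax(ssr, 0)) / s)
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centered series, removes per-box linear trends for
#' every integer box size in the two ranges, and reports the log-log OLS
#' slopes: the short-range exponent `alf1` (boxes 4-16) and long-range
#' `alf2` (boxes 16-64).
#'
#' @param rr NN intervals (ms), at least 200 beats.
#' @param range1,range2 Inclusive box-size ranges (beats).
#' @return One-row tibble: `alf1`, `alf2`.
#' @export
dfa <- function(rr, range1 = c(4, 16), range2 = c(16, 64)) {
  n <- length(rr)
  if (n < 200) abort("need at least 200 beats for DFA")
  y <- cumsum(rr - mean(rr))
  fit_range <- function(r) {
    s <- seq.int(r[1], min(r[2], n %/% 2))
    f <- vapply(s, function(si) .dfa_fluct(y, si), numeric(1))
    ok <- is.finite(f) & f > 0
    if (sum(ok) < 2) abort("degenerate fluctuation (constant series?)")
    unname(coef(lm(log(f[ok]) ~ log(s[ok])))[2])
  }
  tibble::tibble(alf1 = fit_range(range1), alf2 = fit_range(range2))
}

#' Approximate, sample and Shannon entropy of an RR window
#'
#' ApEn uses the canonical convention with self-matches included
#' (`phi^m - phi^(m+1)`); SampEn excludes self-matches and uses Chebyshev
#' distance with the tolerance `r = r_frac * SD(window)`. ShanEn is the
#' Shannon entropy (bits) of the RR histogram with fixed-width bins anchored
#' at the observed minimum.
#'
#' @param rr NN intervals (ms); at least 100 beats for ApEn/SampEn.
#' @param m Template length (default 2).
#' @param r_frac Tolerance as a fraction of the window SD (default 0.2).
#' @param shan_bin_ms Histogram bin width for ShanEn, ms (default 50).
#' @return One-row tibble: `apen`, `sampen`, `shanen` (`sampen` is `NA` when
#'   no template pair matches at length m+1).
#' @export
entropies <- function(rr, m = 2, r_frac = 0.2, shan_bin_ms = 50) {
  n <- length(rr)
  if (n < 100) abort("need at least 100 beats for ApEn/SampEn")
  s <- sd(rr)
  if (s == 0) abort("zero-variance window: ApEn/SampEn undefined")
  r <- r_frac * s
  cnt <- entropy_counts_cpp(rr, as.integer(m), r)
  apen <- cnt$phi_m - cnt$phi_m1
  sampen <- if (cnt$A > 0) -log(cnt$A / cnt$B) else NA_real_
  breaks <- seq(min(rr), max(rr) + shan_bin_ms, by = shan_bin_ms)
  p <- tabulate(findInterval(rr, breaks), nbins = length(breaks)) / n
  p <- p[p > 0]
  tibble::tibble(apen = apen, sampen = sampen,
                 shanen = -sum(p * log2(p)))
}

# delay embedding: rows are m-dimensional state vectors
.embed_delay <- function(x, m, delay) {
  n <- length(x) - (m - 1) * delay
  if (n < 2) abort("series too short for the requested embedding")
  sapply(0:(m - 1), function(k) x[(1:n) + k * delay])
}

#' Grassberger-Procaccia correlation dimension
#'
#' Embeds the window (dimension `m`, unit delay), computes correlation sums
#' on a log-spaced radius grid, and reports the slope of `log C(r)` vs
#' `log r` over the scaling region, chosen as the widest contiguous grid
#' interval whose local slopes stay within 15% of their mean.
#'
#' @param rr NN intervals (ms), at least 500 beats.
#' @param m Embedding dimension (default 10).
#' @param delay Embedding delay in beats (default 1).
#' @param n_grid Number of radius grid points (default 24).
#' @return Correlation dimension (scalar).
#' @export
correlation_dimension <- function(rr, m = 10, delay = 1, n_grid = 24) {
  if (length(rr) < 500) abort("need at least 500 beats for CorrDim")
  if (sd(rr) == 0) abort("degenerate embedding: zero variance")
  emb <- .embed_delay(rr, m, delay)
  # radius grid between small and near-maximal pairwise distances
  samp <- emb[seq(1, nrow(emb), length.out = min(200, nrow(emb))), , drop = FALSE]
  dists <- as.numeric(stats::dist(samp))
  rgrid <- exp(seq(log(quantile(dists, 0.01)), log(max(dists)),
                   length.out = n_grid))
  C <- corr_sums_cpp(emb, rgrid)
  ok <- C > 0
  lr <- log(rgrid[ok]); lc <- log(C[ok])
  slopes <- diff(lc) / diff(lr)
  G <- length(slopes)
  best <- c(1, 1)
  for (i in seq_len(G)) for (j in i:G) {
    sl <- slopes[i:j]
    mu <- mean(sl)
    if (mu > 0 && max(abs(sl - mu)) / mu < 0.15 &&
        (lr[j + 1] - lr[i]) > (lr[best[2] + 1] - lr[best[1]]))
      best <- c(i, j)
  }
  idx <- best[1]:(best[2] + 1)
  unname(coef(lm(lc[idx] ~ lr[idx]))[2])
}

#' Recurrence quantification of an RR window
#'
#' Builds the recurrence matrix of the delay embedding (Euclidean norm,
#' threshold `r`, diagonal excluded) and reports the recurrence rate REC and
#' determinism DET (share of recurrent points lying on diagonal lines of
#' length at least `lmin`).
#'
#' @param rr NN intervals (ms); needs `m * delay + 50` beats.
#' @param m,delay Embedding dimension and delay (defaults 10, 1).
#' @param r Recurrence threshold; default `sqrt(m) * SD(rr)`.
#' @param lmin Minimum diagonal line length (default 2).
#' @return One-row tibble: `rec`, `det` (both %).
#' @export
rqa <- function(rr, m = 10, delay = 1, r = NULL, lmin = 2) {
  if (length(rr) < m * delay + 50) abort("series too short for RQA")
  if (is.null(r)) r <- sqrt(m) * sd(rr)
  if (r <= 0) abort("recurrence threshold must be positive")
  emb <- .embed_delay(rr, m, delay)
  res <- rqa_cpp(emb, r, as.integer(lmin))
  tibble::tibble(rec = res$rec, det = res$det)
}

#' All nonlinear metrics for one window
#'
#' Metrics whose preconditions the window does not meet (e.g. correlation
#' dimension on windows shorter than 500 beats) are returned as `NA`.
#'
#' @param rr NN intervals (ms).
#' @param cfg An [hrv_config()] supplying the nonlinear parameter block.
#' @return One-row tibble: `sd1`, `sd2`, `sd2_sd1`, `alf1`, `alf2`, `apen`,
#'   `sampen`, `shanen`, `corrdim`, `rec`, `det`.
#' @export
nonlinear_metrics <- function(rr, cfg = hrv_config()) {
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  pc <- safe(poincare(rr))
  df <- safe(dfa(rr, cfg$nonlinear.dfa_range1, cfg$nonlinear.dfa_range2))
  en <- safe(entropies(rr, cfg$nonlinear.sampen_m, cfg$nonlinear.sampen_r,
                       cfg$nonlinear.shannon_bin_ms))
  cd <- safe(correlation_dimension(rr, cfg$nonlinear.embed_m,
                                   cfg$nonlinear.embed_delay))
  rq <- safe(rqa(rr, cfg$nonlinear.embed_m, cfg$nonlinear.embed_delay,
                 lmin = cfg$nonlinear.rqa_lmin))
  tibble::tibble(
    sd1 = pc$sd1 %||% NA_real_, sd2 = pc$sd2 %||% NA_real_,
    sd2_sd1 = pc$sd2_sd1 %||% NA_real_,
    alf1 = df$alf1 %||% NA_real_, alf2 = df$alf2 %||% NA_real_,
    apen = en$apen %||% NA_real_, sampen = en$sampen %||% NA_real_,
    shanen = en$shanen %||% NA_real_,
    corrdim = cd %||% NA_real_,
    rec = rq$rec %||% NA_real_, det = rq$det %||% NA_real_)
}
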