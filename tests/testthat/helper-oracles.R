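# Independent oracles used to validate the package's implementations.
# Each is written as a direct, literal transcription of the defining
# formula, favouring clarity over speed.

# brute-force template counting for ApEn (self-matches in) and SampEn
# (self-matches out), Chebyshev distance
oracle_entropies <- function(x, m, r) {
  n <- length(x)
  cheb <- function(i, j, len) max(abs(x[i + 0:(len - 1)] - x[j + 0:(len - 1)]))
  phi <- function(len) {
    N <- n - len + 1
    mean(sapply(seq_len(N), function(i)
      log(sum(sapply(seq_len(N), function(j) cheb(i, j, len) <= r)) / N)))
  }
  apen <- phi(m) - phi(m + 1)
  N <- n - m
  A <- 0; B <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    if (cheb(i, j, m) <= r) {
      B <- B + 1
      if (cheb(i, j, m + 1) <= r) A <- A + 1
    }
  }
  list(apen = apen, sampen = if (A > 0) -log(A / B) else NA_real_)
}

# textbook DFA: integrate, split into non-overlapping boxes, fit a line in
# each box by lm, RMS the residuals, regress log F on log s
oracle_dfa <- function(x, smin, smax) {
  y <- cumsum(x - mean(x))
  n <- length(y)
  ss <- smin:min(smax, n %/% 2)
  Fs <- sapply(ss, function(s) {
    m <- n %/% s
    res2 <- numeric(0)
    for (b in seq_len(m)) {
      idx <- ((b - 1) * s + 1):(b * s)
      fit <- lm(y[idx] ~ idx)
      res2 <- c(res2, residuals(fit)^2)
    }
    sqrt(mean(res2))
  })
  unname(coef(lm(log(Fs) ~ log(ss)))[2])
}

# plain double-loop correlation sums over a radius grid
oracle_corr_sums <- function(emb, rgrid) {
  N <- nrow(emb)
  cnt <- numeric(length(rgrid))
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    d <- sqrt(sum((emb[i, ] - emb[j, ])^2))
    cnt <- cnt + (d <= rgrid)
  }
  cnt / (N * (N - 1) / 2)
}

# exact two-sided Mann-Whitney p by direct enumeration of group
# assignments, computing U from the values (ties counted half)
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  ustat <- function(av, bv)
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- ustat(a, b)
  us <- apply(utils::combn(n, na), 2, function(ii)
    ustat(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# sums of squares in a balanced two-factor design by mean projections
oracle_balanced_ss <- function(value, f1, f2) {
  g <- mean(value)
  m1 <- tapply(value, f1, mean)[f1]
  m2 <- tapply(value, f2, mean)[f2]
  m12 <- tapply(value, interaction(f1, f2), mean)[interaction(f1, f2)]
  c(ss1 = sum((m1 - g)^2), ss2 = sum((m2 - g)^2),
    ss12 = sum((m12 - m1 - m2 + g)^2))
}

# fit a cosinor to the hourly means of a per-window metric of one subject
fit_hourly_metric <- function(s, metric_fun) {
  wp <- select_hourly_windows(s)
  wp <- wp[!wp$missing, ]
  v <- vapply(seq_len(nrow(wp)), function(i)
    metric_fun(window_rr(s, wp$start_s[i], wp$end_s[i])), numeric(1))
  cosinor_fit(v, (wp$start_s + wp$end_s) / 2 / 3600)
}

# cohort spec for the age contrast: smaller amplitude, earlier peak in "old"
age_contrast_groups <- function() {
  dplyr::mutate(
    tibble::tribble(
      ~sex,   ~age_group, ~rr_circ_amplitude_mean, ~rr_acrophase_mean,
      "male", "young",    60,                      3,
      "male", "old",      40,                      22),
    rr_mesor_mean = 900, rr_mesor_sd = 40,
    rr_circ_amplitude_sd = 10, rr_acrophase_sd = 1)
}

# cohort spec for the sex contrast: later variability-modulation peak in
# females (sympathetic proxy read out through hourly SD2)
sex_contrast_groups <- function() {
  dplyr::mutate(
    tibble::tribble(
      ~sex,     ~age_group, ~band_acrophase_mean,
      "female", "young",    18,
      "male",   "young",    15),
    rr_mesor_mean = 900, rr_mesor_sd = 40,
    band_acrophase_sd = 1, band_circ_gain_mean = 0.4)
}

# signed circular difference a - b in (-12, 12] hours
circ_diff_h <- function(a, b) ((a - b + 12) %% 24) - 12
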