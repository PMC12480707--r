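make_series <- function(rr, ...) rr_series(rr = rr, validate = FALSE, ...)

test_that("artifact detection flags only genuine deviations", {
  expect_equal(sum(detect_artifacts(make_series(rep(1000, 50)))), 0)
  rr <- rep(1000, 50); rr[25] <- 2000
  fl <- detect_artifacts(make_series(rr), threshold = 0.20)
  expect_equal(which(fl), 25)
  # alternating 800/850: ~6% deviation from the local median, below 20%
  alt <- rep(c(800, 850), 25)
  expect_equal(sum(detect_artifacts(make_series(alt), 0.20)), 0)
  expect_error(detect_artifacts(make_series(rep(1000, 5))), "short")
  expect_error(detect_artifacts(make_series(rep(1000, 50)), threshold = 1.2),
               "threshold")
})

test_that("beat correction interpolates flagged beats and preserves count", {
  s <- make_series(rep(1000, 20))
  out <- correct_beats(s, rep(FALSE, 20))
  expect_identical(out$series$rr, s$rr)
  expect_equal(out$report$n_corrected, 0)
  # single flagged beat amid constant data -> exactly the constant
  fl <- rep(FALSE, 20); fl[10] <- TRUE
  s2 <- make_series(c(rep(1000, 9), 2000, rep(1000, 10)))
  out2 <- correct_beats(s2, fl)
  expect_equal(out2$series$rr[10], 1000)
  expect_equal(out2$series$flag[10], "corrected")
  expect_equal(nrow(out2$series), 20)
  # flagged beat on a linear ramp -> the line's value
  ramp <- seq(900, 1100, by = 10)
  rrr <- ramp; rrr[11] <- 1500
  fl3 <- seq_along(rrr) == 11
  out3 <- correct_beats(make_series(rrr), fl3)
  expect_equal(out3$series$rr[11], 1000, tolerance = 1e-6)
  expect_error(correct_beats(s, rep(TRUE, 20)), "50%")
})

test_that("boundary runs are linearly extrapolated and reported", {
  rr <- c(3000, seq(1000, 1100, by = 10))
  fl <- c(TRUE, rep(FALSE, 11))
  out <- correct_beats(make_series(rr), fl)
  expect_true(out$report$boundary_extrapolated)
  expect_equal(out$series$rr[1], 990, tolerance = 1)
})

test_that("the rejection rule is a strict 5% inequality", {
  rep_at <- function(f) tibble::tibble(corrected_fraction = f)
  expect_true(apply_rejection_rule(rep_at(0.051)))
  expect_false(apply_rejection_rule(rep_at(0.05)))
  expect_false(apply_rejection_rule(rep_at(0.02)))
})

test_that("smoothness-priors detrending kills affine trends and is linear", {
  expect_equal(detrend_smoothness_priors(rep(7, 100)), rep(0, 100),
               tolerance = 1e-9)
  ramp <- seq(0, 500, length.out = 400)
  expect_lt(max(abs(detrend_smoothness_priors(ramp))), 1e-6 * 500)
  set.seed(1)
  x <- rnorm(200); y <- rnorm(200)
  lhs <- detrend_smoothness_priors(2 * x + 3 * y)
  rhs <- 2 * detrend_smoothness_priors(x) + 3 * detrend_smoothness_priors(y)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_error(detrend_smoothness_priors(x, lambda = -1), "non-negative")
})

test_that("the detrender passes a 0.25 Hz oscillation nearly untouched", {
  z <- sin(2 * pi * 0.25 * (0:1199) / 4)   # 0.25 Hz at 4 Hz sampling
  d <- detrend_smoothness_priors(z, 500)
  atten <- 1 - max(abs(d[200:1000]))
  expect_lt(abs(atten), 0.05)
})

test_that("hourly window selection follows the tie-break and skips artifacts", {
  # constant clean recording: all scores tie -> earliest start each hour
  s <- rr_series(rr = rep(1000, 86500), validate = FALSE)
  wp <- select_hourly_windows(s)
  expect_equal(nrow(wp), 24)
  expect_false(any(wp$missing))
  expect_equal(wp$start_s, (0:23) * 3600)
  expect_equal(wp$end_s - wp$start_s, rep(300, 24))
  # artifact burst in minutes 0-30 of hour 2 -> window in minutes 30-60
  flags <- rep(FALSE, nrow(s))
  burst <- s$t >= 2 * 3600 & s$t < 2 * 3600 + 1800
  flags[burst] <- TRUE
  wp2 <- select_hourly_windows(s, flags)
  expect_gte(wp2$start_s[3], 2 * 3600 + 1800)
  expect_true(wp2$clean[3])
})

test_that("a 23-hour recording yields 23 windows and one missing hour", {
  s <- rr_series(rr = rep(1000, 23 * 3600), validate = FALSE)
  wp <- select_hourly_windows(s)
  expect_equal(sum(wp$missing), 1)
  expect_equal(sum(!wp$missing), 23)
})

test_that("detection and correction recover the artifact-free twin", {
  sp <- synth_subject_spec(ectopic_rate = 0.02, duration = 6, seed = 31L)
  s <- generate_rr(sp, require_full_day = FALSE)
  twin <- generate_rr({sp$ectopic_rate <- 0; sp}, require_full_day = FALSE)
  truth <- s$flag == "artifact"
  fl <- detect_artifacts(s)
  expect_gte(sum(fl & truth) / sum(truth), 0.90)
  out <- correct_beats(s, fl)
  r1 <- time_domain(window_rr(out$series, 0, 3600))$rmssd
  r0 <- time_domain(window_rr(twin, 0, 3600))$rmssd
  expect_lt(abs(r1 - r0) / r0, 0.10)
  expect_equal(nrow(out$series), nrow(s))
})
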