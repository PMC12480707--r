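test_that("a spec with no amplitudes and no noise yields a constant series", {
  sp <- synth_subject_spec(rr_mesor = 1000, rr_circ_amplitude = 0,
                           hf_amp = 0, lf_amp = 0, noise_sd = 0,
                           ectopic_rate = 0, duration = 1, seed = 1L)
  s <- generate_rr(sp, require_full_day = FALSE)
  expect_true(all(s$rr == 1000))
  expect_equal(diff(s$t), rep(1, nrow(s) - 1))
})

test_that("generation is deterministic given the seed", {
  sp <- synth_subject_spec(duration = 2, seed = 99L)
  s1 <- generate_rr(sp, require_full_day = FALSE)
  s2 <- generate_rr(sp, require_full_day = FALSE)
  expect_identical(s1$rr, s2$rr)
  expect_identical(s1$flag, s2$flag)
})

test_that("generated series satisfy the RR-series invariants", {
  for (seed in c(3L, 4L)) {
    s <- generate_rr(synth_subject_spec(duration = 3, ectopic_rate = 0.05,
                                        seed = seed),
                     require_full_day = FALSE)
    expect_true(all(s$rr > 0))
    expect_true(all(diff(s$t) > 0))
    expect_equal(diff(s$t), s$rr[-1] / 1000, tolerance = 1e-9)
  }
})

test_that("short recordings are refused when a full day is required", {
  sp <- synth_subject_spec(duration = 12, seed = 1L)
  expect_error(generate_rr(sp), "full day")
})

test_that("the spectrum of a noise-free series concentrates at the two tones", {
  sp <- synth_subject_spec(noise_sd = 0, ectopic_rate = 0,
                           band_circ_gain = 0, duration = 1, seed = 1L,
                           hf_freq = 0.25, lf_freq = 0.10)
  s <- generate_rr(sp, require_full_day = FALSE)
  rr <- window_rr(s, 0, 600)
  tt <- s$t[s$t < 600]
  samp <- interpolate_rr(rr, tt)
  psd <- estimate_psd(samp$rr)
  inband <- psd$freq >= 0.04 & psd$freq <= 0.5
  near <- inband & (abs(psd$freq - 0.25) <= 0.02 | abs(psd$freq - 0.10) <= 0.02)
  conc <- sum(psd$psd[near]) / sum(psd$psd[inband])
  expect_gte(conc, 0.90)
})

test_that("ectopic injection hits the requested rate", {
  rate <- 0.02
  s <- generate_rr(synth_subject_spec(ectopic_rate = rate, seed = 21L))
  n <- nrow(s)
  obs <- sum(s$flag == "artifact")
  # beats are flagged in pairs: the pair count is Binomial(n, rate/2)
  ci <- 2 * qbinom(c(0.005, 0.995), n, rate / 2)
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
  expect_lt(abs(obs / n - rate) / rate, 0.15)
})

test_that("cohort generation counts subjects and is reproducible on disk", {
  grp <- dplyr::filter(default_cohort_groups(), age_group == "young")
  cs <- synth_cohort_spec(n_per_group = 5, groups = grp, duration = 1,
                          seed = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  coh1 <- generate_cohort(cs, out_dir = d1)
  coh2 <- generate_cohort(cs, out_dir = d2)
  expect_length(coh1$series, 10)
  expect_equal(nrow(coh1$manifest), 10)
  expect_equal(length(list.files(d1, pattern = "csv$")), 12)  # 10 + 2 tables
  expect_identical(readBin(file.path(d1, "ground_truth.csv"), "raw", 1e6),
                   readBin(file.path(d2, "ground_truth.csv"), "raw", 1e6))
})

test_that("invalid subject specs are rejected", {
  expect_error(synth_subject_spec(rr_mesor = 100), "non-positive RR")
  expect_error(synth_subject_spec(ectopic_rate = 0.7), "ectopic_rate")
  expect_error(synth_subject_spec(hf_freq = 0.1), "hf_freq")
})
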