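test_that("hourly aggregation pivots metrics and rejects duplicates", {
  w <- tibble::tibble(subject_id = "s1", hour = 0:23,
                      sdnn = rnorm(24, 35, 5), rmssd = rnorm(24, 30, 5))
  hm <- hourly_aggregate(w)
  expect_equal(nrow(hm), 48)
  expect_setequal(unique(hm$metric), c("sdnn", "rmssd"))
  expect_error(hourly_aggregate(w[c(1, 1, 2), ]), "duplicate")
  # missing hours simply do not appear
  hm2 <- hourly_aggregate(w[-14, ])
  expect_false(13 %in% hm2$hour[hm2$metric == "sdnn"])
})

test_that("the noiseless cosinor is recovered to machine precision", {
  h <- 0:23
  y <- 10 + 3 * cos(2 * pi * (h - 18) / 24)
  f <- cosinor_fit(y, h)
  expect_equal(f$mesor, 10, tolerance = 1e-9)
  expect_equal(f$amplitude, 3, tolerance = 1e-9)
  expect_equal(f$acro_clock_h, 18, tolerance = 1e-9)
  # fitted value at the acrophase equals M + A
  fitted_peak <- f$mesor + f$amplitude *
    cos(2 * pi * f$acro_clock_h / 24 + f$phi_rad)
  expect_equal(fitted_peak, f$mesor + f$amplitude, tolerance = 1e-9)
  expect_true(f$phi_rad <= 0 && f$phi_rad > -2 * pi)
})

test_that("a constant profile has zero amplitude and p near 1", {
  f <- cosinor_fit(rep(5, 24), 0:23)
  expect_equal(f$mesor, 5, tolerance = 1e-9)
  expect_lt(f$amplitude, 1e-9)
  expect_gt(f$p_zero_amp, 0.99)
  expect_error(cosinor_fit(c(1, 2, 3), c(0, 8, 16)), "at least 4")
})

test_that("cosinor coefficients equal an independent three-column OLS solve", {
  set.seed(21)
  for (k in 1:20) {
    h <- 0:23
    y <- rnorm(24, 50, 10) + 8 * cos(2 * pi * (h - runif(1, 0, 24)) / 24)
    f <- cosinor_fit(y, h)
    X <- cbind(1, cos(2 * pi * h / 24), sin(2 * pi * h / 24))
    beta <- qr.solve(X, y)
    expect_equal(c(f$mesor, f$beta, f$gamma), unname(beta), tolerance = 1e-10)
  }
})

test_that("cosinor fits are equivariant under time shifts and offsets", {
  set.seed(22)
  h <- 0:23
  y <- 40 + 6 * cos(2 * pi * (h - 7) / 24) + rnorm(24, 0, 2)
  f0 <- cosinor_fit(y, h)
  for (shift in c(3, -5.5)) {
    f1 <- cosinor_fit(y, (h + shift) %% 24)
    expect_equal(f1$mesor, f0$mesor, tolerance = 1e-9)
    expect_equal(f1$amplitude, f0$amplitude, tolerance = 1e-9)
    expect_equal(f1$acro_clock_h, (f0$acro_clock_h + shift) %% 24,
                 tolerance = 1e-9)
  }
  f2 <- cosinor_fit(y + 100, h)
  expect_equal(f2$mesor, f0$mesor + 100, tolerance = 1e-9)
  expect_equal(f2$amplitude, f0$amplitude, tolerance = 1e-9)
})

test_that("acrophase angles convert to clock hours with wrapping", {
  expect_equal(acrophase_to_clock(0), 0)
  expect_equal(acrophase_to_clock(-3 * pi / 2), 18)
  expect_equal(acrophase_to_clock(pi / 4), 21)
  expect_equal(format_clock(acrophase_to_clock(pi / 4)), "21:00")
})

test_that("tidy and glance expose the fit in broom shape", {
  f <- cosinor_fit(10 + 3 * cos(2 * pi * ((0:23) - 6) / 24) + rnorm(24), 0:23)
  td <- tidy(f)
  expect_setequal(td$term, c("mesor", "amplitude", "phi_rad"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(f)
  expect_equal(gl$n, 24)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("uniform data are not called rhythmic; strong 24-h cosines are", {
  # identical hourly means
  flat <- tidyr::expand_grid(subject_id = paste0("s", 1:6), hour = 0:23)
  flat$value <- 5
  u0 <- uniformity_test(flat)
  expect_gte(u0$uniform_p, 0.99)
  expect_false(u0$rhythmic)
  # 24-h cosine + noise across 10 subjects, several seeds
  hits <- sapply(1:5, function(seed) {
    set.seed(seed)
    d <- tidyr::expand_grid(subject_id = paste0("s", 1:10), hour = 0:23)
    d$value <- 30 + 8 * cos(2 * pi * (d$hour - 5) / 24) + rnorm(nrow(d), 0, 2)
    u <- uniformity_test(d)
    u$uniform_p < 0.01 && u$dominant_period_h == 24
  })
  expect_true(all(hits))
  # pure 12-h cosine: dominant period 12, not 24-h rhythmic
  d12 <- tidyr::expand_grid(subject_id = paste0("s", 1:8), hour = 0:23)
  set.seed(30)
  d12$value <- 20 + 5 * cos(2 * pi * d12$hour / 12) + rnorm(nrow(d12), 0, 0.5)
  u12 <- uniformity_test(d12)
  expect_equal(u12$dominant_period_h, 12)
  expect_false(u12$rhythmic)
})

test_that("fit_cohort fits every registered metric and tolerates gaps", {
  set.seed(23)
  reg <- metric_registry()$metric
  w <- tidyr::expand_grid(subject_id = paste0("s", 1:5), hour = 0:23)
  for (m in reg) w[[m]] <- 10 + 3 * cos(2 * pi * (w$hour - 3) / 24) +
    rnorm(nrow(w), 0, 1)
  hm <- hourly_aggregate(w)
  # one subject with almost no valid hours for one metric
  hm$value[hm$subject_id == "s5" & hm$metric == "sdnn" & hm$hour > 2] <- NA
  fc <- fit_cohort(hm)
  expect_equal(nrow(fc$decisions), length(reg))
  expect_equal(sort(unique(fc$fits$metric)), sort(reg))
  gap <- fc$fits[fc$fits$subject_id == "s5" & fc$fits$metric == "sdnn", ]
  expect_true(is.na(gap$mesor))
  full <- fc$fits[!(fc$fits$subject_id == "s5" & fc$fits$metric == "sdnn"), ]
  expect_true(all(is.finite(full$mesor)))
})
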