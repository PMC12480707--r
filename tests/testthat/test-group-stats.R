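test_that("identical groups give a null comparison", {
  set.seed(31)
  v <- rnorm(12, 10, 2)
  r <- compare_groups(v, v, "mesor")
  expect_equal(r$delta, 0)
  expect_gte(r$p, 0.99)
})

test_that("fully separated small samples match the enumeration example", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6), "mesor")
  expect_equal(r$test, "mann_whitney_exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$delta, -1)
})

test_that("small-sample Mann-Whitney p equals the enumeration oracle", {
  set.seed(32)
  for (k in 1:12) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- sample(1:8, na, replace = TRUE)   # ties likely
    b <- sample(1:8, nb, replace = TRUE)
    mine <- circhrv:::.mw_exact(a, b)
    expect_equal(mine$p, oracle_mw_exact(a, b), tolerance = 1e-12)
  }
})

test_that("Cliff's delta is antisymmetric and bounded", {
  set.seed(33)
  for (k in 1:10) {
    a <- rnorm(7); b <- rnorm(9)
    d <- cliffs_delta(a, b)
    expect_equal(d, -cliffs_delta(b, a), tolerance = 1e-12)
    expect_lte(abs(d), 1)
  }
})

test_that("acrophase comparisons use circular means across midnight", {
  a <- c(23.5, 0.5)    # circular mean 00:00, linear mean 12:00
  b <- c(11.5, 12.5)   # circular mean 12:00
  expect_equal(circular_mean_hours(a), 0, tolerance = 1e-9)
  expect_equal(circular_mean_hours(b), 12, tolerance = 1e-9)
  r <- compare_groups(c(23.5, 0.5, 23.8), c(11.5, 12.5, 11.8), "acrophase")
  expect_equal(r$test, "watson_williams")
  expect_equal(abs(r$circular_mean_diff_h), 12, tolerance = 0.3)
  expect_lt(r$p, 0.05)
})

test_that("multiplicity adjustment reproduces BH and Bonferroni arithmetic", {
  bh <- adjust_multiplicity(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(bh$reject))
  none <- adjust_multiplicity(rep(1, 5))
  expect_false(any(none$reject))
  bf <- adjust_multiplicity(rep(0.001, 20), method = "bonferroni")
  expect_equal(bf$p_adjusted, rep(0.02, 20))
  withd <- adjust_multiplicity(c(0.01, 0.5), deltas = c(0.8, 0.1))
  expect_equal(withd$delta, c(0.8, 0.1))
})

test_that("logistic CIs cover the null when the outcome is independent", {
  set.seed(34)
  cover <- sapply(1:50, function(k) {
    d <- tibble::tibble(age = runif(200, 20, 70),
                        sex = sample(c("female", "male"), 200, TRUE),
                        bmi = rnorm(200, 25, 3),
                        rhythmic = runif(200) < 0.5)
    fit <- rhythmicity_logistic(d)
    fit <- fit[fit$term != "(Intercept)", ]
    setNames(fit$conf.low <= 1 & 1 <= fit$conf.high, fit$term)
  })
  # per-covariate coverage of the null odds ratio
  expect_true(all(rowMeans(cover) >= 0.90))
})

test_that("a deterministic age threshold raises a separation error", {
  d <- tibble::tibble(age = c(runif(100, 20, 49), runif(100, 51, 80)),
                      sex = sample(c("female", "male"), 200, TRUE),
                      bmi = rnorm(200, 25, 3))
  d$rhythmic <- d$age > 50
  expect_error(rhythmicity_logistic(d), "separation")
})

test_that("a known age odds ratio is recovered", {
  set.seed(35)
  ok <- sapply(1:30, function(k) {
    age <- runif(500, 20, 70)
    lp <- log(2) * (age - 45) / 10        # OR 2 per decade
    d <- tibble::tibble(age = age,
                        sex = sample(c("female", "male"), 500, TRUE),
                        bmi = rnorm(500, 25, 3),
                        rhythmic = runif(500) < plogis(lp))
    fit <- rhythmicity_logistic(d)
    or_dec <- fit$odds_ratio[fit$term == "age"]^10
    or_dec > 1.6 && or_dec < 2.5
  })
  expect_gte(mean(ok), 0.90)
})

test_that("type-II ANOVA matches the projection oracle on balanced data", {
  set.seed(36)
  d <- tidyr::expand_grid(sex = c("female", "male"),
                          age_group = c("young", "old"), rep = 1:10)
  d$value <- rnorm(nrow(d), 20, 4)
  tab <- interaction_anova(d)
  o <- oracle_balanced_ss(d$value, d$sex, d$age_group)
  expect_equal(tab$sumsq[tab$term == "sex"], unname(o["ss1"]),
               tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "age_group"], unname(o["ss2"]),
               tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "sex:age_group"], unname(o["ss12"]),
               tolerance = 1e-9)
})

test_that("empty design cells are reported by name", {
  d <- tidyr::expand_grid(sex = c("female", "male"),
                          age_group = c("young", "old"), rep = 1:3)
  d$value <- rnorm(nrow(d))
  d <- d[!(d$sex == "male" & d$age_group == "old"), ]
  expect_error(interaction_anova(d), "male")
})

test_that("a crossover interaction is detected with high power", {
  set.seed(37)
  hits <- sapply(1:25, function(k) {
    d <- tidyr::expand_grid(sex = c("female", "male"),
                            age_group = c("young", "old"), rep = 1:25)
    delta <- 2          # 2 sigma crossover
    cell <- ifelse(xor(d$sex == "female", d$age_group == "old"), delta, -delta)
    d$value <- rnorm(nrow(d), cell, 1)
    tab <- interaction_anova(d)
    tab$p[tab$term == "sex:age_group"] < 0.01
  })
  expect_gte(mean(hits), 0.95)
})
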