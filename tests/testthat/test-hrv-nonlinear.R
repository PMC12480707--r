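test_that("Poincare descriptors satisfy their defining identities", {
  expect_equal(unlist(poincare(rep(1000, 10))[, c("sd1", "sd2")]),
               c(sd1 = 0, sd2 = 0))
  alt <- c(rep(c(800, 850), 50), 800)  # 100 balanced +-50 differences
  expect_equal(poincare(alt)$sd1, 50 / sqrt(2), tolerance = 1e-9)
  set.seed(2)
  for (k in 1:10) {
    rr <- rnorm(100, 1000, sample(5:80, 1))
    p <- poincare(rr)
    pv <- mean((rr - mean(rr))^2)
    expect_equal(p$sd1^2 + p$sd2^2, 2 * pv, tolerance = 1e-9)
    expect_equal(p$sd1^2, mean((diff(rr) - mean(diff(rr)))^2) / 2,
                 tolerance = 1e-9)
  }
  expect_error(poincare(c(1, 2)), "at least 3")
})

test_that("DFA matches a literal per-box lm reference implementation", {
  set.seed(11)
  x <- rnorm(500, 1000, 30)
  mine <- dfa(x)
  expect_equal(mine$alf1, oracle_dfa(x, 4, 16), tolerance = 1e-10)
  expect_equal(mine$alf2, oracle_dfa(x, 16, 64), tolerance = 1e-10)
})

test_that("DFA exponents are shift-invariant and trend-sensitive", {
  set.seed(12)
  x <- rnorm(1000, 0, 1)
  a <- dfa(x); b <- dfa(x + 500)
  expect_equal(a$alf1, b$alf1, tolerance = 1e-9)
  expect_equal(a$alf2, b$alf2, tolerance = 1e-9)
  trended <- dfa(x + 0.05 * seq_along(x))
  expect_gte(trended$alf2, 1.4)
  expect_error(dfa(rep(5, 300)), "degenerate")
  expect_error(dfa(rnorm(100)), "at least 200")
})

test_that("entropies equal the brute-force template-counting oracle", {
  set.seed(13)
  for (k in 1:3) {
    x <- rnorm(150, 1000, 25)
    r <- 0.2 * sd(x)
    o <- oracle_entropies(x, 2, r)
    e <- entropies(x, 2, 0.2)
    expect_equal(e$apen, o$apen, tolerance = 1e-12)
    expect_equal(e$sampen, o$sampen, tolerance = 1e-12)
  }
})

test_that("entropy edge cases behave as theory dictates", {
  # strictly periodic series: every template matches -> sampen 0
  p <- rep(c(900, 950, 1000), 50)
  expect_equal(entropies(p)$sampen, 0, tolerance = 1e-12)
  # all mass in one histogram bin vs uniform over k bins
  expect_equal(entropies(900 + runif(120, 0, 40))$shanen, 0)
  k <- 4
  vals <- rep(c(900, 950, 1000, 1050) + 10, each = 30)
  expect_equal(entropies(vals)$shanen, log2(k), tolerance = 1e-12)
  expect_error(entropies(rep(1000, 120)), "zero-variance")
  expect_error(entropies(rnorm(50)), "at least 100")
})

test_that("ApEn/SampEn are invariant to affine rescaling with SD-scaled r", {
  set.seed(14)
  x <- rnorm(200, 1000, 30)
  a <- entropies(x); b <- entropies(5 * x + 200)
  expect_equal(a$apen, b$apen, tolerance = 1e-9)
  expect_equal(a$sampen, b$sampen, tolerance = 1e-9)
})

test_that("correlation sums match a double-loop oracle and a sinusoid has dimension ~1", {
  x <- 100 * sin(2 * pi * (1:300) / 40) + 900
  emb <- circhrv:::.embed_delay(x, 5, 1)
  rgrid <- exp(seq(log(5), log(400), length.out = 10))
  expect_equal(as.numeric(circhrv:::corr_sums_cpp(emb, rgrid)),
               oracle_corr_sums(emb, rgrid), tolerance = 1e-12)
  y <- 100 * sin(2 * pi * (1:600) / 40) + 900
  cd <- correlation_dimension(y)
  expect_gte(cd, 0.9); expect_lte(cd, 1.2)
  expect_error(correlation_dimension(rep(1000, 600)), "degenerate")
  expect_error(correlation_dimension(rnorm(100)), "at least 500")
})

test_that("recurrence quantification separates periodic from shuffled data", {
  set.seed(15)
  p <- rep(c(900, 950, 1000, 950), 100) + rnorm(400, 0, 1)
  r1 <- rqa(p)
  expect_gte(r1$det, 95)
  # constant series with positive threshold recurs everywhere
  expect_equal(rqa(rep(1000, 100), r = 1)$rec, 100)
  det_shuffled <- median(replicate(21, rqa(sample(p))$det))
  expect_lt(det_shuffled, r1$det)
  expect_error(rqa(rnorm(30)), "short")
  expect_error(rqa(p, r = 0), "positive")
})

test_that("recurrence rate is monotone non-decreasing in the threshold", {
  set.seed(16)
  x <- rnorm(120, 1000, 30)
  rs <- seq(20, 200, by = 30)
  recs <- vapply(rs, function(r) rqa(x, r = r)$rec, numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("nonlinear_metrics degrades gracefully on short windows", {
  set.seed(17)
  x <- rnorm(300, 1000, 30)
  nm <- nonlinear_metrics(x)
  expect_true(is.na(nm$corrdim))       # < 500 beats
  expect_true(is.finite(nm$sampen) && is.finite(nm$alf1) && is.finite(nm$rec))
})
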