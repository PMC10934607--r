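rr_tachogram <- function(rr) tachogram(rr, times = cumsum(rr) / 1000)

test_that("artifact correction flags and repairs outlying intervals", {
  rr <- rep(800, 40)
  clean <- correct_artifacts(rr_tachogram(rr))
  expect_identical(attr(clean, "n_corrected"), 0L)
  expect_equal(clean$intervals, rr)

  rr2 <- rr
  rr2[20] <- 1600
  fixed <- correct_artifacts(rr_tachogram(rr2))
  expect_identical(attr(fixed, "n_corrected"), 1L)
  expect_lt(abs(fixed$intervals[20] - 800) / 800, 0.10)
  expect_error(correct_artifacts(rr_tachogram(rep(800, 5))), "11")
})

test_that("time-domain indices follow their defining formulas", {
  td <- time_domain(rr_tachogram(c(1000, 1000, 1000)))
  expect_equal(td$mean_rr, 1000)
  expect_equal(td$sdnn, 0)
  expect_equal(td$mean_hr, 60)
  expect_equal(td$rmssd, 0)
  expect_identical(td$nn50, 0L)

  td2 <- time_domain(rr_tachogram(c(800, 860, 800)))
  expect_identical(td2$nn50, 2L)
  expect_equal(td2$pnn50, 100)
  expect_equal(td2$rmssd, 60)
  expect_error(time_domain(rr_tachogram(900)), "2 intervals")
})

test_that("time-domain indices equal a naive transcription on random data", {
  set.seed(40)
  rr <- rnorm(200, 850, 40)
  got <- time_domain(rr_tachogram(rr))
  hr <- 60000 / rr
  hr_s <- stats::filter(hr, rep(0.2, 5), sides = 2)
  hr_s <- hr_s[!is.na(hr_s)]
  expect_equal(got$mean_rr, sum(rr) / 200, tolerance = 1e-9)
  expect_equal(got$sdnn, sqrt(sum((rr - mean(rr))^2) / 199),
               tolerance = 1e-9)
  expect_equal(got$min_hr, min(hr_s), tolerance = 1e-9)
  expect_equal(got$max_hr, max(hr_s), tolerance = 1e-9)
  expect_equal(got$rmssd, sqrt(mean(diff(rr)^2)), tolerance = 1e-9)
  expect_equal(got$pnn50, mean(abs(diff(rr)) > 50) * 100, tolerance = 1e-9)
})

test_that("spectral power lands in the band of the RR modulation", {
  make_mod <- function(f_mod) {
    t <- 0; rr <- c()
    while (t < 310) {
      r <- 1000 + 30 * sin(2 * pi * f_mod * t)
      rr <- c(rr, r); t <- t + r / 1000
    }
    rr_tachogram(rr)
  }
  lf_mod <- frequency_domain(make_mod(0.10))
  expect_gte(lf_mod$lf_abs / (lf_mod$lf_abs + lf_mod$hf_abs), 0.90)
  expect_gte(lf_mod$lf_nu, 90)
  hf_mod <- frequency_domain(make_mod(0.25))
  expect_gte(hf_mod$hf_nu, 90)
  # normalized units always partition 100
  expect_equal(lf_mod$lf_nu + lf_mod$hf_nu, 100, tolerance = 1e-6)
  expect_equal(hf_mod$lf_nu + hf_mod$hf_nu, 100, tolerance = 1e-6)
  expect_gte(lf_mod$total_power, lf_mod$lf_abs + lf_mod$hf_abs)
  expect_error(frequency_domain(rr_tachogram(rep(800, 20))), "120 s")
})

test_that("Poincare descriptors match direct computation", {
  rr <- rep(c(800, 900), 30)
  pc <- poincare(rr_tachogram(rr))
  expect_equal(pc$sd1, sqrt(mean(diff(rr)^2) / 2), tolerance = 1e-12)
  expect_equal(pc$sd2, sqrt(max(0, 2 * sd(rr)^2 - pc$sd1^2)),
               tolerance = 1e-12)

  const <- poincare(rr_tachogram(rep(700, 20)))
  expect_equal(const$sd1, 0)
  expect_true(is.na(const$sd2_sd1))

  # sd1-rmssd identity for arbitrary tachograms
  set.seed(3)
  for (i in 1:5) {
    rr_i <- rnorm(50, 900, 60)
    tac <- rr_tachogram(rr_i)
    expect_equal(poincare(tac)$sd1,
                 time_domain(tac)$rmssd / sqrt(2), tolerance = 1e-6)
  }
})

test_that("entropies equal the naive O(n^2) oracle", {
  set.seed(77)
  rr <- rnorm(200, 850, 30)
  got <- hrv_entropy(rr_tachogram(rr))
  want <- entropy_naive(rr, m = 2, r = 0.2 * sd(rr))
  expect_equal(got$apen, want$apen, tolerance = 1e-9)
  expect_equal(got$sampen, want$sampen, tolerance = 1e-9)
})

test_that("regular series are less entropic than their shuffled copies", {
  rr <- rep(c(800, 900), 40)
  tac <- rr_tachogram(rr)
  e_reg <- hrv_entropy(tac)
  shuffled <- with(list(), { set.seed(5); sample(rr) })
  e_shuf <- hrv_entropy(rr_tachogram(shuffled))
  expect_lt(e_reg$sampen, e_shuf$sampen)

  e_const <- hrv_entropy(rr_tachogram(rep(800, 60)))
  expect_equal(e_const$apen, 0)
})

test_that("DFA exponents recover white and integrated noise scaling", {
  set.seed(2024)
  white <- rnorm(1000, 900, 40)
  a_w <- dfa(rr_tachogram(white))
  expect_true(a_w$dfa_a1 >= 0.4 && a_w$dfa_a1 <= 0.6)

  brown <- 900 + cumsum(rnorm(1000, 0, 10))
  brown <- brown - min(brown) + 500   # keep intervals positive
  a_b <- dfa(rr_tachogram(brown))
  expect_true(a_b$dfa_a1 >= 1.3 && a_b$dfa_a1 <= 1.7)

  short <- dfa(rr_tachogram(rnorm(150, 900, 40)))
  expect_false(is.na(short$dfa_a1))
  expect_true(is.na(short$dfa_a2))
})

test_that("fluctuation function is non-negative and grows with box size", {
  set.seed(10)
  rr <- rnorm(500, 850, 30)
  tac <- rr_tachogram(rr)
  profile <- cumsum(rr - mean(rr))
  fl <- vapply(c(4, 8, 16, 32, 64), function(s) {
    nb <- floor(length(rr) / s)
    ss <- 0
    for (b in seq_len(nb)) {
      seg <- profile[((b - 1) * s + 1):(b * s)]
      fit <- lm.fit(cbind(1, seq_len(s)), seg)
      ss <- ss + sum(fit$residuals^2)
    }
    sqrt(ss / (nb * s))
  }, numeric(1))
  expect_true(all(fl >= 0))
  expect_true(all(diff(fl) > 0))
})

test_that("the full report carries every index and respects preconditions", {
  set.seed(30)
  rr <- rnorm(400, 850, 40)
  rep_full <- hrv_report(rr_tachogram(rr))
  expect_s3_class(rep_full, "hrv_report")
  check_schema(unclass(rep_full), "hrv_report")
  expect_false(any(is.na(unlist(rep_full[c("mean_rr", "sdnn", "rmssd",
                                           "lf_abs", "hf_abs", "sd1",
                                           "apen", "dfa_a1")]))))
  # short series: spectral and DFA-long indices degrade to NA, no error
  rep_short <- hrv_report(rr_tachogram(rnorm(60, 850, 40)))
  expect_true(is.na(rep_short$lf_abs))
  expect_true(is.na(rep_short$dfa_a2))
})
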