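test_that("Savitzky-Golay baseline reproduces constants and cubics", {
  fs <- 500
  const <- uniform_signal(rep(3.7, 2000), fs)
  expect_equal(extract_respiratory(const)$samples, rep(3.7, 2000),
               tolerance = 1e-9)

  t <- seq(0, 4, by = 1 / fs)
  cubic <- uniform_signal(0.5 + 2 * t - 3 * t^2 + 0.25 * t^3, fs)
  sm <- extract_respiratory(cubic, polyorder = 3)
  interior <- 800:1200
  expect_equal(sm$samples[interior], cubic$samples[interior],
               tolerance = 1e-9)
})

test_that("Savitzky-Golay passes respiration and rejects heart sounds", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)
  slow <- uniform_signal(sin(2 * pi * 0.25 * t), fs)
  fast <- uniform_signal(sin(2 * pi * 50 * t), fs)
  interior <- (5 * fs):(15 * fs)
  expect_gte(max(abs(extract_respiratory(slow)$samples[interior])), 0.9)
  expect_lte(max(abs(extract_respiratory(fast)$samples[interior])), 0.1)
})

test_that("baseline subtraction is exact and validated", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  resp <- uniform_signal(sin(2 * pi * 0.3 * t), fs)
  raw <- uniform_signal(resp$samples, fs)
  expect_true(all(remove_baseline(raw, resp)$samples == 0))
  zero <- uniform_signal(rep(0, length(t)), fs)
  expect_identical(remove_baseline(raw, zero)$samples, raw$samples)
  short <- uniform_signal(resp$samples[1:50], fs)
  expect_error(remove_baseline(raw, short), "equal length")
  wrong_fs <- uniform_signal(resp$samples, fs * 2)
  expect_error(remove_baseline(raw, wrong_fs), "sampling rate")
})

test_that("cardiac component is recovered from a synthetic mixture", {
  cfg0 <- synth_config(duration = 30, noise_sd = 0, resp_baseline_amp = 0,
                       seed = 3)
  cardiac_true <- generate_fcg(cfg0)$signal
  keep <- 2000:28000
  # moderate respiration: the extracted baseline captures it almost fully
  cfg2 <- synth_config(duration = 30, noise_sd = 0, resp_baseline_amp = 2,
                       seed = 3)
  raw2 <- generate_fcg(cfg2)$signal
  est2 <- remove_baseline(raw2, extract_respiratory(raw2))
  expect_gt(cor(est2$samples[keep], cardiac_true$samples[keep]), 0.99)
  # respiration-dominated raw signal: the 1.5 s frame leaves ~0.5% of the
  # baseline, all of it below 1 Hz — gone after the heart-sound band-pass
  cfg5 <- synth_config(duration = 30, noise_sd = 0, seed = 3)
  raw5 <- generate_fcg(cfg5)$signal
  est5 <- remove_baseline(raw5, extract_respiratory(raw5))
  expect_gt(cor(est5$samples[keep], cardiac_true$samples[keep]), 0.98)
  expect_gt(cor(bandpass_heart_sounds(est5)$samples[keep],
                bandpass_heart_sounds(cardiac_true)$samples[keep]), 0.999)
})

test_that("heart-sound band-pass has unit mid-band gain and kills drift", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  mid <- uniform_signal(sin(2 * pi * 100 * t), fs)
  out <- bandpass_heart_sounds(mid)
  interior <- (2 * fs):(8 * fs)
  amp <- max(abs(out$samples[interior]))
  expect_true(amp >= 0.95 && amp <= 1.05)

  slow <- uniform_signal(sin(2 * pi * 1 * t), fs)
  out_slow <- bandpass_heart_sounds(slow)
  expect_lt(sqrt(mean(out_slow$samples[interior]^2)) /
              sqrt(mean(slow$samples[interior]^2)), 0.05)

  zero <- uniform_signal(rep(0, 1000), fs)
  expect_true(all(bandpass_heart_sounds(zero)$samples == 0))
  expect_error(bandpass_heart_sounds(mid, hi = 600), "fs/2")
})

test_that("filters are zero-lag and length-preserving", {
  fs <- 1000
  set.seed(7)
  # band-limited burst: the cross-correlation peak must sit at zero lag
  t <- seq(0, 4, by = 1 / fs)
  burst <- exp(-(t - 2)^2 / (2 * 0.05^2)) * sin(2 * pi * 80 * t)
  sig <- uniform_signal(burst, fs)
  out <- bandpass_heart_sounds(sig)
  expect_identical(length(out$samples), length(sig$samples))
  cc <- ccf(out$samples, sig$samples, lag.max = 20, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)

  ecg_out <- preprocess_ecg(sig)
  expect_identical(length(ecg_out$samples), length(sig$samples))
})

test_that("ECG conditioning suppresses powerline frequencies", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  mains <- uniform_signal(sin(2 * pi * 50 * t), fs)
  out <- preprocess_ecg(mains)
  interior <- (2 * fs):(8 * fs)
  expect_lt(sqrt(mean(out$samples[interior]^2)) /
              sqrt(mean(mains$samples[interior]^2)), 0.02)
  zero <- uniform_signal(rep(0, 1000), fs)
  expect_true(all(abs(preprocess_ecg(zero)$samples) < 1e-12))
})

test_that("ECG conditioning shifts clean R-peaks by less than 2 ms", {
  rec <- clean_recording()
  cond <- preprocess_ecg(rec$ecg)
  tt <- signal_times(rec$ecg)
  for (rk in rec$truth$r_times[seq(1, length(rec$truth$r_times), by = 5)]) {
    win <- which(abs(tt - rk) <= 0.08)
    t_raw <- tt[win[which.max(rec$ecg$samples[win])]]
    t_cond <- tt[win[which.max(cond$samples[win])]]
    expect_lt(abs(t_cond - t_raw), 0.002)
  }
})
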