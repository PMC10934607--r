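test_that("template extraction records the wavelet peak and validates spans", {
  rec <- clean_recording()
  hs <- rec$hs
  k <- 10
  s1 <- rec$truth$s1_times[k]
  tpl <- extract_template(hs, s1 - 0.06, s1 + 0.06, "S1")
  # the wavelet's true envelope peak sits at the S1 centre time
  expect_lt(abs((s1 - 0.06) + tpl$peak_offset / hs$fs - s1), 2 / hs$fs)

  expect_error(extract_template(hs, 5, 5, "S1"), "start_s < end_s")
  expect_error(extract_template(hs, 5, 4, "S1"), "start_s < end_s")
  const <- uniform_signal(rep(2, 1000), 1000)
  expect_error(extract_template(const, 0.1, 0.3, "S1"), "all samples equal")
})

test_that("NCC is exactly 1 at self-similar and affine-related windows", {
  set.seed(21)
  base <- rnorm(50)
  x <- c(base, base)  # the template recurs at offset 51
  tpl <- hs_template(base, fs = 100, label = "S1")
  tr <- ncc(uniform_signal(x, 100), tpl, flat_tol = 0)
  raw_vals <- tr$values
  expect_equal(max(raw_vals), 1, tolerance = 1e-12)
  # affine invariance: a*x + b leaves the trace unchanged; negative a flips
  tr2 <- ncc(uniform_signal(3.5 * x + 11, 100), tpl, flat_tol = 0)
  expect_equal(tr2$values, raw_vals, tolerance = 1e-12)
  tr3 <- ncc(uniform_signal(-2 * x + 4, 100), tpl, flat_tol = 0)
  expect_equal(tr3$values, -raw_vals, tolerance = 1e-12)
})

test_that("production NCC equals the naive double-loop oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(12:80, 1)
    m <- sample(4:min(12, n - 1), 1)
    x <- rnorm(n)
    tpl_samples <- rnorm(m)
    tpl <- hs_template(tpl_samples, fs = 10, label = "S1")
    got <- ncc(uniform_signal(x, 10), tpl, flat_tol = 0)$values
    want <- ncc_naive(x, tpl_samples)
    expect_lt(max(abs(got - want)), 1e-9)
    expect_true(all(got >= -1 - 1e-9 & got <= 1 + 1e-9))
  }
})

test_that("zero-variance windows yield neutral similarity", {
  x <- c(rep(0, 30), 1, 2, 1, rep(0, 30))
  tpl <- hs_template(c(1, 2, 1), fs = 10, label = "S1")
  v <- ncc(uniform_signal(x, 10), tpl, flat_tol = 0)$values
  expect_true(all(v[1:20] == 0))
  expect_equal(max(v), 1, tolerance = 1e-12)
})

test_that("peak picking keeps the apex and suppresses near-by ties", {
  fs <- 100
  bump <- c(rep(0, 50), seq(0, 0.8, length.out = 21),
            seq(0.8, 0, length.out = 21)[-1], rep(0, 50))
  tr <- structure(list(values = bump, fs = fs, t0 = 0, label = "S1"),
                  class = "ncc_trace")
  ev <- find_events(tr, min_height = 0.5, min_distance_s = 0.3)
  expect_identical(length(ev), 1L)
  expect_equal(ev$times, (50 + 20) / fs, tolerance = 1e-12)

  two <- rep(0, 200)
  two[c(60, 70)] <- 0.9  # 0.1 s apart at fs 100
  tr2 <- structure(list(values = two, fs = fs, t0 = 0, label = "S1"),
                   class = "ncc_trace")
  ev2 <- find_events(tr2, min_height = 0.5, min_distance_s = 0.3)
  expect_identical(length(ev2), 1L)
  expect_equal(ev2$times, 59 / fs, tolerance = 1e-12)  # earlier peak wins
})

test_that("re-alignment lands events on the true fiducials for all labels", {
  # zero systolic-delay jitter isolates the alignment convention itself
  cfg <- synth_config(duration = 40, seed = 9, s2_delay_sd = 0,
                      noise_sd = 0)
  rec <- generate_fcg(cfg)
  hs <- bandpass_heart_sounds(remove_baseline(rec$signal,
                                              extract_respiratory(rec$signal)))
  for (lab in c("S1", "S2", "S1S2")) {
    tpl <- auto_select_template(hs, lab)
    ev <- detect_events(hs, tpl)
    truth_t <- if (lab == "S2") rec$truth$s2_times else rec$truth$s1_times
    expect_identical(length(ev), length(truth_t))
    err <- vapply(truth_t, function(s) min(abs(ev$times - s)), numeric(1))
    expect_lt(max(err), 0.005)
  }
})

test_that("full pipeline finds one event per beat within 5 ms (S1)", {
  rec <- clean_recording()
  tpl <- auto_select_template(rec$hs, "S1")
  ev <- detect_events(rec$hs, tpl)
  expect_identical(length(ev), length(rec$truth$s1_times))
  err <- vapply(rec$truth$s1_times, function(s) min(abs(ev$times - s)),
                numeric(1))
  expect_lt(max(err), 0.005)
})

test_that("automatic template selection encloses the true sounds", {
  rec <- clean_recording()
  hs <- rec$hs
  tpl1 <- auto_select_template(hs, "S1")
  expect_true(any(rec$truth$s1_times > tpl1$source_span[1] &
                    rec$truth$s1_times < tpl1$source_span[2]))
  tpl12 <- auto_select_template(hs, "S1S2")
  k <- which(rec$truth$s1_times > tpl12$source_span[1] &
               rec$truth$s1_times < tpl12$source_span[2])
  expect_identical(length(k), 1L)
  expect_true(rec$truth$s2_times[k] < tpl12$source_span[2])
  zero <- uniform_signal(rep(0, 8000), 1000)
  expect_error(auto_select_template(zero, "S1"), "burst")
})

test_that("NCC stays bounded on random property cases", {
  set.seed(77)
  for (i in 1:20) {
    x <- cumsum(rnorm(200))          # correlated signal
    tpl <- hs_template(rnorm(sample(5:30, 1)), fs = 10, label = "S2")
    v <- ncc(uniform_signal(x, 10), tpl)$values
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("fs mismatch and oversized templates are rejected", {
  sig <- uniform_signal(rnorm(100), 100)
  tpl <- hs_template(rnorm(10), fs = 200, label = "S1")
  expect_error(ncc(sig, tpl), "sampling rate")
  tpl2 <- hs_template(rnorm(200), fs = 100, label = "S1")
  expect_error(ncc(sig, tpl2), "longer than")
})
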