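test_that("a constant lag is self-calibrated and fully matched", {
  r <- event_series(seq(1, 30, by = 0.9), "R")
  d <- event_series(r$times + 0.1, "S1")
  m <- match_events(d, r, tol_s = 0.15)
  expect_identical(m$tp, length(r))
  expect_identical(m$fp, 0L)
  expect_identical(m$fn, 0L)
  expect_equal(m$expected_lag_s, 0.1, tolerance = 1e-12)
})

test_that("missing and spurious events are booked as FN and FP", {
  r <- event_series(seq(1, 20, by = 0.8), "R")
  n <- length(r)
  # drop one interior beat, add two spurious detections mid-diastole
  d_times <- sort(c(r$times[-8] + 0.05, 4.31, 12.71))
  m <- match_events(event_series(d_times, "S1"), r, tol_s = 0.15)
  expect_identical(m$tp, n - 1L)
  expect_identical(m$fn, 1L)
  expect_identical(m$fp, 2L)
  # conservation invariants
  expect_identical(m$tp + m$fn, n)
  expect_identical(m$tp + m$fp, length(d_times))
})

test_that("matching a series against itself is the identity", {
  x <- event_series(cumsum(runif(25, 0.7, 1.1)), "S1")
  m <- match_events(x, x, expected_lag_s = 0)
  expect_identical(m$tp, length(x))
  expect_identical(m$fp + m$fn, 0L)
  expect_error(match_events(x, event_series(numeric(0), "R")),
               "empty reference")
})

test_that("recognition statistics reproduce the published totals", {
  expect_equal(recognition_stats(list(tp = 1399, fp = 35, fn = 30)),
               c(sensitivity = 1399 / 1429 * 100, ppv = 1399 / 1434 * 100),
               tolerance = 1e-12)
  st <- recognition_stats(list(tp = 1399, fp = 35, fn = 30))
  expect_equal(round(st[["sensitivity"]], 1), 97.9)
  expect_equal(round(st[["ppv"]], 1), 97.6)
  st2 <- recognition_stats(list(tp = 1381, fp = 70, fn = 48))
  expect_equal(round(st2[["sensitivity"]], 1), 96.6)
  expect_equal(round(st2[["ppv"]], 1), 95.2)
  expect_equal(recognition_stats(list(tp = 10, fp = 0, fn = 0)),
               c(sensitivity = 100, ppv = 100))
  expect_error(recognition_stats(list(tp = 0, fp = 0, fn = 0)),
               "denominator")
})

test_that("inter-beat intervals are millisecond differences", {
  expect_equal(inter_beat_intervals(
    event_series(c(0, 1, 2), "S1"))$intervals, c(1000, 1000))
  tac <- inter_beat_intervals(event_series(c(0, 0.8, 1.7), "S1"))
  expect_equal(tac$intervals, c(800, 900))
  expect_equal(tac$times, c(0.8, 1.7))
  expect_error(inter_beat_intervals(event_series(1, "S1")), "2 events")
})

test_that("detected tachogram matches truth within 5 ms per interval", {
  rec <- clean_recording()
  tpl <- auto_select_template(rec$hs, "S1")
  ev <- detect_events(rec$hs, tpl)
  det <- inter_beat_intervals(ev)
  ref <- inter_beat_intervals(event_series(rec$truth$s1_times, "S1"))
  expect_identical(length(det), length(ref))
  expect_lt(max(abs(det$intervals - ref$intervals)), 5)
})

test_that("interval exclusion drops everything touching FP/FN", {
  r <- event_series(seq(0, 20, by = 1), "R")   # 21 beats, 20 intervals
  n <- length(r)
  # perfect detection: all n - 1 pairs retained
  d0 <- event_series(r$times + 0.05, "S1")
  m0 <- match_events(d0, r)
  p0 <- paired_valid_intervals(inter_beat_intervals(d0),
                               inter_beat_intervals(r), m0)
  expect_identical(length(p0$x), n - 1L)
  expect_equal(p0$x, p0$y, tolerance = 1e-9)

  # one isolated interior miss removes its two flanking intervals
  d1 <- event_series(r$times[-10] + 0.05, "S1")
  m1 <- match_events(d1, r)
  p1 <- paired_valid_intervals(inter_beat_intervals(d1),
                               inter_beat_intervals(r), m1)
  expect_identical(length(p1$x), n - 3L)
})

test_that("exclusion agrees with a brute-force audit on a messy fixture", {
  r <- event_series(seq(0, 30, by = 1), "R")
  # 2 FPs and 1 interior FN
  d_times <- sort(c(r$times[-12] + 0.05, 5.5, 17.45))
  d <- event_series(d_times, "S1")
  m <- match_events(d, r)
  expect_identical(m$fp, 2L)
  expect_identical(m$fn, 1L)
  det_t <- inter_beat_intervals(d)
  ref_t <- inter_beat_intervals(r)
  p <- paired_valid_intervals(det_t, ref_t, m)
  # audit from the detected side: count consecutive-detection pairs whose
  # members are TPs assigned to consecutive reference beats
  audit <- 0L
  for (j in seq_len(length(d) - 1)) {
    k1 <- match(j, m$assignments)
    k2 <- match(j + 1, m$assignments)
    if (!is.na(k1) && !is.na(k2) && k2 == k1 + 1) audit <- audit + 1L
  }
  expect_identical(length(p$x), audit)
  expect_lte(length(p$x), min(length(d), length(r)) - 1L)
  # masked tachograms mirror the retained pairs
  expect_identical(sum(p$det_tacho$valid_mask), audit)
  expect_identical(sum(p$ref_tacho$valid_mask), audit)
})

test_that("tachogram construction validates its invariants", {
  expect_error(tachogram(c(800, -5), c(1, 2)), "positive")
  expect_error(tachogram(c(800, 810), c(1)), "equal length")
  tac <- tachogram(c(800, 810), c(0.8, 1.61))
  expect_equal(tac$intervals, diff(c(0, 0.8, 1.61)) * 1000,
               tolerance = 1e-6)
})
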