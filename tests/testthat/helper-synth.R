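# Shared synthetic fixtures, generated once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 40 s clean recording with default (realistic) noise, plus its heart-sound
# component — reused by matcher/beats/pipeline tests.
clean_recording <- function() {
  cached("clean40", {
    rec <- generate_recording(synth_config(duration = 40, seed = 11))
    resp <- extract_respiratory(rec$fcg)
    rec$hs <- bandpass_heart_sounds(remove_baseline(rec$fcg, resp))
    rec
  })
}

# Naive O(N*M) zero-mean NCC, the independent oracle for the production
# implementation.
ncc_naive <- function(x, tpl) {
  n <- length(x); m <- length(tpl)
  tbar <- mean(tpl)
  out <- numeric(n - m + 1)
  for (k in seq_len(n - m + 1)) {
    w <- x[k:(k + m - 1)]
    num <- sum((w - mean(w)) * (tpl - tbar))
    den <- sqrt(sum((w - mean(w))^2) * sum((tpl - tbar)^2))
    out[k] <- if (den == 0) 0 else num / den
  }
  out
}

# Brute-force Passing-Bablok slope/intercept via explicit double loops,
# independent of the production combn-based code.
pb_naive <- function(x, y) {
  n <- length(x)
  s <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[j] == x[i]) next
    sij <- (y[j] - y[i]) / (x[j] - x[i])
    if (sij != -1) s <- c(s, sij)
  }
  s <- sort(s)
  nn <- length(s)
  k <- sum(s < -1)
  slope <- if (nn %% 2 == 1) s[(nn + 1) / 2 + k] else
    (s[nn / 2 + k] + s[nn / 2 + 1 + k]) / 2
  list(slope = slope, intercept = median(y - slope * x))
}

# Naive O(n^2) ApEn/SampEn with explicit loops (Chebyshev distance).
entropy_naive <- function(x, m = 2, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cnt <- numeric(nt)
    for (i in 1:nt) {
      c_i <- 0
      for (j in 1:nt) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) c_i <- c_i + 1
      }
      cnt[i] <- c_i
    }
    mean(log(cnt / nt))
  }
  apen <- phi(m) - phi(m + 1)
  nt <- n - m
  a <- 0; b <- 0
  for (i in 1:nt) for (j in 1:nt) {
    if (i == j) next
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) b <- b + 1
    if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) a <- a + 1
  }
  list(apen = apen, sampen = if (a > 0 && b > 0) -log(a / b) else NA_real_)
}
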