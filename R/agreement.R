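#' Passing-Bablok regression
#'
#' Non-parametric method-comparison regression. The slope is the shifted
#' median of all pairwise slopes \eqn{S_{ij} = (y_j - y_i)/(x_j - x_i)}
#' (\eqn{i < j}), where slopes equal to -1 and pairs with tied `x` are
#' excluded and the median is offset by `K`, the number of slopes below -1
#' — which makes the estimate invariant under exchange of the two methods.
#' The intercept is `median(y - slope * x)`. Confidence intervals use the
#' rank-based normal approximation of the original procedure.
#'
#' @param x,y Paired measurements of the same quantity by two methods
#'   (length >= 10... the procedure is defined for n >= 3 but interval
#'   estimates need a reasonable n; an error is raised below 3 points and
#'   the CI uses the normal approximation regardless).
#' @param conf_level Confidence level for the slope/intercept intervals
#'   (default 0.95).
#' @return An object of class `passing_bablok` with components `slope`,
#'   `intercept`, `slope_ci`, `intercept_ci`, `n`, plus the data and the
#'   cusum linearity result (see [cusum_linearity()]).
#' @seealso [cusum_linearity()], [bland_altman()], [pearson_ci()]
#' @export
#' @examples
#' x <- c(1:15)
#' y <- 2 * x + 3
#' fit <- passing_bablok(x, y)
#' coef(fit)
passing_bablok <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("`x` and `y` must be paired", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired points", call. = FALSE)
  if (max(x) == min(x))
    stop("degenerate input: all x equal", call. = FALSE)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  s <- dy[keep] / dx[keep]
  s <- s[s != -1]
  if (!length(s)) stop("no admissible pairwise slopes", call. = FALSE)
  s <- sort(s)
  nn <- length(s)
  k_off <- sum(s < -1)
  # shifted median
  slope <- if (nn %% 2 == 1) s[(nn + 1) %/% 2 + k_off] else
    mean(s[nn %/% 2 + k_off + c(0L, 1L)])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  w <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((nn - w) / 2)
  m2 <- nn - m1 + 1
  slope_ci <- c(s[max(1L, m1 + k_off)], s[min(nn, m2 + k_off)])
  intercept <- stats::median(y - slope * x)
  intercept_ci <- c(stats::median(y - slope_ci[2] * x),
                    stats::median(y - slope_ci[1] * x))
  fit <- structure(list(slope = slope, intercept = intercept,
                        slope_ci = slope_ci, intercept_ci = intercept_ci,
                        n = n, conf_level = conf_level, x = x, y = y),
                   class = "passing_bablok")
  fit$cusum <- cusum_linearity(x, y, slope, intercept)
  fit
}

#' @export
print.passing_bablok <- function(x, digits = 4, ...) {
  cat("Passing-Bablok regression\n")
  cat(sprintf("  n = %d\n", x$n))
  cat(sprintf("  slope     %s  [%s; %s]\n",
              format(x$slope, digits = digits),
              format(x$slope_ci[1], digits = digits),
              format(x$slope_ci[2], digits = digits)))
  cat(sprintf("  intercept %s  [%s; %s]\n",
              format(x$intercept, digits = digits),
              format(x$intercept_ci[1], digits = digits),
              format(x$intercept_ci[2], digits = digits)))
  cat(sprintf("  cusum linearity: %s (p %s 0.1)\n",
              if (x$cusum$linear) "not rejected" else "rejected",
              if (x$cusum$linear) ">" else "<="))
  invisible(x)
}

#' @export
coef.passing_bablok <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.passing_bablok <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$intercept + object$slope * xx
}

#' @export
residuals.passing_bablok <- function(object, ...) {
  object$y - predict(object)
}

#' @export
summary.passing_bablok <- function(object, ...) {
  r <- pearson_ci(object$x, object$y,
                  conf_level = object$conf_level)
  out <- c(object[c("slope", "slope_ci", "intercept", "intercept_ci", "n",
                    "cusum", "conf_level")],
           list(r = r$r, r_ci = r$ci))
  class(out) <- "summary.passing_bablok"
  out
}

#' @export
print.summary.passing_bablok <- function(x, digits = 4, ...) {
  cat("Passing-Bablok method comparison\n")
  cat(sprintf("  n = %d, r = %s [%s; %s]\n", x$n,
              format(x$r, digits = digits),
              format(x$r_ci[1], digits = digits),
              format(x$r_ci[2], digits = digits)))
  cat(sprintf("  slope     %s [%s; %s]\n", format(x$slope, digits = digits),
              format(x$slope_ci[1], digits = digits),
              format(x$slope_ci[2], digits = digits)))
  cat(sprintf("  intercept %s [%s; %s]\n",
              format(x$intercept, digits = digits),
              format(x$intercept_ci[1], digits = digits),
              format(x$intercept_ci[2], digits = digits)))
  cat(sprintf("  cusum linearity %s\n",
              if (x$cusum$linear) "not rejected (p > 0.1)"
              else "rejected (p <= 0.1)"))
  invisible(x)
}

#' @export
plot.passing_bablok <- function(x, ..., xlab = "method 1",
                                ylab = "method 2") {
  graphics::plot(x$x, x$y, pch = 20, xlab = xlab, ylab = ylab, ...)
  graphics::abline(a = x$intercept, b = x$slope, col = "red")
  graphics::abline(a = 0, b = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Cusum linearity test for a Passing-Bablok fit
#'
#' Walks the points in ascending `x` order, accumulating the signs of the
#' residuals about the fitted line, and compares the maximum absolute
#' cumulative sum against the Kolmogorov-Smirnov-type critical value. A
#' systematic (non-linear) deviation makes long runs of equal signs and a
#' large cusum excursion.
#'
#' @param x,y Paired data.
#' @param slope,intercept The fitted line.
#' @param alpha Significance level (default 0.10; critical value 1.22).
#' @return A list with `linear` (`TRUE` when linearity is *not* rejected,
#'   i.e. p > alpha), `stat` (max |cusum| / sqrt(L + 1) with L the number
#'   of nonzero residual signs) and `critical`.
#' @export
cusum_linearity <- function(x, y, slope, intercept, alpha = 0.10) {
  stopifnot(length(x) == length(y))
  ord <- order(x)
  res <- y[ord] - (intercept + slope * x[ord])
  sgn <- sign(res)
  sgn <- sgn[sgn != 0]
  if (!length(sgn))
    return(list(linear = TRUE, stat = 0, critical = ks_critical(alpha)))
  cs <- cumsum(sgn)
  stat <- max(abs(cs)) / sqrt(length(sgn) + 1)
  crit <- ks_critical(alpha)
  list(linear = stat < crit, stat = stat, critical = crit)
}

# Two-sided Kolmogorov critical values c(alpha): 1.36 at 0.05, 1.22 at 0.10.
ks_critical <- function(alpha) {
  sqrt(-log(alpha / 2) / 2)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Paired data, n >= 4, both with positive variance.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `r` and `ci` (length-2 vector).
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (n < 4) stop("need at least 4 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined statistic: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(r = r, ci = tanh(c(z - q * se, z + q * se)))
}

#' Bland-Altman agreement analysis
#'
#' Analyzes the paired differences `d = y - x`. When the differences are
#' compatible with normality (Shapiro-Wilk, alpha 0.05 by default), the
#' bias is their mean and the limits of agreement are
#' `bias +/- 1.96 * sd(d)`, with a t-based confidence interval for the bias
#' (`SE = sd/sqrt(n)`) and for each limit (`SE = sd * sqrt(3/n)`). When
#' normality is rejected, the bias is the median and the limits are the
#' 2.5th and 97.5th percentiles (linear-interpolation quantiles), with
#' seeded bootstrap confidence intervals.
#'
#' @param x,y Paired measurements, n >= 10.
#' @param conf_level Confidence level (default 0.95).
#' @param normality_alpha Shapiro-Wilk significance level gating the
#'   percentile variant (default 0.05). Set to 0 to force the normal
#'   variant, 1 to force the percentile variant.
#' @param boot_n Bootstrap resamples for percentile-variant CIs
#'   (default 2000).
#' @param seed Seed for the bootstrap (default 1).
#' @return An object of class `bland_altman` with fields `bias`, `bias_ci`,
#'   `loa_low`, `loa_high`, `loa_low_ci`, `loa_high_ci`, `normal`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50, 800, 50)
#' bland_altman(x, x + rnorm(50, 2, 5))
bland_altman <- function(x, y, conf_level = 0.95, normality_alpha = 0.05,
                         boot_n = 2000, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must be paired",
                                   call. = FALSE)
  d <- y - x
  n <- length(d)
  if (n < 10) stop("insufficient data: need n >= 10", call. = FALSE)
  normal <- if (normality_alpha <= 0) TRUE
    else if (normality_alpha >= 1) FALSE
    else if (stats::sd(d) == 0) TRUE
    else stats::shapiro.test(d)$p.value >= normality_alpha
  q <- 1 - (1 - conf_level) / 2
  if (normal) {
    m <- mean(d); s <- stats::sd(d)
    tq <- stats::qt(q, df = n - 1)
    bias <- m
    loa_low <- m - 1.96 * s
    loa_high <- m + 1.96 * s
    bias_ci <- m + c(-1, 1) * tq * s / sqrt(n)
    se_loa <- s * sqrt(3 / n)
    loa_low_ci <- loa_low + c(-1, 1) * tq * se_loa
    loa_high_ci <- loa_high + c(-1, 1) * tq * se_loa
  } else {
    qs <- function(v) c(stats::median(v),
                        stats::quantile(v, c(0.025, 0.975), names = FALSE,
                                        type = 7))
    est <- qs(d)
    bias <- est[1]; loa_low <- est[2]; loa_high <- est[3]
    boot <- with_seed(seed, {
      vapply(seq_len(boot_n),
             function(i) qs(sample(d, n, replace = TRUE)),
             numeric(3))
    })
    ci <- apply(boot, 1, stats::quantile, probs = c(1 - q, q),
                names = FALSE, type = 7)
    bias_ci <- ci[, 1]; loa_low_ci <- ci[, 2]; loa_high_ci <- ci[, 3]
  }
  structure(list(bias = bias, bias_ci = bias_ci,
                 loa_low = loa_low, loa_high = loa_high,
                 loa_low_ci = loa_low_ci, loa_high_ci = loa_high_ci,
                 normal = normal, n = n, differences = d,
                 means = (x + y) / 2, conf_level = conf_level),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat(sprintf("Bland-Altman analysis (n = %d, %s differences)\n", x$n,
              if (x$normal) "normal" else "non-normal"))
  cat(sprintf("  bias %s [%s; %s]\n", format(x$bias, digits = digits),
              format(x$bias_ci[1], digits = digits),
              format(x$bias_ci[2], digits = digits)))
  cat(sprintf("  LoA  [%s; %s]\n", format(x$loa_low, digits = digits),
              format(x$loa_high, digits = digits)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ..., xlab = "mean of methods",
                              ylab = "difference") {
  graphics::plot(x$means, x$differences, pch = 20, xlab = xlab,
                 ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("blue", "red", "red"))
  invisible(x)
}

#' Full agreement analysis of two paired series
#'
#' Passing-Bablok regression (with cusum linearity), Pearson correlation
#' with CI, and Bland-Altman analysis in one call — the comparison applied
#' to each template's inter-beat intervals against the ECG reference.
#'
#' @param x Reference series (e.g. ECG inter-beat intervals, ms).
#' @param y Test series (e.g. heart-sound inter-beat intervals, ms).
#' @param ... Passed to [bland_altman()].
#' @return A list with `regression` ([passing_bablok()]), `correlation`
#'   ([pearson_ci()]) and `bland_altman` ([bland_altman()]).
#' @export
agreement_analysis <- function(x, y, ...) {
  list(regression = passing_bablok(x, y),
       correlation = pearson_ci(x, y),
       bland_altman = bland_altman(x, y, ...))
}
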