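#' Bootstrap confidence interval for a mean
#'
#' Draws `B` resamples of size n with replacement from `values`, takes the
#' mean of each, and summarises the bootstrap distribution: its mean H_bar*,
#' its standard deviation sigma* (computed with a 1/B variance, no B-1
#' correction), the absolute bias |mean(values) - H_bar*|, and a confidence
#' interval. The default `normal_quantile` interval is
#' H_bar* +/- z_{1-alpha/2} * sigma*; the `percentile` interval takes the
#' empirical alpha/2 and 1-alpha/2 quantiles of the replicate means.
#'
#' @param values numeric sample (e.g. per-unit Shannon indices), length >= 2.
#' @param B number of bootstrap replicates (default 1000).
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @param method `"normal_quantile"` (default) or `"percentile"`.
#' @param seed integer seed; results are bit-reproducible given the seed and
#'   the caller's RNG stream is left untouched.
#' @return object of class `bootstrap_result`: list with `B`, `n`,
#'   `sample_mean`, `h_bar_star`, `sigma_star`, `bias`, `ci_low`, `ci_high`,
#'   `width`, `alpha`, `method`, `seed`.
#' @export
bootstrap_mean_ci <- function(values, B = 1000, alpha = 0.05,
                              method = c("normal_quantile", "percentile"),
                              seed) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 2L || any(!is.finite(values))) {
    abort("need at least 2 finite values to bootstrap")
  }
  if (B < 2L) abort("B must be >= 2")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (missing(seed)) abort("a seed is required for a reproducible bootstrap")

  reps <- with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n, ncol = B))
  })
  h_bar <- mean(reps)
  sigma <- sqrt(mean((reps - h_bar)^2))  # 1/B variance
  if (method == "normal_quantile") {
    z <- qnorm(1 - alpha / 2)
    ci <- c(h_bar - z * sigma, h_bar + z * sigma)
  } else {
    ci <- unname(quantile(reps, c(alpha / 2, 1 - alpha / 2)))
  }
  structure(list(B = as.integer(B), n = n, sample_mean = mean(values),
                 h_bar_star = h_bar, sigma_star = sigma,
                 bias = abs(mean(values) - h_bar),
                 ci_low = ci[[1L]], ci_high = ci[[2L]],
                 width = ci[[2L]] - ci[[1L]], alpha = alpha, method = method,
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap of the mean: B = %d, n = %d, seed = %d\n",
              x$B, x$n, x$seed))
  cat(sprintf("  H_bar* = %.5f, sigma* = %.6f, bias = %.5f\n",
              x$h_bar_star, x$sigma_star, x$bias))
  cat(sprintf("  %d%% %s CI (%.4f, %.4f), width %.4f\n",
              round(100 * (1 - x$alpha)), x$method, x$ci_low, x$ci_high,
              x$width))
  invisible(x)
}

# Lilliefors sup-distance between the empirical CDF and the normal CDF with
# mean/sd estimated from the sample
lilliefors_statistic <- function(values) {
  n <- length(values)
  z <- (sort(values) - mean(values)) / sd(values)
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Lilliefors normality test with a Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov-type test of normality with mean and sd estimated from
#' the sample. The statistic D is the sup distance between the empirical CDF
#' and the fitted normal CDF; the p-value is estimated by Monte Carlo as the
#' proportion of `n_mc` standard-normal samples of the same size (with the
#' same parameter estimation) whose D* is at least the observed D — no table
#' lookup, reproducible given the seed.
#'
#' @param values numeric sample, length >= 4, non-constant.
#' @param n_mc number of null replicates (default 10000).
#' @param seed integer seed.
#' @return object of class `normality_test`: list with `statistic`, `p_value`,
#'   `n`, `n_mc`, `seed`.
#' @export
lilliefors_normal <- function(values, n_mc = 10000, seed) {
  n <- length(values)
  if (n < 4L || any(!is.finite(values))) {
    abort("need at least 4 finite values")
  }
  if (sd(values) == 0) abort("zero-variance input; normality is undefined")
  if (missing(seed)) abort("a seed is required for the Monte-Carlo p-value")
  d_obs <- lilliefors_statistic(values)
  d_null <- with_seed(seed, {
    m <- matrix(rnorm(n * n_mc), nrow = n)
    apply(m, 2L, lilliefors_statistic)
  })
  structure(list(statistic = d_obs, p_value = mean(d_null >= d_obs),
                 n = n, n_mc = as.integer(n_mc), seed = as.integer(seed)),
            class = "normality_test")
}

#' @export
print.normality_test <- function(x, ...) {
  cat(sprintf("Lilliefors normality test: D = %.5f, Monte-Carlo p = %.4f (n = %d, %d null replicates, seed %d)\n",
              x$statistic, x$p_value, x$n, x$n_mc, x$seed))
  invisible(x)
}
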