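#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    pg_stop("petgate_insufficient_data",
            "x and y must be paired with at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    pg_stop("petgate_invalid_parameter", "x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    pg_stop("petgate_undefined_correlation",
            "correlation undefined for zero-variance input")
  stats::cor(x, y)
}

#' Deming errors-in-variables regression
#'
#' Fits `y = intercept + slope * x` acknowledging measurement error in
#' both variables.  `lambda_ratio` is the ratio of the error variance of
#' `y` to that of `x`; the default 1 gives orthogonal regression, and
#' `lambda_ratio -> Inf` recovers ordinary least squares of `y` on `x`.
#' The closed-form estimate uses the sample variances and covariance.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param lambda_ratio Positive error-variance ratio; default 1.
#' @return An object of class `deming_fit` with `slope`, `intercept`,
#'   `lambda_ratio`.
#' @export
deming_fit <- function(x, y, lambda_ratio = 1) {
  if (length(x) != length(y) || length(x) < 3L)
    pg_stop("petgate_insufficient_data",
            "x and y must be paired with at least 3 observations")
  check_scalar_number(lambda_ratio, "lambda_ratio",
                      lower = 0, strict_lower = TRUE)
  sxx <- stats::var(x)
  syy <- stats::var(y)
  sxy <- stats::cov(x, y)
  scale2 <- max(sxx * lambda_ratio, syy, .Machine$double.eps)
  if (abs(sxy) < 1e-12 * scale2) {
    if (abs(syy - lambda_ratio * sxx) < 1e-12 * scale2)
      pg_stop("petgate_ambiguous_fit",
              "zero covariance with matched variances: the fit is ambiguous")
    pg_stop("petgate_ambiguous_fit",
            "covariance is zero; no meaningful line through the data")
  }
  q <- syy - lambda_ratio * sxx
  slope <- (q + sqrt(q^2 + 4 * lambda_ratio * sxy^2)) / (2 * sxy)
  intercept <- mean(y) - slope * mean(x)
  structure(list(slope = slope, intercept = intercept,
                 lambda_ratio = lambda_ratio),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming fit (lambda = %g): y = %.4g + %.4g x\n",
              x$lambda_ratio, x$intercept, x$slope))
  invisible(x)
}

#' Relative Bland-Altman agreement analysis
#'
#' Per pair, the relative difference is
#' `d_i = 100 * (ref_i - test_i) / m_i`, where the denominator `m_i` is
#' the pairwise mean (Bland-Altman convention, default) or the reference
#' value.  Bias is the mean of `d`, the limits of agreement are
#' `bias +/- 1.96 sd(d)` (sample sd), and the amplitude is their
#' difference.  With this sign convention, underestimation by the test
#' modality yields a positive bias.
#'
#' @param reference,test Paired numeric vectors (length >= 2); every
#'   denominator must be positive.
#' @param denominator `"mean"` (default) or `"reference"`.
#' @return An object of class `agreement_result` with `bias_pct`,
#'   `loa_lower_pct`, `loa_upper_pct`, `loa_amplitude_pct`, `n_pairs`,
#'   plus the per-pair `means` and `diffs_pct` for plotting.
#' @export
bland_altman_relative <- function(reference, test,
                                  denominator = c("mean", "reference")) {
  denominator <- match.arg(denominator)
  if (length(reference) != length(test) || length(reference) < 2L)
    pg_stop("petgate_insufficient_data",
            "reference and test must be paired with at least 2 observations")
  m <- (reference + test) / 2
  den <- if (denominator == "mean") m else reference
  if (any(!is.finite(den)) || any(den <= 0))
    pg_stop("petgate_invalid_data",
            "all pair denominators must be positive")
  d <- 100 * (reference - test) / den
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias_pct = bias,
                 loa_lower_pct = bias - 1.96 * s,
                 loa_upper_pct = bias + 1.96 * s,
                 loa_amplitude_pct = 2 * 1.96 * s,
                 n_pairs = length(d),
                 means = m, diffs_pct = d,
                 denominator = denominator),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.2f%%, LoA [%.2f, %.2f]%%, amplitude %.2f%%\n",
    x$n_pairs, x$bias_pct, x$loa_lower_pct, x$loa_upper_pct,
    x$loa_amplitude_pct))
  invisible(x)
}

#' Bland-Altman plot of an agreement result
#'
#' @param x An `agreement_result`.
#' @param xlab,ylab,main Usual plot labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.agreement_result <- function(x, xlab = "Pairwise mean",
                                  ylab = "Relative difference (%)",
                                  main = "Bland-Altman", ...) {
  graphics::plot(x$means, x$diffs_pct, xlab = xlab, ylab = ylab,
                 main = main, pch = 19, ...)
  graphics::abline(h = x$bias_pct, col = "blue")
  graphics::abline(h = c(x$loa_lower_pct, x$loa_upper_pct),
                   col = "red", lty = 2)
  invisible(x)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences receive
#' mid-ranks.  For up to 15 non-zero pairs the p value is computed from
#' the exact null distribution of the positive-rank sum (all sign
#' assignments equally likely, handled by convolution so ties are exact
#' too); beyond that a normal approximation with tie correction and
#' continuity correction is used.  If every difference is zero the test
#' is degenerate and `p = 1` is returned by convention.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_limit Largest number of non-zero pairs for which the exact
#'   distribution is enumerated (default 15).
#' @return Two-sided p value in `(0, 1]`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 15) {
  if (length(x) != length(y))
    pg_stop("petgate_invalid_parameter", "x and y must be paired")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # exact null distribution of 2W by convolution over ranks (doubling
    # keeps mid-ranks integral)
    r2 <- round(2 * r)
    total <- sum(r2)
    dist <- numeric(total + 1L)  # index k+1 holds P-count of 2W = k
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(total + 1L - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- round(2 * w)
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):(total + 1L)])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}
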