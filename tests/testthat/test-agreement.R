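# independent oracles ------------------------------------------------------

pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# two-stage grid search minimising summed perpendicular squared distances
deming_grid_oracle <- function(x, y) {
  obj <- function(b) {
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2 / (1 + b^2))
  }
  bs <- seq(-10, 10, by = 0.01)
  b0 <- bs[which.min(vapply(bs, obj, numeric(1)))]
  bs <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  b <- bs[which.min(vapply(bs, obj, numeric(1)))]
  c(slope = b, intercept = mean(y) - b * mean(x))
}

# exhaustive sign-flip null distribution of the positive-rank sum
wilcoxon_enum_oracle <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# ---------------------------------------------------------------------------

test_that("pearson_r matches the textbook summation formula", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  x <- c(1, 2, 3); y <- c(2, 1, 3)
  expect_equal(pearson_r(x, y), pearson_oracle(x, y))
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(pearson_r(x, y), pearson_oracle(x, y))
  }
})

test_that("pearson_r is invariant under positive affine transforms", {
  set.seed(2)
  x <- rnorm(20); y <- x + rnorm(20)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(3 * x + 7, y), r)
  expect_equal(pearson_r(x, 0.1 * y - 2), r)
  expect_error(pearson_r(rep(1, 5), 1:5),
               class = "petgate_undefined_correlation")
  expect_error(pearson_r(1:2, 1:2), class = "petgate_insufficient_data")
})

test_that("deming_fit recovers exact lines and the orthogonal symmetry", {
  fit <- deming_fit(1:3, 1:3)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  set.seed(3)
  x <- rnorm(15, 10, 3); y <- 2 + 0.8 * x + rnorm(15, 0, 0.5)
  f1 <- deming_fit(x, y, 1)
  f2 <- deming_fit(y, x, 1)
  expect_equal(f2$slope, 1 / f1$slope)
})

test_that("deming_fit matches a perpendicular-distance grid search", {
  set.seed(4)
  for (i in 1:3) {
    x <- rnorm(10, 5, 2)
    y <- 1 + 1.3 * x + rnorm(10, 0, 0.8)
    fit <- deming_fit(x, y, 1)
    ora <- deming_grid_oracle(x, y)
    expect_equal(fit$slope, unname(ora["slope"]), tolerance = 1e-3)
    expect_equal(fit$intercept, unname(ora["intercept"]), tolerance = 1e-2)
  }
})

test_that("deming_fit approaches OLS as the variance ratio diverges", {
  set.seed(5)
  x <- rnorm(30, 10, 4); y <- 3 + 0.7 * x + rnorm(30)
  ols <- stats::lm(y ~ x)
  f <- deming_fit(x, y, 1e6)
  expect_equal(f$slope, unname(coef(ols)[2]), tolerance = 1e-4)
  expect_equal(f$intercept, unname(coef(ols)[1]), tolerance = 1e-3)
})

test_that("deming_fit flags degenerate configurations", {
  # orthogonal, uncorrelated, equal variances: direction undefined
  x <- c(-1, 0, 1, 0); y <- c(0, 1, 0, -1)
  expect_error(deming_fit(x, y, 1), class = "petgate_ambiguous_fit")
  expect_error(deming_fit(1:2, 1:2), class = "petgate_insufficient_data")
})

test_that("relative Bland-Altman matches hand-computed values", {
  ba0 <- bland_altman_relative(c(100, 200), c(100, 200))
  expect_equal(ba0$bias_pct, 0)
  expect_equal(ba0$loa_amplitude_pct, 0)
  ba <- bland_altman_relative(c(100, 200), c(90, 210))
  d1 <- 100 * 10 / 95
  d2 <- 100 * (-10) / 205
  expect_equal(ba$bias_pct, mean(c(d1, d2)))
  expect_equal(ba$bias_pct, 2.824133, tolerance = 1e-6)
  expect_equal(ba$loa_upper_pct - ba$loa_lower_pct, ba$loa_amplitude_pct)
  expect_equal(ba$loa_amplitude_pct, 2 * 1.96 * sd(c(d1, d2)))
  expect_equal(ba$n_pairs, 2)
})

test_that("Bland-Altman is antisymmetric and shrinks under level shifts", {
  set.seed(6)
  ref <- runif(15, 80, 200)
  tst <- ref * runif(15, 0.8, 1.1)
  a <- bland_altman_relative(ref, tst)
  b <- bland_altman_relative(tst, ref)
  expect_equal(b$bias_pct, -a$bias_pct)
  expect_equal(b$loa_lower_pct, -a$loa_upper_pct)
  expect_equal(b$loa_upper_pct, -a$loa_lower_pct)
  # adding a common offset to every pair shrinks the relative differences
  shifted <- bland_altman_relative(ref + 100, tst + 100)
  expect_lt(abs(shifted$bias_pct), abs(a$bias_pct))
  expect_error(bland_altman_relative(c(1, -2), c(1, 1)),
               class = "petgate_invalid_data")
})

test_that("reference-denominator variant is available", {
  ba <- bland_altman_relative(c(100, 200), c(90, 210),
                              denominator = "reference")
  expect_equal(ba$bias_pct, mean(c(10, -5)))
})

test_that("Wilcoxon exact p values match full enumeration", {
  expect_equal(wilcoxon_signed_rank(1:5, 1:5), 1)
  # all five differences positive with distinct magnitudes
  x <- c(5, 7, 9, 11, 13); y <- c(4, 5, 6, 7, 8)
  expect_equal(wilcoxon_signed_rank(x, y), 0.0625)
  set.seed(7)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    x <- rnorm(n)
    y <- x + rnorm(n)
    if (i %% 2 == 0) y[1:2] <- x[1:2] + rep(diff(range(x)) / 4, 2)  # ties
    expect_equal(wilcoxon_signed_rank(x, y), wilcoxon_enum_oracle(x, y))
  }
})

test_that("tie-free exact p agrees with the classical distribution", {
  set.seed(8)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(x, y),
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("Wilcoxon p values are proper and respond to concordant evidence", {
  set.seed(9)
  x <- rnorm(8); y <- x + abs(rnorm(8)) + 0.1
  p1 <- wilcoxon_signed_rank(x, y)
  # one more concordant pair strengthens the evidence
  x2 <- c(x, 0); y2 <- c(y, 1)
  p2 <- wilcoxon_signed_rank(x2, y2)
  expect_lt(p2, p1)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
  # zeros are dropped, not counted
  expect_equal(wilcoxon_signed_rank(c(x, 5), c(y, 5)), p1)
  # the large-sample path also yields a proper two-sided p
  xl <- rnorm(40); yl <- xl + rnorm(40, 0.3)
  pl <- wilcoxon_signed_rank(xl, yl)
  expect_gt(pl, 0)
  expect_lte(pl, 1)
})
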