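# BCa bootstrap intervals and permutation tests.

test_that("identical samples give a zero difference with an interval around it", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9)
  r <- mean_diff_bca(x, x, n_boot = 2000, seed = 1)
  expect_equal(r$mean_difference, 0)
  expect_lte(r$ci_low, 0)
  expect_gte(r$ci_high, 0)
})

test_that("the interval is translation-invariant and seed-deterministic", {
  set.seed(41)
  x <- stats::rnorm(20)
  y <- stats::rnorm(20, 1)
  a <- mean_diff_bca(x, y, n_boot = 2000, seed = 5)
  b <- mean_diff_bca(x + 100, y + 100, n_boot = 2000, seed = 5)
  expect_equal(a$mean_difference, b$mean_difference)
  expect_equal(a$ci_low, b$ci_low, tolerance = 1e-9)
  expect_equal(a$ci_high, b$ci_high, tolerance = 1e-9)
  expect_identical(mean_diff_bca(x, y, n_boot = 500, seed = 7),
                   mean_diff_bca(x, y, n_boot = 500, seed = 7))
})

test_that("swapping the samples negates the estimate and mirrors the interval", {
  set.seed(42)
  x <- stats::rnorm(30)
  y <- stats::rnorm(30, 1.5)
  a <- mean_diff_bca(x, y, n_boot = 4000, seed = 9)
  b <- mean_diff_bca(y, x, n_boot = 4000, seed = 9)
  expect_equal(a$mean_difference, -b$mean_difference)
  expect_equal(a$ci_low, -b$ci_high, tolerance = 0.05)
  expect_equal(a$ci_high, -b$ci_low, tolerance = 0.05)
  p1 <- permutation_pvalue(x, y, n_perm = 2000, seed = 9)
  p2 <- permutation_pvalue(y, x, n_perm = 2000, seed = 9)
  expect_equal(p1, p2, tolerance = 0.02)
})

test_that("widening the confidence level widens the BCa interval", {
  set.seed(43)
  x <- stats::rnorm(25)
  y <- stats::rnorm(25, 0.8)
  narrow <- mean_diff_bca(x, y, n_boot = 3000, alpha = 0.10, seed = 3)
  wide <- mean_diff_bca(x, y, n_boot = 3000, alpha = 0.01, seed = 3)
  expect_lt(wide$ci_low, narrow$ci_low)
  expect_gt(wide$ci_high, narrow$ci_high)
})

test_that("degenerate zero-variance samples collapse the interval with a flag", {
  r <- mean_diff_bca(rep(2, 5), rep(3, 5), seed = 1)
  expect_equal(r$mean_difference, 1)
  expect_equal(r$ci_low, 1)
  expect_equal(r$ci_high, 1)
  expect_match(r$flagged, "degenerate")
})

test_that("paired mode resamples within-pair differences", {
  set.seed(44)
  x <- stats::rnorm(15)
  y <- x + 0.5 + stats::rnorm(15, 0, 0.1)
  r <- mean_diff_bca(x, y, paired = TRUE, n_boot = 3000, seed = 2)
  expect_equal(r$mean_difference, mean(y - x))
  # pairing uses the tight within-pair spread, so the interval is narrow
  ru <- mean_diff_bca(x, y, paired = FALSE, n_boot = 3000, seed = 2)
  expect_lt(r$ci_high - r$ci_low, ru$ci_high - ru$ci_low)
  expect_error(mean_diff_bca(x, y[1:5], paired = TRUE), "equal length")
})

test_that("identical samples give a permutation p of essentially 1", {
  x <- c(0.5, 1.5, -0.2, 0.9, 2.0)
  expect_gte(permutation_pvalue(x, x, n_perm = 1000, seed = 1), 0.99)
})

test_that("permutation p is invariant under common affine transforms", {
  set.seed(45)
  x <- stats::rnorm(12)
  y <- stats::rnorm(12, 1)
  p1 <- permutation_pvalue(x, y, n_perm = 1000, seed = 4)
  p2 <- permutation_pvalue(3 * x - 7, 3 * y - 7, n_perm = 1000, seed = 4)
  expect_identical(p1, p2)
})

test_that("sampled permutation agrees with exhaustive enumeration at small n", {
  x <- c(1.2, -0.4, 0.8, 2.1)
  y <- c(0.3, -1.0, 0.5, 1.4)
  p_exact <- permutation_pvalue(x, y, exact = TRUE)
  # independent brute-force oracle over all C(8,4) label assignments
  z <- c(x, y)
  combs <- utils::combn(8, 4)
  t_obs <- abs(stats::t.test(x, y)$statistic)
  tt <- apply(combs, 2, function(i) {
    abs(stats::t.test(z[i], z[-i])$statistic)
  })
  expect_equal(p_exact, mean(tt >= t_obs - 1e-12))
  # the sampled p converges to the exact one
  p_mc <- permutation_pvalue(x, y, n_perm = 4000, seed = 6)
  expect_lt(abs(p_mc - p_exact), 0.03)

  # paired: sign-flip enumeration against a direct oracle
  d <- y - x
  p_pair <- permutation_pvalue(x, y, paired = TRUE, exact = TRUE)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  t_of <- function(v) mean(v) / (stats::sd(v) / sqrt(length(v)))
  tts <- apply(signs, 1, function(s) abs(t_of(s * d)))
  expect_equal(p_pair, mean(tts >= abs(t_of(d)) - 1e-12))
})

test_that("zero-variance permutation input is flagged with p = 1", {
  expect_warning(p <- permutation_pvalue(rep(1, 4), rep(1, 4)), "variance")
  expect_equal(p, 1)
})

test_that("estimate_difference combines interval and p-value deterministically", {
  set.seed(46)
  x <- stats::rnorm(10, 0)
  y <- stats::rnorm(10, 2)
  r <- estimate_difference(x, y, n_boot = 1000, n_perm = 1000, seed = 8)
  expect_lt(r$p_value, 0.05)
  expect_true(r$ci_low <= r$mean_difference && r$mean_difference <= r$ci_high)
  expect_identical(r, estimate_difference(x, y, n_boot = 1000, n_perm = 1000,
                                          seed = 8))
})
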