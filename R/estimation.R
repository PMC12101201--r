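# Estimation statistics: BCa bootstrap confidence intervals of mean
# differences and permutation tests.

#' BCa bootstrap confidence interval of a mean difference
#'
#' Point estimate `mean(y) - mean(x)` with a bias-corrected and accelerated
#' (BCa) bootstrap confidence interval. The bias correction `z0` is taken
#' from the bootstrap distribution; the acceleration `a` from the jackknife
#' skewness of the estimate. In `paired` mode the statistic is the mean of
#' within-pair differences and resampling is over pairs.
#'
#' @param x,y Numeric samples (each of size >= 2; equal length if paired).
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param alpha Two-sided miscoverage; 0.05 gives a 95% interval.
#' @param paired Resample within-pair differences instead of the two
#'   samples independently.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An object of class `estimation_result`: `mean_difference`,
#'   `ci_low`, `ci_high`, `conf_level`, `n_boot`, `seed`, `paired`, and a
#'   `flagged` note for degenerate cases (interval collapsed, or a
#'   pathological BCa interval not containing the point estimate).
#' @export
mean_diff_bca <- function(x, y, n_boot = 5000, alpha = 0.05,
                          paired = FALSE, seed = default_seed()) {
  stop_arg(length(x) >= 2 && length(y) >= 2, "each sample needs >= 2 values")
  if (paired) stop_arg(length(x) == length(y),
                       "paired samples must have equal length")
  obs <- mean(y) - mean(x)
  flagged <- NULL

  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(structure(list(mean_difference = obs, ci_low = obs, ci_high = obs,
                          conf_level = 1 - alpha, n_boot = n_boot,
                          seed = seed, paired = paired,
                          flagged = "degenerate: zero variance, interval collapsed to the point"),
                     class = "estimation_result"))
  }

  boot <- with_seed(child_seed(seed, "bca-boot"), {
    if (paired) {
      d <- y - x
      n <- length(d)
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      colMeans(matrix(d[idx], nrow = n))
    } else {
      nx <- length(x)
      ny <- length(y)
      ix <- matrix(sample.int(nx, nx * n_boot, replace = TRUE), nrow = nx)
      iy <- matrix(sample.int(ny, ny * n_boot, replace = TRUE), nrow = ny)
      colMeans(matrix(y[iy], nrow = ny)) - colMeans(matrix(x[ix], nrow = nx))
    }
  })

  # bias correction from the bootstrap distribution
  prop <- (sum(boot < obs) + 0.5 * sum(boot == obs)) / n_boot
  prop <- min(max(prop, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- stats::qnorm(prop)

  # acceleration from jackknife skewness
  theta <- if (paired) {
    d <- y - x
    vapply(seq_along(d), function(i) mean(d[-i]), numeric(1))
  } else {
    c(vapply(seq_along(x), function(i) mean(y) - mean(x[-i]), numeric(1)),
      vapply(seq_along(y), function(i) mean(y[-i]) - mean(x), numeric(1)))
  }
  u <- mean(theta) - theta
  denom <- 6 * sum(u^2)^1.5
  a <- if (denom == 0) 0 else sum(u^3) / denom

  zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- unname(stats::quantile(boot, adj, type = 7))
  if (obs < ci[1] || obs > ci[2]) {
    flagged <- "pathological BCa interval: point estimate outside interval"
  }
  structure(list(mean_difference = obs, ci_low = ci[1], ci_high = ci[2],
                 conf_level = 1 - alpha, n_boot = n_boot, seed = seed,
                 paired = paired, flagged = flagged),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("<estimation_result> mean difference ", signif(x$mean_difference, 4),
      " [", signif(x$ci_low, 4), ", ", signif(x$ci_high, 4), "] (",
      100 * x$conf_level, "% BCa, ", x$n_boot, " resamples, ",
      if (x$paired) "paired" else "unpaired", ")\n", sep = "")
  if (!is.null(x$p_value)) {
    cat("  permutation p = ", signif(x$p_value, 4), " (", x$n_perm,
        " reshuffles)\n", sep = "")
  }
  if (!is.null(x$flagged)) cat("  flagged:", x$flagged, "\n")
  invisible(x)
}

welch_t <- function(sx, sxx, nx, sy, syy, ny) {
  mx <- sx / nx
  my <- sy / ny
  vx <- (sxx - sx^2 / nx) / (nx - 1)
  vy <- (syy - sy^2 / ny) / (ny - 1)
  (my - mx) / sqrt(vx / nx + vy / ny)
}

#' Two-sided permutation test of a mean difference
#'
#' Permutation t-test with the Welch (unequal-variance) t statistic:
#' `n_perm` reshuffles of the group labels (or, in `paired` mode, random
#' sign flips of the within-pair differences with the one-sample t
#' statistic). The Monte-Carlo p-value uses add-one smoothing,
#' `p = (1 + #{|t*| >= |t|}) / (1 + n_perm)`, so it is never exactly zero.
#' With `exact = TRUE`, all distinct label assignments (or sign patterns)
#' are enumerated and the unsmoothed exact p-value is returned.
#'
#' @param x,y Numeric samples (combined size >= 3).
#' @param n_perm Number of label reshuffles (default 5000).
#' @param paired Use sign-flip permutations of `y - x`.
#' @param exact Enumerate all assignments instead of sampling.
#' @param seed Integer seed; deterministic given the seed.
#' @return The two-sided p-value in (0, 1].
#' @export
permutation_pvalue <- function(x, y, n_perm = 5000, paired = FALSE,
                               exact = FALSE, seed = default_seed()) {
  stop_arg(length(x) + length(y) >= 3, "combined sample size must be >= 3")
  if (paired) {
    stop_arg(length(x) == length(y), "paired samples must have equal length")
    d <- y - x
    n <- length(d)
    if (all(d == 0)) {
      warning("zero variance of differences: p = 1", call. = FALSE)
      return(1)
    }
    ssd <- sum(d^2)
    t_of <- function(s) {
      v <- (ssd - s^2 / n) / (n - 1)
      (s / n) / sqrt(v / n)
    }
    t_obs <- t_of(sum(d))
    if (exact) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      s <- as.vector(signs %*% d)
      tt <- t_of(s)
      return(mean(abs(tt) >= abs(t_obs) - 1e-12))
    }
    s <- with_seed(child_seed(seed, "perm-signs"), {
      flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
      colSums(flips * d)
    })
    tt <- t_of(s)
    return((1 + sum(abs(tt) >= abs(t_obs) - 1e-12)) / (1 + n_perm))
  }

  z <- c(x, y)
  nx <- length(x)
  ny <- length(y)
  if (stats::var(z) == 0) {
    warning("zero combined variance: p = 1", call. = FALSE)
    return(1)
  }
  t_obs <- welch_t(sum(x), sum(x^2), nx, sum(y), sum(y^2), ny)
  z2 <- z^2
  tot <- sum(z)
  tot2 <- sum(z2)
  if (exact) {
    combs <- utils::combn(nx + ny, nx)
    sx <- apply(combs, 2, function(i) sum(z[i]))
    sxx <- apply(combs, 2, function(i) sum(z2[i]))
    tt <- welch_t(sx, sxx, nx, tot - sx, tot2 - sxx, ny)
    return(mean(abs(tt) >= abs(t_obs) - 1e-12))
  }
  tt <- with_seed(child_seed(seed, "perm-labels"), {
    keys <- matrix(stats::runif((nx + ny) * n_perm), nrow = nx + ny)
    ord <- apply(keys, 2, order)
    xi <- matrix(z[ord[1:nx, , drop = FALSE]], nrow = nx)
    xi2 <- matrix(z2[ord[1:nx, , drop = FALSE]], nrow = nx)
    sx <- colSums(xi)
    sxx <- colSums(xi2)
    welch_t(sx, sxx, nx, tot - sx, tot2 - sxx, ny)
  })
  (1 + sum(abs(tt) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
}

#' Estimate a condition contrast: mean difference, BCa CI and permutation p
#'
#' Convenience wrapper combining [mean_diff_bca()] and
#' [permutation_pvalue()] for one contrast, as used for condition
#' comparisons of localization metrics. Paired mode (the default) is
#' appropriate when the same listeners are measured in both conditions.
#'
#' @inheritParams mean_diff_bca
#' @param n_perm Number of permutations for the p-value.
#' @return An `estimation_result` with `p_value` and `n_perm` set.
#' @export
estimate_difference <- function(x, y, n_boot = 5000, n_perm = 5000,
                                alpha = 0.05, paired = TRUE,
                                seed = default_seed()) {
  res <- mean_diff_bca(x, y, n_boot = n_boot, alpha = alpha, paired = paired,
                       seed = seed)
  res$p_value <- permutation_pvalue(x, y, n_perm = n_perm, paired = paired,
                                    seed = seed)
  res$n_perm <- n_perm
  res
}
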