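#' Pooled-resampling test for a difference in group means
#'
#' Both groups are pooled; on each of `n_resamples` iterations two
#' pseudo-groups of the original sizes are drawn from the pool and their
#' mean difference recorded, building the resampling distribution of the
#' mean difference under the null of exchangeable groups. The central
#' two-sided `(1 - alpha)` percentile interval of that distribution is
#' reported, and the null is rejected when the observed mean difference
#' falls outside it.
#'
#' The default draws with replacement (bootstrap resampling); the
#' permutation mode reshuffles the pool without replacement instead. The
#' two coincide asymptotically but differ at small n, so the choice is
#' explicit.
#'
#' @param x,y Numeric samples (each of size at least 2, finite).
#' @param n_resamples Number of resampling iterations (default 10000;
#'   fewer than 100 is refused).
#' @param alpha Two-sided level (default 0.05, i.e. a 95% interval).
#' @param mode `"bootstrap"` (with replacement, default) or
#'   `"permutation"`.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `resample_test`: `observed_diff`
#'   (mean(x) - mean(y)), `ci_low`, `ci_high`, `reject`, `n_resamples`,
#'   `alpha`, `mode`, `n1`, `n2`, `seed`.
#' @examples
#' g <- simulate_metric_groups(9, 5, meanA = 0, meanB = 2, sd = 1, seed = 1)
#' resampling_mean_diff_test(g$A, g$B, seed = 1)
#' @export
resampling_mean_diff_test <- function(x, y, n_resamples = 10000,
                                      alpha = 0.05,
                                      mode = c("bootstrap", "permutation"),
                                      seed = NULL) {
  mode <- match.arg(mode)
  if (length(x) < 2L || length(y) < 2L)
    stop_srseize("each group needs at least 2 values")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_srseize("groups must be finite")
  if (n_resamples < 100)
    stop_srseize("n_resamples below 100 gives unusable percentile bounds")
  n1 <- length(x); n2 <- length(y)
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  diffs <- with_seed(seed, {
    if (mode == "bootstrap") {
      a <- matrix(sample(pool, n1 * n_resamples, replace = TRUE), n1)
      b <- matrix(sample(pool, n2 * n_resamples, replace = TRUE), n2)
      colMeans(a) - colMeans(b)
    } else {
      vapply(seq_len(n_resamples), function(i) {
        p <- sample(pool)
        mean(p[seq_len(n1)]) - mean(p[-seq_len(n1)])
      }, numeric(1))
    }
  })
  ci <- quantile(diffs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(observed_diff = obs, ci_low = ci[1], ci_high = ci[2],
                 reject = obs < ci[1] || obs > ci[2],
                 n_resamples = n_resamples, alpha = alpha, mode = mode,
                 n1 = n1, n2 = n2, seed = seed),
            class = "resample_test")
}

#' @export
print.resample_test <- function(x, ...) {
  cat(sprintf("Pooled %s resampling test for a difference in means\n",
              x$mode))
  cat(sprintf("  n = %d vs %d, %d resamples\n", x$n1, x$n2, x$n_resamples))
  cat(sprintf("  observed difference: %.4g\n", x$observed_diff))
  cat(sprintf("  %g%% resampling interval: [%.4g, %.4g]\n",
              100 * (1 - x$alpha), x$ci_low, x$ci_high))
  cat(sprintf("  null %s at alpha = %g\n",
              if (x$reject) "REJECTED" else "not rejected", x$alpha))
  invisible(x)
}

#' Empirical rejection rate of a test over simulated data
#'
#' Runs `generate(i)` for `i` in `1:n_sims` (each call already sees a
#' distinct RNG substream under the master seed), applies `test` to the
#' generated data and returns the fraction of rejections.
#'
#' @param generate Function of the simulation index returning whatever
#'   `test` consumes.
#' @param test Function returning `TRUE` for rejection (or an object with
#'   a logical `$reject`).
#' @param n_sims Number of simulations (at least 100).
#' @param seed Master integer seed.
#' @return Rejection rate in `[0, 1]`.
#' @export
rejection_rate <- function(generate, test, n_sims, seed = NULL) {
  if (n_sims < 100) stop_srseize("n_sims must be at least 100")
  with_seed(seed, {
    rej <- vapply(seq_len(n_sims), function(i) {
      r <- test(generate(i))
      if (is.logical(r)) r else isTRUE(r$reject)
    }, logical(1))
    mean(rej)
  })
}

#' Type-I error rate of a test under a null generator
#' @inheritParams rejection_rate
#' @return Empirical rejection rate under the null.
#' @export
type1_error <- function(generate, test, n_sims, seed = NULL)
  rejection_rate(generate, test, n_sims, seed)

#' Empirical power of a test under an effect generator
#' @inheritParams rejection_rate
#' @return Empirical rejection rate under the alternative.
#' @export
power_estimate <- function(generate, test, n_sims, seed = NULL)
  rejection_rate(generate, test, n_sims, seed)
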