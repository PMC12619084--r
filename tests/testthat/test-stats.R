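test_that("resampling test is degenerate-safe and seed-reproducible", {
  r <- resampling_mean_diff_test(rep(3, 5), rep(3, 4), seed = 1)
  expect_identical(r$observed_diff, 0)
  expect_false(r$reject)
  expect_true(r$ci_low <= 0 && 0 <= r$ci_high)
  a <- rnorm(9); b <- rnorm(5)
  r1 <- resampling_mean_diff_test(a, b, seed = 9)
  r2 <- resampling_mean_diff_test(a, b, seed = 9)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_identical(r1$reject, r2$reject)
  expect_error(resampling_mean_diff_test(1, rnorm(5)), "at least 2")
  expect_error(resampling_mean_diff_test(a, b, n_resamples = 50), "100")
})

test_that("a five-sigma mean shift is rejected, in agreement with Welch", {
  g <- simulate_metric_groups(50, 50, meanA = 0, meanB = 5, sd = 1,
                              seed = 11)
  r <- resampling_mean_diff_test(g$A, g$B, seed = 12)
  expect_true(r$reject)
  # independent oracle on the same data
  expect_lt(t.test(g$A, g$B)$p.value, 1e-3)
  expect_true(r$observed_diff < r$ci_low || r$observed_diff > r$ci_high)
})

test_that("label exchange flips the sign but not the decision", {
  g <- simulate_metric_groups(9, 5, meanA = 0, meanB = 1.5, sd = 1,
                              seed = 13)
  r_ab <- resampling_mean_diff_test(g$A, g$B, seed = 14)
  r_ba <- resampling_mean_diff_test(g$B, g$A, seed = 14)
  expect_equal(r_ab$observed_diff, -r_ba$observed_diff)
  expect_identical(r_ab$reject, r_ba$reject)
})

test_that("permutation mode behaves like the bootstrap at scale", {
  g <- simulate_metric_groups(20, 20, meanA = 0, meanB = 2, sd = 1,
                              seed = 15)
  rp <- resampling_mean_diff_test(g$A, g$B, mode = "permutation",
                                  n_resamples = 2000, seed = 16)
  expect_true(rp$reject)
  null <- simulate_metric_groups(10, 10, 0, 0, 1, seed = 17)
  rn <- resampling_mean_diff_test(null$A, null$B, mode = "permutation",
                                  n_resamples = 2000, seed = 18)
  expect_true(rn$ci_low < rn$ci_high)
})

test_that("KS statistic equals the double-loop brute force, ties included", {
  set.seed(41)
  for (i in 1:8) {
    n1 <- sample(3:50, 1); n2 <- sample(3:50, 1)
    x <- round(rnorm(n1), 1)   # rounding forces ties within and across
    y <- round(rnorm(n2, 0.4), 1)
    r <- ks_two_sample(x, y)
    expect_equal(r$D, brute_ks_D(x, y), tolerance = 1e-12)
    # cross-check with the stock implementation
    expect_equal(r$D, unname(suppressWarnings(
      stats::ks.test(x, y)$statistic)), tolerance = 1e-12)
  }
  same <- rnorm(10)
  r0 <- ks_two_sample(same, same)
  expect_identical(r0$D, 0)
  expect_identical(r0$p, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("asymptotic KS p stays within a factor two of exact enumeration", {
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5, sample(c(0, 1, 2), 1))
    r <- ks_two_sample(x, y)
    pe <- exact_perm_ks_p(x, y)
    expect_gt(r$p / pe, 0.5)
    expect_lt(r$p / pe, 2)
  }
  # and equals the stock asymptotic tail at larger n
  x <- rnorm(120); y <- rnorm(90, 0.3)
  expect_equal(ks_two_sample(x, y)$p,
               suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value),
               tolerance = 1e-9)
})

test_that("published-scale KS comparison lands at the right magnitude", {
  # D = 0.15 at event counts 778 vs 326: asymptotic tail of order 1e-5
  lambda <- sqrt(778 * 326 / (778 + 326)) * 0.15
  p <- srseize:::ks_asymptotic_p(lambda)
  expect_gt(p, 1e-6)
  expect_lt(p, 1e-4)
})

test_that("duplicated groups give F = 0 and p = 1", {
  x <- rep(seq(0, 100, by = 20), each = 3)
  set.seed(51)
  a <- data.frame(stimulus = x,
                  response = 60 / (1 + exp(-(x - 40) / 12)) + rnorm(length(x)))
  for (model in c("sigmoid3", "quadratic")) {
    r <- extra_ss_f_test(a, a, model = model)
    expect_lt(r$F, 1e-6)
    expect_gt(r$p, 0.999)
    expect_gte(r$ss_pooled, r$ss_separate - 1e-9)
    expect_identical(r$df_num, 3L)
  }
})

test_that("a three-fold plateau difference is detected by the sigmoid F test", {
  x <- rep(seq(0, 100, by = 10), each = 2)
  gen <- function(plateau, seed) {
    set.seed(seed)
    data.frame(stimulus = x,
               response = plateau / (1 + exp(-(x - 45) / 12)) +
                 rnorm(length(x), sd = 0.05 * plateau))
  }
  rejections <- sum(vapply(1:100, function(s) {
    r <- extra_ss_f_test(gen(60, s), gen(20, s + 1000), model = "sigmoid3")
    r$p < 0.01
  }, logical(1)))
  expect_gte(rejections, 95)
})

test_that("F-test p-values are uniform under the null", {
  x <- rep(seq(-2, 2, length.out = 7), each = 2)
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    mk <- function() data.frame(
      stimulus = x, response = 1 + 0.5 * x - 0.3 * x^2 + rnorm(length(x)))
    extra_ss_f_test(mk(), mk(), model = "quadratic")$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
})

test_that("rejection-rate harness counts correctly and power is monotone", {
  always <- function(data) TRUE
  expect_identical(rejection_rate(function(i) NULL, always, 100, seed = 1), 1)
  expect_error(rejection_rate(function(i) NULL, always, 50), "100")
  shifts <- c(0, 0.5, 1, 2)
  pw <- vapply(shifts, function(d) {
    power_estimate(
      generate = function(i) list(x = rnorm(9), y = rnorm(5, d)),
      test = function(g) resampling_mean_diff_test(g$x, g$y,
                                                   n_resamples = 1000),
      n_sims = 300, seed = 71)
  }, numeric(1))
  expect_true(all(diff(pw) > -0.02))
  expect_gt(pw[4], pw[1] + 0.3)
})
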