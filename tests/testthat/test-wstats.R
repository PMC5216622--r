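# Independent oracle: the weighted mean / SD formulas coded as plain loops,
# kept deliberately separate from the package implementation.
oracle_wmean <- function(x, w) {
  num <- 0; den <- 0
  for (i in seq_along(x)) { num <- num + x[i] * w[i]; den <- den + w[i] }
  num / den
}
oracle_wsd <- function(x, w, n_obs) {
  m <- oracle_wmean(x, w)
  num <- 0; den <- 0
  for (i in seq_along(x)) { num <- num + w[i] * (x[i] - m)^2; den <- den + w[i] }
  sqrt(num / den * n_obs / (n_obs - 1))
}

test_that("weighted mean handles equal weights, point masses and arithmetic", {
  expect_equal(wtd_mean(weighted_sample(c(10, 20), c(1, 1))), 15)
  expect_equal(wtd_mean(weighted_sample(c(10, 20), c(0, 5))), 20)
  expect_equal(wtd_mean(weighted_sample(c(10, 12, 20), c(0.15, 0.15, 0.70))), 17.3)
  # invariant to uniform weight rescaling
  s1 <- weighted_sample(c(3, 7, 11), c(1, 2, 3))
  s2 <- weighted_sample(c(3, 7, 11), c(10, 20, 30))
  expect_equal(wtd_mean(s1), wtd_mean(s2))
  expect_error(weighted_sample(c(1, 2), c(0, 0)), class = "paleosize_degenerate_error")
})

test_that("weighted SD matches the loop-coded oracle and the sample SD", {
  expect_equal(wtd_sd(weighted_sample(c(1, 3))), sqrt(2))
  expect_equal(wtd_sd(weighted_sample(rep(47.75, 5))), 0)
  # species-level sample: six cross-period species means with fixture weights
  cfg <- default_config()
  obs <- zero_sd_obs(with(cfg$specs, tibble::tibble(species, period, mean,
                                                    n = n_measured)))
  pooled <- species_pooled_means(obs)
  w <- species_weights(generate_assemblage(cfg), "warm")
  s <- weighted_sample(pooled[w$species], w$weight, n_obs = 6)
  expect_equal(wtd_sd(s), unname(oracle_wsd(pooled[w$species], w$weight, 6)))
  # property: random weighted samples agree with the oracle
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(10, 30, 5); wts <- runif(10)
    expect_equal(wtd_sd(weighted_sample(x, wts)), oracle_wsd(x, wts, 10))
    expect_equal(wtd_mean(weighted_sample(x, wts)), oracle_wmean(x, wts))
  }
})

test_that("uniform-weight statistics equal their unweighted counterparts", {
  set.seed(7)
  x <- rnorm(25, 35, 4)
  s <- weighted_sample(x, rep(0.3, 25))
  expect_equal(wtd_mean(s), mean(x))
  expect_equal(wtd_sd(s), sd(x))
})

test_that("standard error follows sd / sqrt(n_obs) at both levels", {
  expect_equal(round(wtd_se(5.97, 219), 2), 0.40)  # observation level
  expect_equal(round(wtd_se(6.60, 6), 2), 2.69)    # species level
  expect_equal(wtd_se(0, 17), 0)
})

test_that("Welch test agrees with stats::t.test and the hand formula", {
  set.seed(1)
  a <- rnorm(30, 47, 5); b <- rnorm(28, 51, 7)
  mine <- welch_test(a, b)
  ref <- t.test(b, a)  # oracle; same orientation (b - a)
  expect_equal(mine$t_statistic, unname(ref$statistic))
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p_value, ref$p.value)
  # identical samples: t = 0, p = 1
  same <- welch_test(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_test(rep(1, 3), rep(1, 3)), class = "paleosize_degenerate_error")
})

test_that("summary-statistic Welch route equals the raw-data route", {
  a <- make_sample(47.75, 5.75, 30)
  b <- make_sample(51.68, 7.28, 30)
  expect_equal(welch_test(a, b), welch_test_summary(47.75, 5.75, 30, 51.68, 7.28, 30),
               tolerance = 1e-10)
})

test_that("weighted Welch test reduces exactly to the unweighted test", {
  set.seed(2)
  a <- rnorm(20, 34, 4); b <- rnorm(24, 38, 4)
  ww <- weighted_welch_test(weighted_sample(a), weighted_sample(b))
  uw <- welch_test(a, b)
  expect_equal(ww, uw, tolerance = 1e-12)
  # b = a gives t = 0
  expect_equal(weighted_welch_test(weighted_sample(a), weighted_sample(a))$t_statistic, 0)
  # pooled df option
  wp <- weighted_welch_test(weighted_sample(a), weighted_sample(b), df_mode = "pooled")
  expect_equal(wp$df, 42)
})

test_that("p-values decrease monotonically in |t| at fixed df", {
  t_seq <- c(0.5, 1, 2, 3, 5)
  p <- 2 * pt(-abs(t_seq), df = 30)
  expect_true(all(diff(p) < 0))
  # same property through the weighted test: scale the mean difference up
  base <- make_sample(30, 3, 20)
  p_obs <- vapply(c(1, 2, 4), function(shift) {
    weighted_welch_test(weighted_sample(base), weighted_sample(base + shift))$p_value
  }, numeric(1))
  expect_true(all(diff(p_obs) < 0))
})

test_that("statistics are invariant to joint permutation of values and weights", {
  set.seed(3)
  x <- rnorm(15, 30, 5); w <- runif(15)
  perm <- sample(15)
  expect_equal(wtd_mean(weighted_sample(x, w)), wtd_mean(weighted_sample(x[perm], w[perm])))
  expect_equal(wtd_sd(weighted_sample(x, w)), wtd_sd(weighted_sample(x[perm], w[perm])))
  expect_true(wtd_mean(weighted_sample(x, w)) >= min(x))
  expect_true(wtd_mean(weighted_sample(x, w)) <= max(x))
})
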