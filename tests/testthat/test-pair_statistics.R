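test_that("null moments match closed forms and a permutation Monte Carlo", {
  # binary pair, T = 10, #A = 3, #B = 4: textbook hypergeometric moments
  a <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  b <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  m <- hypergeometric_moments(a, b, 0)
  expect_equal(m$mean, 1.2)
  expect_equal(m$variance, 0.56)
  expect_equal(m$effective_length, 10)

  # silent unit: zero mean and variance
  m0 <- hypergeometric_moments(integer(10), b, 0)
  expect_equal(m0$mean, 0)
  expect_equal(m0$variance, 0)

  # M = 2 toy with layer totals A = (2,1), B = (3,1): cross-layer terms
  a2 <- c(2, 1, rep(0, 8))
  b2 <- c(2, 1, 1, rep(0, 7))
  m2 <- hypergeometric_moments(a2, b2, 0)
  expect_equal(m2$mean, 0.7)
  expect_equal(m2$variance, (336 + 81 + 2 * 56) / 900)
  set.seed(31)
  mc <- perm_moments(a2, b2, 0, nrep = 2e4)
  expect_equal(mc$mean, m2$mean, tolerance = 0.05)
  expect_equal(mc$variance, m2$variance, tolerance = 0.06)
})

test_that("the variance reduces to the textbook hypergeometric form for binary series", {
  set.seed(32)
  for (rep in 1:20) {
    N <- sample(20:200, 1)
    nA <- sample.int(N - 1, 1)
    nB <- sample.int(N - 1, 1)
    a <- sample(c(rep(1L, nA), rep(0L, N - nA)))
    b <- sample(c(rep(1L, nB), rep(0L, N - nB)))
    v <- hypergeometric_moments(a, b, 0)$variance
    textbook <- nB * (nA / N) * (1 - nA / N) * (N - nB) / (N - 1)
    expect_equal(v, textbook, tolerance = 1e-12)
  }
})

test_that("the uncorrected standardized statistic follows from the moments", {
  a <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  b <- c(1, 1, 0, 1, 1, 0, 0, 0, 0, 0)  # overlap of 2 in bins 1-2
  s <- uncorrected_statistic(a, b, 0)
  expect_equal(s$statistic, (2 - 1.2) / sqrt(0.56))
  expect_equal(s$dof, 2 * 10 * 1 - 1)
  expect_error(uncorrected_statistic(integer(10), b, 0), "variance")
})

test_that("difference counts subtract the reference-lag count", {
  # #AB,1 = 5, #AB,-1 = 3 -> 2 (constructed series)
  a <- c(1, 1, 1, 1, 1, 1, 0, 0, 1, 0)
  expect_equal(difference_count(a, a, 1, -1), 0)  # symmetric by construction
  x <- c(1, 0, 1, 0, 1, 0, 1, 0)
  y <- c(0, 1, 0, 1, 0, 1, 0, 1)
  expect_equal(difference_count(x, y, 1, -1),
               joint_count(x, y, 1) - joint_count(x, y, -1))
  expect_error(difference_count(x, y, 1, 1), "differ")
  # synchrony case with l* = -2
  expect_equal(reference_lag_for(0), -2L)
  expect_equal(reference_lag_for(3), -3L)
  expect_equal(reference_lag_for(0, "fixed", l_max = 10), -11L)
})

test_that("segmented variance: single-segment identity and silent segments", {
  set.seed(33)
  a <- rbinom(400, 1, 0.2)
  b <- rbinom(400, 1, 0.2)
  v_global <- hypergeometric_moments(a, b, 0)$variance  # window = full series
  sv <- segmented_variance(a, b, 0, -2, k = 400)
  expect_equal(sv, 2 * v_global + 2 * v_global / 399, tolerance = 1e-12)

  # a fully silent stretch contributes nothing
  a2 <- c(a[1:100], integer(100))
  b2 <- c(b[1:100], integer(100))
  expect_equal(segmented_variance(a2, b2, 0, -2, k = 100),
               segmented_variance(a[1:100], b[1:100], 0, -2, k = 100))

  expect_error(segment_scheme(100, k = 1), "exceed")
  expect_error(segment_scheme(100, k = 3, lag = 5), "lag")
})

test_that("segmented variance matches the permutation-oracle variance of #ABBA", {
  set.seed(34)
  T <- 1000; lag <- 2
  a <- rbinom(T, 1, 0.15)
  b <- rbinom(T, 1, 0.15)
  est <- segmented_variance(a, b, lag, -lag, k = 100)
  nrep <- 1e4
  vals <- numeric(nrep)
  for (i in seq_len(nrep)) {
    ap <- sample(a); bp <- sample(b)
    vals[i] <- joint_count(ap, bp, lag) - joint_count(ap, bp, -lag)
  }
  expect_equal(mean(vals), 0, tolerance = 3 * sd(vals) / sqrt(nrep))
  expect_equal(est, var(vals), tolerance = 0.1 * var(vals))
})

test_that("the corrected pair test detects a delayed copy and gates sparse pairs", {
  set.seed(35)
  a <- rbinom(2000, 1, 0.2)
  b <- c(0L, a[-2000])  # copy delayed by one bin
  r <- pair_test(a, b, l_max = 5, corrected_alpha = 1e-4)
  expect_true(r$significant)
  expect_equal(r$selected_lag, 1L)
  expect_equal(r$reference_lag, -1L)
  expect_gt(r$Q, qf(0.999, 1, r$dof))

  # expected joint count at or below 4: approximations unreliable -> gated
  sp_a <- c(rep(1L, 5), rep(0L, 995))
  sp_b <- c(rep(1L, 5), rep(0L, 995))
  rs <- pair_test(sp_a, sp_b, l_max = 5)
  expect_false(rs$gate_passed)
  expect_false(rs$significant)
  expect_lte(rs$null_mean, 4)

  # zero variance with a non-zero difference must never be significant
  ones <- rep(1L, 10)
  bb <- c(0L, rep(1L, 9))
  rz <- pair_statistic(ones, bb, 1, -1, k = 10)
  expect_equal(rz$variance, 0)
  expect_false(rz$testable)
  expect_equal(rz$p_value, 1)
})

test_that("the difference count has null mean zero and Q is calibrated at a fixed lag", {
  set.seed(36)
  nrep <- 600; T <- 1000
  diffs <- numeric(nrep); pvals <- numeric(nrep)
  for (i in seq_len(nrep)) {
    a <- rbinom(T, 1, 0.05); b <- rbinom(T, 1, 0.05)
    res <- pair_statistic(a, b, 2, -2, k = 100)
    diffs[i] <- res$difference
    pvals[i] <- res$p_value
  }
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(nrep))
  frac <- mean(pvals <= 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})
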