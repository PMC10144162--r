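test_that("correlation matrix handles perfect, absent and degenerate correlation", {
  x <- rnorm(10) + 5
  C <- correlation_matrix(cbind(a = x, b = 2 * x + 1))
  expect_equal(C["a", "b"], 1)
  expect_equal(diag(C), c(a = 1, b = 1))

  set.seed(42)
  z <- matrix(rnorm(2e4), ncol = 2)
  expect_lt(abs(correlation_matrix(z)[1, 2]), 0.05)

  expect_error(correlation_matrix(cbind(a = x, flat = rep(5, 10))),
               "flat", class = "floralint_degenerate_trait_error")
  expect_error(correlation_matrix(cbind(x[1:2], x[1:2] * 2)),
               "3 individuals")
})

test_that("integration index matches closed forms", {
  # 8 perfectly collinear traits: eigenvalues {8, 0, ...}, variance = T
  x <- rnorm(30) + 10
  coll <- sapply(1:8, function(k) k * x + k)
  colnames(coll) <- floral_traits()
  res <- integration_index(coll)
  expect_equal(res$eigenvalues[1], 8, tolerance = 1e-8)
  expect_equal(sum(abs(res$eigenvalues[-1])), 0, tolerance = 1e-8)
  expect_equal(res$raw_variance, 8, tolerance = 1e-8)
  expect_equal(res$percent_INT, 100 * (8 - 7 / 30) / 8, tolerance = 1e-6)

  # exactly independent traits: all eigenvalues 1, corrected = -(T-1)/N
  iid <- exact_corr_data(30, diag(8))
  res0 <- integration_index(iid)
  expect_equal(res0$raw_variance, 0, tolerance = 1e-10)
  expect_equal(res0$corrected_INT, -7 / 30, tolerance = 1e-10)
  expect_true(res0$negative)

  # T = 3 equicorrelation 0.5: eigenvalues {2, 0.5, 0.5}, variance 0.75
  eq <- exact_corr_data(20, matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3))
  res5 <- integration_index(eq)
  expect_equal(sort(res5$eigenvalues), c(0.5, 0.5, 2), tolerance = 1e-8)
  expect_equal(res5$raw_variance, 0.75, tolerance = 1e-8)
  expect_error(integration_index(eq[, 1, drop = FALSE]), "2 traits")
})

test_that("eigenvalues of a correlation matrix conserve the trace", {
  set.seed(7)
  for (rep in 1:20) {
    T <- sample(3:10, 1)
    N <- sample(10:40, 1)
    x <- matrix(rnorm(N * T), N) %*% matrix(rnorm(T * T), T)
    res <- integration_index(x, apply_correction = FALSE)
    expect_equal(sum(res$eigenvalues), T, tolerance = 1e-8)
    expect_gte(min(res$eigenvalues), -1e-10)
    expect_gte(res$raw_variance, 0)
    expect_lte(res$raw_variance, T + 1e-8)
  }
})

test_that("raw eigenvalue variance of independent traits matches its exact expectation", {
  # with the sample-variance (divisor T-1) convention, E[raw] = T/(N-1);
  # the corrected index therefore keeps a small positive offset of
  # T/(N-1) - (T-1)/N, which the population-divisor option removes
  set.seed(11)
  T <- 8; N <- 30
  raws <- replicate(500, integration_index(
    matrix(rnorm(N * T), N))$raw_variance)
  expect_equal(mean(raws), T / (N - 1), tolerance = 0.015 * 3)
  set.seed(11)
  pop <- replicate(500, integration_index(
    matrix(rnorm(N * T), N), divisor = "population")$corrected_INT)
  expect_lt(abs(mean(pop)), 0.03)
})

test_that("percent integration increases with equicorrelation strength", {
  set.seed(21)
  rs <- c(0, 0.2, 0.4, 0.6, 0.8)
  means <- sapply(rs, function(r) {
    L <- chol(equicorr_test(8, r))
    mean(replicate(50, integration_index(
      matrix(rnorm(500 * 8), 500) %*% L)$percent_INT))
  })
  expect_true(all(diff(means) > 0))
})

test_that("bootstrap CIs are reproducible and degenerate under collinearity", {
  set.seed(3)
  x <- matrix(rnorm(30 * 8), 30) %*% chol(equicorr_test(8, 0.5))
  b1 <- bootstrap_integration(x, n_boot = 100, seed = 99)
  b2 <- bootstrap_integration(x, n_boot = 100, seed = 99)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_error(bootstrap_integration(x, n_boot = 0), "n_boot")

  base <- rnorm(30) + 10
  coll <- sapply(1:8, function(k) k * base)
  b3 <- bootstrap_integration(coll, n_boot = 50, seed = 1)
  max_pct <- 100 * (8 - 7 / 30) / 8
  expect_equal(b3$ci_low, max_pct, tolerance = 1e-8)
  expect_equal(b3$ci_high, max_pct, tolerance = 1e-8)
})

test_that("bootstrap CI covers the population percent integration", {
  T <- 8; r <- 0.6; N <- 30
  ev <- c(1 + (T - 1) * r, rep(1 - r, T - 1))
  pop_pct <- 100 * var(ev) / T
  set.seed(5)
  L <- chol(equicorr_test(T, r))
  hits <- replicate(100, {
    x <- matrix(rnorm(N * T), N) %*% L
    b <- bootstrap_integration(x, n_boot = 2000,
                               seed = sample.int(1e6, 1))
    b$ci_low <= pop_pct && pop_pct <= b$ci_high
  })
  expect_gte(mean(hits), 0.90)
})

test_that("percent integration respects its attainable bounds", {
  set.seed(31)
  for (rep in 1:20) {
    N <- sample(5:40, 1)
    x <- matrix(rnorm(N * 8), N) %*% matrix(rnorm(64), 8)
    res <- integration_index(x)
    expect_lte(res$percent_INT, 100 * (8 - 7 / N) / 8 + 1e-8)
  }
})
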