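test_that("marginal specs are moment-matched analytically for every family", {
  # closed-form moments recomputed independently from the solved parameters
  sp <- marginal_spec("normal", 1.3, 0.7)
  expect_equal(c(sp$par$mean, sp$par$sd), c(1.3, 0.7), tolerance = 1e-12)

  sp <- marginal_spec("lognormal", 2, 1.5)
  m <- exp(sp$par$meanlog + sp$par$sdlog^2 / 2)
  s <- m * sqrt(exp(sp$par$sdlog^2) - 1)
  expect_equal(c(m, s), c(2, 1.5), tolerance = 1e-10)

  sp <- marginal_spec("gamma", 3, 0.8)
  expect_equal(sp$par$shape / sp$par$rate, 3, tolerance = 1e-10)
  expect_equal(sqrt(sp$par$shape) / sp$par$rate, 0.8, tolerance = 1e-10)

  sp <- marginal_spec("bernoulli", 0.3)
  expect_equal(sp$par$prob, 0.3)

  sp <- marginal_spec("truncated-normal", 0.6, 0.3, lower = 0, upper = 2)
  mm <- popitc:::.truncnorm_moments(sp$par$mu, sp$par$s, 0, 2)
  expect_equal(unname(mm), c(0.6, 0.3), tolerance = 1e-6)

  expect_error(marginal_spec("lognormal", -1, 1), "mean > 0")
  expect_error(marginal_spec("bernoulli", 1.3), "\\[0, 1\\]")
})

test_that("copula with all-normal marginals equals direct MVN sampling", {
  k <- 3
  corr <- matrix(0.2, k, k); diag(corr) <- 1
  agg <- aggregate_data(theta = rep(0.6, k), sd = rep(0.4, k), corr = corr,
                        counts = matrix(c(90, 310, 95, 105), 2, 2))
  n <- 1e5
  pp <- copula_population(agg, n_star = n, seed = 11)
  # independent oracle: direct multivariate normal draws
  set.seed(12)
  direct <- MASS::mvrnorm(n, rep(0.6, k), diag(rep(0.4, k)) %*% corr %*% diag(rep(0.4, k)))
  for (j in 1:k) {
    ks <- suppressWarnings(ks.test(pp$x_star[, j], direct[, j]))
    expect_gt(ks$p.value, 0.001)
  }
  expect_lt(max(abs(cor(pp$x_star) - cor(direct))), 0.02)
  expect_lt(max(abs(colMeans(pp$x_star) - 0.6)), 3 * 0.4 / sqrt(n))
})

test_that("copula respects independence and CLT bounds at benchmark size", {
  agg_id <- aggregate_data(rep(0.6, 4), rep(0.4, 4), diag(4),
                           matrix(c(90, 310, 95, 105), 2, 2))
  pp <- copula_population(agg_id, n_star = 2e4, seed = 5)
  cc <- cor(pp$x_star)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.03)

  corr <- matrix(0.2, 4, 4); diag(corr) <- 1
  agg <- aggregate_data(rep(0.6, 4), rep(0.4, 4), corr,
                        matrix(c(90, 310, 95, 105), 2, 2))
  pp <- copula_population(agg, n_star = 1000, em_idx = c(3, 4), seed = 6)
  expect_equal(pp$n_star, 1000)
  expect_lt(max(abs(colMeans(pp$x_star) - 0.6)), 3 * 0.4 / sqrt(1000))
})

test_that("copula accepts mixed marginal families", {
  corr <- matrix(0.3, 2, 2); diag(corr) <- 1
  agg <- aggregate_data(c(2, 0.3), c(1, 0.46), corr,
                        matrix(c(90, 310, 95, 105), 2, 2))
  marg <- list(marginal_spec("gamma", 2, 1), marginal_spec("bernoulli", 0.3))
  pp <- copula_population(agg, marg, n_star = 5e4, seed = 7)
  expect_true(all(pp$x_star[, 1] > 0))
  expect_true(all(pp$x_star[, 2] %in% c(0, 1)))
  expect_lt(abs(mean(pp$x_star[, 1]) - 2), 0.02)
  expect_lt(abs(mean(pp$x_star[, 2]) - 0.3), 0.01)
  expect_gt(cor(pp$x_star)[1, 2], 0.1)   # dependence propagated
})

test_that("factorized simulation matches a forward-sampling oracle", {
  # symmetric logit with zero slope: proportion 1/2
  pp <- factorized_population(marginal_spec("normal", 0.6, 0.4),
                              list(conditional_spec(2, 1, alpha0 = 0,
                                                    alpha1 = 0)),
                              n_star = 2e4, seed = 1)
  expect_lt(abs(mean(pp$x_star[, 2]) - 0.5), 0.015)

  # positive slope: positive association with the root covariate
  pp <- factorized_population(marginal_spec("normal", 0.6, 0.4),
                              list(conditional_spec(2, 1, alpha0 = 0,
                                                    alpha1 = 2)),
                              n_star = 2e4, seed = 2)
  expect_gt(cor(pp$x_star[, 1], pp$x_star[, 2]), 0.1)

  # three-variable chain age -> c -> d against a subject-by-subject oracle
  n <- 1e5
  a0c <- -0.5; a1c <- 1.5; a0d <- 0.2; a1d <- c(0.8, -1.0)
  pp <- factorized_population(
    marginal_spec("normal", 0.6, 0.4),
    list(conditional_spec(2, 1, alpha0 = a0c, alpha1 = a1c,
                          centers = 0.6),
         conditional_spec(3, c(1, 2), alpha0 = a0d, alpha1 = a1d,
                          centers = c(0.6, 0.4))),
    n_star = n, seed = 3)
  set.seed(103)
  age <- rnorm(n, 0.6, 0.4)
  cc <- rbinom(n, 1, expit(a0c + a1c * (age - 0.6)))
  dd <- rbinom(n, 1, expit(a0d + a1d[1] * (age - 0.6) + a1d[2] * (cc - 0.4)))
  tol <- 4 / sqrt(n)
  expect_lt(abs(mean(pp$x_star[, 2]) - mean(cc)), 2 * tol)
  expect_lt(abs(mean(pp$x_star[, 3]) - mean(dd)), 2 * tol)
  expect_lt(abs(mean(pp$x_star[, 2] * pp$x_star[, 3]) - mean(cc * dd)), 2 * tol)
  expect_lt(abs(cor(pp$x_star[, 1], pp$x_star[, 2]) - cor(age, cc)), 0.02)

  # referencing a not-yet-simulated parent is an ordering error
  expect_error(
    factorized_population(marginal_spec("normal", 0, 1),
                          list(conditional_spec(2, 3, alpha0 = 0, alpha1 = 1)),
                          n_star = 10),
    "not-yet-simulated")
})
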