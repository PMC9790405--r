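test_that("Q-model recovers the generating coefficients at large N", {
  cfg <- scenario_config(n_ac = 1e5)
  ac <- simulate_trial(cfg, cfg$mu_ac, seed = 31)
  fit <- fit_q_model(ac)
  expect_true(fit$converged)
  truth <- c(-0.62, rep(-log(0.5), 4), log(0.17), rep(-log(0.67), 2))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$beta_hat - truth) < 3.5 * se))
})

test_that("duplicating every row leaves estimates unchanged and halves vcov", {
  ipd <- toy_ipd(n = 80, seed = 32)
  dup <- trial_ipd(ipd$x[rep(1:80, 2), ], ipd$z[rep(1:80, 2)],
                   ipd$y[rep(1:80, 2)], em_idx = attr(ipd, "em_idx"))
  f1 <- fit_q_model(ipd)
  f2 <- fit_q_model(dup)
  expect_equal(f1$beta_hat, f2$beta_hat, tolerance = 1e-8)
  expect_equal(f2$vcov, f1$vcov / 2, tolerance = 1e-6)
})

test_that("marginal means and contrast have their closed forms", {
  # null fit: everything 1/2
  fit <- structure(list(beta_hat = rep(0, 5), vcov = diag(5),
                        converged = TRUE, em_idx = 2L, k = 2L),
                   class = "q_model_fit")
  pp <- popitc:::.pseudo_population(matrix(rnorm(20), 10, 2), 2L)
  mm <- marginal_means(fit, pp)
  expect_equal(mm$mu1, 0.5)
  expect_equal(mm$mu0, 0.5)

  # single pseudo-subject, hand-computed expits
  beta <- c(0.1, 0.5, -0.3, -1.2, 0.4)   # b0, b1 (k=2), bz, b2 (em = col 2)
  fit2 <- structure(list(beta_hat = beta, vcov = diag(5), converged = TRUE,
                         em_idx = 2L, k = 2L), class = "q_model_fit")
  x1 <- matrix(c(0.7, -0.2), 1, 2)
  pp1 <- popitc:::.pseudo_population(x1, 2L)
  mm1 <- marginal_means(fit2, pp1)
  eta0 <- 0.1 + 0.5 * 0.7 + (-0.3) * (-0.2)
  eta1 <- eta0 - 1.2 + 0.4 * (-0.2)
  expect_equal(mm1$mu0, expit(eta0), tolerance = 1e-12)
  expect_equal(mm1$mu1, expit(eta1), tolerance = 1e-12)

  expect_equal(marginal_contrast(list(mu1 = 0.5, mu0 = 0.5)), 0)
  expect_equal(marginal_contrast(list(mu1 = 0.75, mu0 = 0.5)), log(3))
  expect_equal(marginal_contrast(list(mu1 = 0.5, mu0 = 0.75)), -log(3))
  expect_equal(marginal_or(list(mu1 = 0.75, mu0 = 0.5)), 3)
  expect_error(marginal_contrast(list(mu1 = 1, mu0 = 0.5)),
               class = "popitc_degenerate_estimate")
})

test_that("G-computation equals exhaustive post-stratification for a discrete covariate", {
  # one binary covariate, saturated logistic model: model-based
  # standardization must coincide with crude direct post-stratification
  set.seed(41)
  n <- 400
  x <- matrix(rbinom(n, 1, 0.4), n, 1)
  z <- rep(c(1L, 0L), n / 2)
  y <- rbinom(n, 1, plogis(-0.4 + 0.8 * x[, 1] + (-0.9 + 0.6 * x[, 1]) * z))
  ipd <- trial_ipd(x, z, y, em_idx = 1)
  fit <- fit_q_model(ipd)
  xs <- matrix(rbinom(500, 1, 0.7), 500, 1)
  pp <- popitc:::.pseudo_population(xs, 1L)
  mm <- marginal_means(fit, pp)
  # oracle: observed stratum event rates weighted by pseudo-population shares
  share1 <- mean(xs)
  rate <- function(g, arm) mean(y[x[, 1] == g & z == arm])
  mu1_ps <- share1 * rate(1, 1) + (1 - share1) * rate(0, 1)
  mu0_ps <- share1 * rate(1, 0) + (1 - share1) * rate(0, 0)
  expect_equal(mm$mu1, mu1_ps, tolerance = 1e-12)
  expect_equal(mm$mu0, mu0_ps, tolerance = 1e-12)
})

test_that("identity-link standardization collapses to the conditional contrast", {
  # on the linear predictor scale the average contrast is exactly
  # betaz + mean(x_EM) . beta2: standardization and conditioning coincide
  set.seed(43)
  xs <- matrix(rnorm(600, 0.6, 0.4), 200, 3)
  beta <- c(0.2, 0.3, -0.1, 0.25, -1.1, 0.5, -0.2)
  lp <- popitc:::.potential_lp(beta, xs, c(2L, 3L))
  expect_equal(mean(lp$eta1) - mean(lp$eta0),
               -1.1 + sum(colMeans(xs[, 2:3]) * c(0.5, -0.2)),
               tolerance = 1e-12)
})

test_that("marginal contrast is monotone in the treatment coefficient", {
  set.seed(44)
  xs <- matrix(rnorm(400, 0.6, 0.4), 200, 2)
  pp <- popitc:::.pseudo_population(xs, 2L)
  vals <- sapply(c(-1, -0.5, 0, 0.5, 1), function(bz) {
    fit <- structure(list(beta_hat = c(-0.3, 0.4, 0.2, bz, 0.3),
                          vcov = diag(5), converged = TRUE,
                          em_idx = 2L, k = 2L), class = "q_model_fit")
    marginal_contrast(marginal_means(fit, pp))
  })
  expect_true(all(diff(vals) > 0))
})

test_that("gcomp_ml_estimate is reproducible and supports both inference modes", {
  cfg <- scenario_config(n_ac = 200)
  ac <- simulate_trial(cfg, cfg$mu_ac, seed = 51)
  agg <- aggregate_trial(simulate_trial(cfg, cfg$mu_bc, n = 600, seed = 52))
  e1 <- gcomp_ml_estimate(ac, agg, n_boot = 60, seed = 53)
  e2 <- gcomp_ml_estimate(ac, agg, n_boot = 60, seed = 53)
  expect_identical(e1$estimate, e2$estimate)
  expect_identical(e1$se, e2$se)
  expect_identical(e1$scale, "marginal")
  em <- gcomp_ml_estimate(ac, agg, n_boot = 200, inference = "mvn-sim",
                          seed = 54)
  # the two inference routes approximate the same sampling distribution
  expect_lt(abs(em$se - e1$se) / e1$se, 0.6)
  eb <- gcomp_ml_estimate(ac, agg, n_boot = 60, point = "boot-mean", seed = 53)
  expect_identical(eb$se, e1$se)
  expect_equal(eb$meta$plug_in, e1$estimate)
})

test_that("covariate adjustment does not inflate variance under a collapsible null", {
  # no effect modification, identical populations: the standardized
  # estimate tracks the crude estimate replicate by replicate
  cfg <- scenario_config(n_ac = 400, mu_ac = 0.6, betaz = 0, beta2 = 0)
  diffs <- ses <- numeric(15)
  for (s in 1:15) {
    ac <- simulate_trial(cfg, cfg$mu_ac, seed = 700 + s)
    agg <- aggregate_trial(simulate_trial(cfg, cfg$mu_bc, n = 600, seed = 800 + s))
    g <- gcomp_ml_estimate(ac, agg, n_boot = 0, seed = s)
    crude <- weighted_marginal_logor(ac, rep(1, 400))
    diffs[s] <- g$estimate - crude
  }
  expect_lt(sd(diffs), 0.2)               # tightly coupled to the crude estimate
  expect_lt(abs(mean(diffs)), 0.1)
})
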