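test_that("already-balanced data need no adjustment", {
  set.seed(1)
  x <- matrix(rnorm(200), 100, 2)
  wts <- estimate_weights(x, colMeans(x))
  expect_equal(wts$alpha, c(0, 0), tolerance = 1e-7)
  expect_equal(wts$w, rep(1, 100), tolerance = 1e-6)
  expect_equal(wts$ess, 100, tolerance = 1e-6)
})

test_that("one-dimensional solution matches a grid-search oracle", {
  x <- matrix(c(0, 1, 2), 3, 1)
  theta <- 0.8
  wts <- estimate_weights(x, theta)
  expect_equal(sum(wts$w * x) / sum(wts$w), theta, tolerance = 1e-8)
  # brute-force oracle over the 1-D objective
  grid <- seq(-5, 5, by = 1e-4)
  obj <- vapply(grid, function(a) sum(exp((x - theta) * a)), numeric(1))
  expect_equal(wts$alpha, grid[which.min(obj)], tolerance = 2e-4)
})

test_that("aggregate means outside the observed hull are infeasible", {
  x <- matrix(c(0, 1), 2, 1)
  expect_error(estimate_weights(x, 2), class = "popitc_infeasible_weights")
  # multivariate: theta outside the hull along a direction, inside marginally
  x2 <- cbind(c(0, 1, 0.1), c(0, 1, 0.9))
  expect_error(estimate_weights(x2, c(0.9, 0.1)),
               class = "popitc_infeasible_weights")
})

test_that("balancing property and ESS bound hold across random problems", {
  set.seed(7)
  for (case in 1:25) {
    n <- sample(40:300, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p, 0, 0.5), n, p)
    theta <- colMeans(x) + runif(p, -0.2, 0.2)
    wts <- estimate_weights(x, theta)
    wbar <- colSums(wts$w * x) / sum(wts$w)
    expect_lt(max(abs(wbar - theta)), 1e-6)        # exact balance
    expect_lte(wts$ess, n + 1e-9)                  # ESS <= N
    if (max(abs(theta - colMeans(x))) > 1e-3) expect_lt(wts$ess, n)
  }
})

test_that("Newton solution agrees with quasi-Newton optim from random starts", {
  set.seed(11)
  x <- matrix(rnorm(300, 0.3, 0.4), 150, 2)
  theta <- c(0.45, 0.5)
  wts <- estimate_weights(x, theta)
  xc <- sweep(x, 2, theta)
  f <- function(a) sum(exp(drop(xc %*% a)))
  g <- function(a) drop(crossprod(xc, exp(drop(xc %*% a))))
  for (s in 1:5) {
    start <- rnorm(2, 0, 2)
    o <- optim(start, f, g, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
    expect_lt(max(abs(o$par - wts$alpha)), 1e-5)
  }
})

test_that("weighted marginal log-OR has its closed forms and invariances", {
  ipd <- toy_ipd(n = 120, seed = 9)
  n11 <- sum(ipd$y == 1 & ipd$z == 1); n01 <- sum(ipd$y == 0 & ipd$z == 1)
  n10 <- sum(ipd$y == 1 & ipd$z == 0); n00 <- sum(ipd$y == 0 & ipd$z == 0)
  expect_equal(weighted_marginal_logor(ipd, rep(1, 120)),
               log((n11 / n01) / (n10 / n00)))
  # scale invariance
  set.seed(2)
  w <- runif(120, 0.2, 3)
  expect_equal(weighted_marginal_logor(ipd, w),
               weighted_marginal_logor(ipd, 2 * w), tolerance = 1e-12)
  # agrees with a weighted logistic regression of y on z (independent route)
  gfit <- suppressWarnings(glm(ipd$y ~ ipd$z, weights = w, family = binomial()))
  expect_equal(weighted_marginal_logor(ipd, w), unname(coef(gfit)[2]),
               tolerance = 1e-8)
  # hand-computed 6-subject oracle
  toy <- trial_ipd(matrix(0, 6, 1), z = c(1L, 1L, 1L, 0L, 0L, 0L),
                   y = c(1L, 1L, 0L, 1L, 0L, 0L))
  w6 <- c(2, 1, 1, 1, 1, 2)
  p1 <- (2 * 1 + 1 * 1 + 1 * 0) / 4      # weighted event rate, active
  p0 <- (1 * 1 + 1 * 0 + 2 * 0) / 4      # weighted event rate, control
  expect_equal(weighted_marginal_logor(toy, w6),
               qlogis(p1) - qlogis(p0))
  # degenerate arm detection
  toy0 <- trial_ipd(matrix(0, 4, 1), z = c(1L, 1L, 0L, 0L),
                    y = c(1L, 1L, 1L, 0L))
  expect_error(weighted_marginal_logor(toy0, c(1, 1, 1, 1)),
               class = "popitc_degenerate_estimate")
})

test_that("maic_estimate reduces to the crude estimate under balance and is reproducible", {
  cfg <- scenario_config(n_ac = 300, mu_ac = 0.6)  # same population as BC
  ac <- simulate_trial(cfg, cfg$mu_ac, seed = 21)
  agg <- aggregate_trial(simulate_trial(cfg, cfg$mu_bc, n = 600, seed = 22))
  # force exact balance: aggregate means set to the AC sample means
  agg_bal <- aggregate_data(colMeans(ac$x), agg$sd, agg$corr, agg$counts)
  est <- maic_estimate(ac, agg_bal, n_boot = 0)
  expect_equal(est$estimate, weighted_marginal_logor(ac, rep(1, 300)),
               tolerance = 1e-7)
  expect_equal(est$meta$ess_reduction, 0, tolerance = 1e-5)

  e1 <- maic_estimate(ac, agg, n_boot = 100, seed = 33)
  e2 <- maic_estimate(ac, agg, n_boot = 100, seed = 33)
  expect_identical(e1$se, e2$se)
  expect_equal(e1$ci_high - e1$ci_low, 2 * 1.96 * e1$se)
  # boot-mean convention: point equals the bootstrap mean, not the plug-in
  e3 <- maic_estimate(ac, agg, n_boot = 100, point = "boot-mean", seed = 33)
  expect_identical(e3$se, e1$se)
  expect_false(identical(e3$estimate, e1$estimate))
  expect_equal(e3$meta$plug_in, e1$estimate)
})
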