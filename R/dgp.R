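#' Benchmark scenario configuration
#'
#' Parameters of the data-generating process used throughout the simulation
#' benchmark. Two trials are generated from the same outcome model: an
#' \emph{AC} trial (active treatment A vs common comparator C) whose IPD are
#' retained, and a \emph{BC} trial (active treatment B vs C) which is
#' aggregated before analysis. Subject-level covariates are multivariate
#' normal with exchangeable correlation; the binary outcome follows a
#' logistic model with prognostic main effects for all covariates and
#' treatment-by-covariate interactions for the effect modifiers. Both active
#' treatments share the same conditional effect and interaction
#' coefficients, so the true A-vs-B effect in the BC population is zero.
#'
#' The defaults encode the benchmark conditions: four covariates (the last
#' two effect-modifying), marginal SD 0.4, pairwise correlation 0.2, BC
#' covariate means 0.6, intercept \eqn{\beta_0 = -0.62} (35\% baseline event
#' rate), prognostic log-odds ratio \eqn{-\ln 0.5} per covariate (conditional
#' OR 2), interaction \eqn{-\ln 0.67} per effect modifier (conditional OR
#' about 1.5), and conditional treatment effect \eqn{\ln 0.17}. The AC
#' covariate means take one of 0.45 / 0.30 / 0.15, giving standardized
#' differences of 0.375 / 0.75 / 1.125 versus BC, i.e. strong, moderate and
#' poor covariate overlap.
#'
#' @param n_ac number of subjects in the AC trial (benchmark grid uses 200,
#'   400, 600; any positive integer is accepted).
#' @param n_bc number of subjects in the BC trial.
#' @param allocation active-to-control allocation ratio, as a length-2
#'   numeric vector \code{c(active, control)}.
#' @param k number of covariates.
#' @param em_idx integer indices of the effect-modifying covariates.
#' @param mu_ac scalar or length-\code{k} AC covariate means.
#' @param mu_bc scalar or length-\code{k} BC covariate means.
#' @param sigma scalar or length-\code{k} marginal covariate SD.
#' @param rho pairwise Pearson correlation between covariates.
#' @param beta0 outcome model intercept.
#' @param beta1 scalar or length-\code{k} prognostic coefficients.
#' @param beta2 scalar or length-\code{|em_idx|} interaction coefficients.
#' @param betaz conditional treatment coefficient, shared by A-vs-C and
#'   B-vs-C.
#'
#' @return An object of class \code{"scenario_config"}: a validated list of
#'   the above components with \code{mu_ac}, \code{mu_bc}, \code{sigma},
#'   \code{beta1}, \code{beta2} recycled to full length.
#' @examples
#' cfg <- scenario_config(n_ac = 200, mu_ac = 0.15)  # poor overlap
#' cfg$em_idx
#' @export
scenario_config <- function(n_ac = 600, n_bc = 600, allocation = c(2, 1),
                            k = 4, em_idx = c(3, 4),
                            mu_ac = 0.45, mu_bc = 0.6, sigma = 0.4,
                            rho = 0.2,
                            beta0 = -0.62, beta1 = -log(0.5),
                            beta2 = -log(0.67), betaz = log(0.17)) {
  stopifnot(.is_count(n_ac), .is_count(n_bc), .is_count(k))
  if (length(allocation) != 2L || any(allocation <= 0))
    stop("`allocation` must be a positive length-2 ratio c(active, control)",
         call. = FALSE)
  em_idx <- as.integer(em_idx)
  if (anyDuplicated(em_idx) || any(em_idx < 1L) || any(em_idx > k))
    stop("`em_idx` must be distinct indices in 1..k", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= -1 / (k - 1) || rho >= 1)
    stop("`rho` must give a positive-definite exchangeable correlation",
         call. = FALSE)
  rec <- function(v, len, nm) {
    if (length(v) == 1L) v <- rep(v, len)
    if (length(v) != len)
      stop(sprintf("`%s` must have length 1 or %d", nm, len), call. = FALSE)
    v
  }
  cfg <- list(
    n_ac = as.integer(n_ac), n_bc = as.integer(n_bc),
    allocation = allocation, k = as.integer(k), em_idx = em_idx,
    mu_ac = rec(mu_ac, k, "mu_ac"), mu_bc = rec(mu_bc, k, "mu_bc"),
    sigma = rec(sigma, k, "sigma"), rho = rho,
    beta0 = beta0, beta1 = rec(beta1, k, "beta1"),
    beta2 = rec(beta2, length(em_idx), "beta2"), betaz = betaz
  )
  if (any(cfg$sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
  .check_corr(.exch_corr(k, rho), "implied correlation matrix")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration\n")
  cat(sprintf("  AC trial: N = %d, covariate means %s\n", x$n_ac,
              paste(format(x$mu_ac), collapse = ", ")))
  cat(sprintf("  BC trial: N = %d, covariate means %s\n", x$n_bc,
              paste(format(x$mu_bc), collapse = ", ")))
  cat(sprintf("  K = %d covariates (SD %s, rho = %g); effect modifiers: %s\n",
              x$k, paste(format(x$sigma), collapse = ", "), x$rho,
              paste(x$em_idx, collapse = ", ")))
  cat(sprintf("  beta0 = %.4g, beta1 = %s, beta2 = %s, betaz = %.4g\n",
              x$beta0, paste(format(x$beta1, digits = 4), collapse = ", "),
              paste(format(x$beta2, digits = 4), collapse = ", "), x$betaz))
  invisible(x)
}

#' Trial individual patient data
#'
#' Container for subject-level trial data: an \eqn{N \times K} covariate
#' matrix, a binary treatment indicator (1 = active, 0 = common comparator)
#' and a binary outcome. Used for the AC trial IPD, and internally for the
#' simulated BC trial before aggregation.
#'
#' @param x numeric covariate matrix with one row per subject.
#' @param z binary treatment indicator of length \code{nrow(x)}.
#' @param y binary outcome of length \code{nrow(x)}.
#' @param em_idx optional integer indices of the effect-modifying columns of
#'   \code{x}; stored as an attribute and used as the default adjustment set
#'   by the estimation functions.
#' @return An object of class \code{"trial_ipd"}.
#' @examples
#' ipd <- trial_ipd(matrix(rnorm(20), 10, 2), z = rep(1:0, 5),
#'                  y = rbinom(10, 1, 0.4), em_idx = 2)
#' @export
trial_ipd <- function(x, z, y, em_idx = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  z <- as.integer(z)
  y <- as.integer(y)
  n <- nrow(x)
  if (length(z) != n || length(y) != n)
    stop("`z` and `y` must have one entry per row of `x`", call. = FALSE)
  if (anyNA(x) || anyNA(z) || anyNA(y))
    stop("trial IPD must not contain missing values", call. = FALSE)
  if (!all(z %in% c(0L, 1L)) || !all(y %in% c(0L, 1L)))
    stop("`z` and `y` must be binary (0/1)", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.null(em_idx)) {
    em_idx <- as.integer(em_idx)
    if (any(em_idx < 1L) || any(em_idx > ncol(x)))
      stop("`em_idx` out of range", call. = FALSE)
  }
  structure(list(x = x, z = z, y = y), em_idx = em_idx, class = "trial_ipd")
}

#' @export
print.trial_ipd <- function(x, ...) {
  cat(sprintf("Trial IPD: %d subjects, %d covariates (%d active / %d control), %d events\n",
              nrow(x$x), ncol(x$x), sum(x$z == 1L), sum(x$z == 0L), sum(x$y)))
  em <- attr(x, "em_idx")
  if (!is.null(em))
    cat(sprintf("  effect modifiers: %s\n", paste(colnames(x$x)[em], collapse = ", ")))
  invisible(x)
}

#' Simulate a two-arm trial from the benchmark outcome model
#'
#' Draws correlated normal covariates, assigns treatment deterministically by
#' the allocation ratio (the first \eqn{\lceil N \cdot a/(a+c) \rceil}
#' subjects receive the active treatment) and simulates Bernoulli outcomes
#' with success probability
#' \deqn{\mathrm{expit}(\beta_0 + x\beta_1 + (\beta_z + x^{EM}\beta_2)
#'   1[z = 1]).}
#' Covariate rows are exchangeable, so fixed allocation is equivalent in
#' distribution to randomized allocation with the arm sizes held fixed.
#'
#' @param config a [scenario_config()].
#' @param arm_means length-\code{k} covariate means for the trial being
#'   simulated (\code{config$mu_ac} for the AC trial, \code{config$mu_bc}
#'   for BC).
#' @param n number of subjects; defaults to \code{config$n_ac}.
#' @param seed optional integer seed for reproducibility.
#' @return A [trial_ipd()] with the effect-modifier indices of the
#'   configuration attached.
#' @examples
#' cfg <- scenario_config(n_ac = 300)
#' ac <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' bc <- simulate_trial(cfg, cfg$mu_bc, n = cfg$n_bc, seed = 2)
#' @export
simulate_trial <- function(config, arm_means, n = config$n_ac, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(arm_means) == 1L) arm_means <- rep(arm_means, config$k)
  stopifnot(length(arm_means) == config$k)
  if (!is.null(seed)) set.seed(seed)
  k <- config$k
  sig <- diag(config$sigma) %*% .exch_corr(k, config$rho) %*% diag(config$sigma)
  x <- .rmvnorm(n, arm_means, sig)
  colnames(x) <- paste0("x", seq_len(k))
  n_active <- ceiling(n * config$allocation[1] / sum(config$allocation))
  z <- rep(c(1L, 0L), c(n_active, n - n_active))
  eta <- config$beta0 + drop(x %*% config$beta1) +
    (config$betaz + drop(x[, config$em_idx, drop = FALSE] %*% config$beta2)) * z
  y <- stats::rbinom(n, 1L, .expit(eta))
  trial_ipd(x, z, y, em_idx = config$em_idx)
}

#' Aggregate-level trial data
#'
#' Summaries of a trial in the form published in a trial report: covariate
#' means and standard deviations, a covariate correlation matrix (by
#' convention borrowed from the IPD trial when the aggregate publication
#' does not report one), and the 2x2 events table by arm.
#'
#' @param theta length-K covariate means.
#' @param sd length-K covariate standard deviations (positive).
#' @param corr K x K correlation matrix (symmetric positive definite, unit
#'   diagonal).
#' @param counts 2 x 2 matrix of event / non-event counts with rows
#'   \code{c("events", "nonevents")} and columns \code{c("active",
#'   "control")}.
#' @return An object of class \code{"aggregate_data"} with \code{n_active}
#'   and \code{n_control} derived from the column sums of \code{counts}.
#' @seealso [aggregate_trial()] to build one from simulated IPD.
#' @examples
#' agg <- aggregate_data(theta = rep(0.6, 4), sd = rep(0.4, 4),
#'                       corr = diag(4),
#'                       counts = matrix(c(90, 310, 95, 105), 2, 2))
#' @export
aggregate_data <- function(theta, sd, corr, counts) {
  stopifnot(is.numeric(theta), is.numeric(sd), length(sd) == length(theta))
  if (any(sd <= 0)) stop("`sd` must be positive", call. = FALSE)
  corr <- as.matrix(corr)
  if (nrow(corr) != length(theta))
    stop("`corr` dimension must match `theta`", call. = FALSE)
  .check_corr(corr)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0))
    stop("`counts` must be a nonnegative 2x2 table", call. = FALSE)
  dimnames(counts) <- list(c("events", "nonevents"), c("active", "control"))
  structure(list(theta = as.numeric(theta), sd = as.numeric(sd), corr = corr,
                 counts = counts,
                 n_active = sum(counts[, "active"]),
                 n_control = sum(counts[, "control"])),
            class = "aggregate_data")
}

#' @export
print.aggregate_data <- function(x, ...) {
  cat(sprintf("Aggregate trial data: %d active / %d control subjects\n",
              x$n_active, x$n_control))
  cat("  covariate means:", paste(format(x$theta, digits = 4), collapse = ", "), "\n")
  cat("  covariate SDs:  ", paste(format(x$sd, digits = 4), collapse = ", "), "\n")
  cat("  events (active/control):", x$counts[1, 1], "/", x$counts[1, 2], "\n")
  invisible(x)
}

#' Aggregate a simulated trial to published-style summaries
#'
#' Reduces IPD to the information typically available from a trial
#' publication: sample covariate means and SDs, the sample correlation
#' matrix, and the 2x2 events table by arm.
#'
#' @param ipd a [trial_ipd()].
#' @return An [aggregate_data()] object.
#' @examples
#' cfg <- scenario_config()
#' bc <- simulate_trial(cfg, cfg$mu_bc, n = cfg$n_bc, seed = 7)
#' aggregate_trial(bc)
#' @export
aggregate_trial <- function(ipd) {
  stopifnot(inherits(ipd, "trial_ipd"))
  x <- ipd$x
  counts <- matrix(c(sum(ipd$y[ipd$z == 1L]), sum(ipd$z == 1L) - sum(ipd$y[ipd$z == 1L]),
                     sum(ipd$y[ipd$z == 0L]), sum(ipd$z == 0L) - sum(ipd$y[ipd$z == 0L])),
                   2, 2)
  aggregate_data(theta = colMeans(x), sd = apply(x, 2, stats::sd),
                 corr = stats::cor(x), counts = counts)
}

#' True marginal log-odds ratio by Monte Carlo standardization
#'
#' Computes the population-average (marginal) log-odds ratio of each active
#' treatment versus the common comparator in the BC population implied by a
#' scenario configuration. A large Monte Carlo sample of covariate vectors
#' is drawn from the BC covariate distribution; the true conditional outcome
#' model is averaged on the probability scale under active treatment and
#' under the comparator, and the means are contrasted on the logit scale.
#' Because the odds ratio is non-collapsible, this marginal value differs
#' from the conditional coefficient \code{betaz} whenever the covariates are
#' prognostic.
#'
#' @param config a [scenario_config()].
#' @param n_oracle Monte Carlo sample size (at least 1e6 recommended).
#' @param seed optional integer seed.
#' @return The marginal log-odds ratio (a scalar).
#' @examples
#' cfg <- scenario_config()
#' true_marginal_logor(cfg, n_oracle = 1e5, seed = 1)
#' @export
true_marginal_logor <- function(config, n_oracle = 2e6, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  k <- config$k
  sig <- diag(config$sigma) %*% .exch_corr(k, config$rho) %*% diag(config$sigma)
  # draw in blocks to bound memory at large n_oracle
  block <- 5e5L
  n_left <- as.integer(n_oracle)
  s1 <- s0 <- 0
  while (n_left > 0L) {
    m <- min(block, n_left)
    x <- .rmvnorm(m, config$mu_bc, sig)
    eta0 <- config$beta0 + drop(x %*% config$beta1)
    eta1 <- eta0 + config$betaz +
      drop(x[, config$em_idx, drop = FALSE] %*% config$beta2)
    s1 <- s1 + sum(.expit(eta1))
    s0 <- s0 + sum(.expit(eta0))
    n_left <- n_left - m
  }
  mu1 <- s1 / n_oracle
  mu0 <- s0 / n_oracle
  .logit(mu1) - .logit(mu0)
}

#' Overlap percentage of two equal-variance normal populations
#'
#' Cohen's overlapping-coefficient for two normal distributions of equal
#' size and equal variance whose means differ by \code{d} standard
#' deviations: \eqn{100 \cdot 2\Phi(-d/2)}. Used to express the degree of
#' covariate overlap implied by a standardized mean difference.
#'
#' @param d nonnegative standardized mean difference (Cohen's effect size).
#' @return Overlap as a percentage in \eqn{[0, 100]}.
#' @examples
#' cohen_overlap(c(0.375, 0.75, 1.125))  # approx 85, 71, 57
#' @export
cohen_overlap <- function(d) {
  if (any(d < 0)) stop("`d` must be nonnegative", call. = FALSE)
  100 * 2 * stats::pnorm(-d / 2)
}
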