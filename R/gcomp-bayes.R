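#' Normal prior specification for the Q-model coefficients
#'
#' Independent normal priors for the Bayesian Q-model. The default is
#' weakly informative: Normal(0, 10^2) on the intercept and
#' Normal(0, 1.15^2) on every slope, treatment and interaction coefficient.
#' A null-centered normal with SD 1.15 places just over 95\% of its mass
#' between conditional odds ratios of 0.1 and 10, encoding the contextual
#' judgement that larger conditional effects are unlikely in practice.
#'
#' @param location prior mean(s); scalar or per-coefficient vector.
#' @param scale prior SD(s); scalar or per-coefficient vector, or
#'   \code{NULL} to use \code{intercept_scale} / \code{slope_scale}.
#' @param intercept_scale prior SD of the intercept when \code{scale} is
#'   \code{NULL}.
#' @param slope_scale prior SD of all other coefficients when \code{scale}
#'   is \code{NULL}.
#' @return An object of class \code{"prior_spec"}.
#' @examples
#' prior_spec()                      # default weakly informative
#' prior_spec(scale = 2.5)           # common SD for all coefficients
#' @export
prior_spec <- function(location = 0, scale = NULL,
                       intercept_scale = 10, slope_scale = 1.15) {
  if (!is.null(scale) && any(scale <= 0)) stop("`scale` must be positive", call. = FALSE)
  if (intercept_scale <= 0 || slope_scale <= 0)
    stop("prior scales must be positive", call. = FALSE)
  structure(list(location = location, scale = scale,
                 intercept_scale = intercept_scale,
                 slope_scale = slope_scale),
            class = "prior_spec")
}

# expand a prior_spec to per-coefficient location/scale vectors of length p
.expand_priors <- function(priors, p) {
  loc <- rep_len(priors$location, p)
  sc <- if (is.null(priors$scale)) {
    c(priors$intercept_scale, rep(priors$slope_scale, p - 1L))
  } else rep_len(priors$scale, p)
  list(location = loc, scale = sc)
}

.jags_logistic_model <- "
model {
  for (n in 1:N) {
    y[n] ~ dbern(p[n])
    logit(p[n]) <- inprod(D[n, ], beta[])
  }
  for (j in 1:P) {
    beta[j] ~ dnorm(loc[j], prec[j])
  }
}"

#' Bayesian Q-model fit by MCMC
#'
#' Samples the posterior of the logistic Q-model coefficients (same linear
#' predictor as [fit_q_model()]) with independent normal priors, using JAGS
#' (Gibbs sampling with the \code{glm} block-sampling module). Convergence
#' is assessed with the split-chain potential scale reduction factor; a
#' value above 1.05 for any coefficient triggers a warning but the draws are
#' still returned.
#'
#' @param ipd a [trial_ipd()].
#' @param priors a [prior_spec()].
#' @param em_idx effect-modifier column indices; defaults to the indices
#'   attached to \code{ipd}.
#' @param chains number of MCMC chains.
#' @param iterations total iterations per chain, including warmup.
#' @param warmup warmup (adaptation + burn-in) iterations per chain,
#'   discarded.
#' @param seed optional integer seed (per-chain RNG seeds are derived from
#'   it).
#' @return An object of class \code{"posterior_draws"}: list with the
#'   L x P coefficient matrix \code{draws} (L = chains x (iterations -
#'   warmup), columns ordered as in [fit_q_model()]), a \code{diagnostics}
#'   data frame (per-coefficient \code{rhat} and chain \code{ess}),
#'   \code{converged}, \code{em_idx}, \code{k}.
#' @examples
#' \donttest{
#' cfg <- scenario_config(n_ac = 200)
#' ac <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' post <- fit_q_model_bayes(ac, iterations = 1000, warmup = 500, seed = 2)
#' post$diagnostics
#' }
#' @export
fit_q_model_bayes <- function(ipd, priors = prior_spec(),
                              em_idx = attr(ipd, "em_idx"),
                              chains = 2, iterations = 4000, warmup = 2000,
                              seed = NULL) {
  stopifnot(inherits(ipd, "trial_ipd"), inherits(priors, "prior_spec"))
  if (is.null(em_idx)) stop("`em_idx` is required", call. = FALSE)
  if (warmup >= iterations)
    stop("`warmup` must be smaller than `iterations`", call. = FALSE)
  d <- .q_design(ipd$x, ipd$z, em_idx)
  p <- ncol(d)
  pr <- .expand_priors(priors, p)
  if (!"glm" %in% rjags::list.modules()) rjags::load.module("glm", quiet = TRUE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max %/% 2L, 1L)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = seed + ch))
  n_adapt <- max(100L, floor(warmup / 2))
  jm <- rjags::jags.model(
    textConnection(.jags_logistic_model),
    data = list(y = ipd$y, D = d, N = nrow(d), P = p,
                loc = pr$location, prec = 1 / pr$scale^2),
    inits = inits, n.chains = chains, n.adapt = n_adapt, quiet = TRUE)
  stats::update(jm, warmup - n_adapt, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "beta", n.iter = iterations - warmup,
                              progress.bar = "none")
  draws <- as.matrix(samp)
  colnames(draws) <- colnames(d)
  rhat <- if (chains >= 2) {
    coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1]
  } else rep(NA_real_, p)
  ess <- coda::effectiveSize(samp)
  converged <- !(chains >= 2 && any(rhat > 1.05, na.rm = TRUE))
  if (!converged)
    warning("MCMC convergence diagnostic above 1.05 for some coefficients",
            call. = FALSE)
  structure(list(draws = draws,
                 diagnostics = data.frame(coefficient = colnames(d),
                                          rhat = unname(rhat),
                                          ess = unname(ess)),
                 converged = converged,
                 em_idx = as.integer(em_idx), k = ncol(ipd$x)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: L = %d, %d coefficients (%s)\n",
              nrow(x$draws), ncol(x$draws),
              if (x$converged) "converged" else "convergence flagged"))
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' Per-draw marginal contrasts by posterior-predictive imputation
#'
#' For each posterior draw \eqn{l} of the Q-model coefficients, computes the
#' conditional outcome probabilities for every pseudo-population subject
#' under active treatment and under the comparator, imputes binary potential
#' outcomes by Bernoulli sampling from those probabilities (draws from the
#' posterior predictive distribution), averages the imputed outcomes per
#' arm, and contrasts the arm means on the logit scale:
#' \deqn{\hat\Delta^{(l)} = g\Big(\frac{1}{N^*}\sum_i y^{*(l)}_{1,i}\Big) -
#'       g\Big(\frac{1}{N^*}\sum_i y^{*(l)}_{0,i}\Big).}
#' A draw whose imputed arm is all events or all non-events receives a
#' Haldane-Anscombe correction (0.5 added to the arm's event and non-event
#' counts) and is counted in the \code{"n_degenerate"} attribute.
#'
#' @param draws a [fit_q_model_bayes()] result.
#' @param pseudo a pseudo-population of matching dimension.
#' @param seed optional integer seed for the Bernoulli imputation.
#' @return Numeric vector of length L of per-draw marginal log-odds ratios,
#'   with attribute \code{n_degenerate}.
#' @examples
#' \donttest{
#' cfg <- scenario_config(n_ac = 200)
#' ac <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' agg <- aggregate_trial(simulate_trial(cfg, cfg$mu_bc, n = 600, seed = 2))
#' pp <- copula_population(agg, n_star = 500, em_idx = cfg$em_idx, seed = 3)
#' post <- fit_q_model_bayes(ac, iterations = 1000, warmup = 500, seed = 4)
#' contrasts <- posterior_marginal_contrasts(post, pp, seed = 5)
#' mean(contrasts)
#' }
#' @export
posterior_marginal_contrasts <- function(draws, pseudo, seed = NULL) {
  stopifnot(inherits(draws, "posterior_draws"),
            inherits(pseudo, "pseudo_population"))
  if (ncol(pseudo$x_star) != draws$k)
    stop("pseudo-population dimension does not match the posterior draws",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  b <- draws$draws
  l <- nrow(b)
  n_star <- pseudo$n_star
  k <- draws$k
  em <- draws$em_idx
  # potential-outcome design matrices: everyone treated / everyone control
  d1 <- cbind(1, pseudo$x_star, 1, pseudo$x_star[, em, drop = FALSE])
  d0 <- cbind(1, pseudo$x_star, 0,
              matrix(0, n_star, length(em)))
  p1 <- .expit(d1 %*% t(b))          # N* x L conditional probabilities
  p0 <- .expit(d0 %*% t(b))
  y1 <- stats::rbinom(length(p1), 1L, p1)   # posterior-predictive imputation
  y0 <- stats::rbinom(length(p0), 1L, p0)
  e1 <- colSums(matrix(y1, n_star, l))
  e0 <- colSums(matrix(y0, n_star, l))
  degen <- e1 == 0L | e1 == n_star | e0 == 0L | e0 == n_star
  # Haldane-Anscombe correction on degenerate imputed arms
  num1 <- ifelse(e1 == 0L | e1 == n_star, e1 + 0.5, e1)
  den1 <- ifelse(e1 == 0L | e1 == n_star, n_star + 1, n_star)
  num0 <- ifelse(e0 == 0L | e0 == n_star, e0 + 0.5, e0)
  den0 <- ifelse(e0 == 0L | e0 == n_star, n_star + 1, n_star)
  out <- .logit(num1 / den1) - .logit(num0 / den0)
  attr(out, "n_degenerate") <- sum(degen)
  out
}

#' Bayesian parametric G-computation for A vs C
#'
#' The Bayesian counterpart of [gcomp_ml_estimate()]: the Q-model posterior
#' is sampled by MCMC ([fit_q_model_bayes()]), a Gaussian-copula
#' pseudo-population is simulated once from the aggregate summaries, and
#' per-draw marginal contrasts are obtained by posterior-predictive outcome
#' imputation ([posterior_marginal_contrasts()]). The point estimate is the
#' posterior mean of the contrasts, the standard error their posterior SD,
#' and the reported 95\% interval is Wald-type (matching the downstream
#' normal combination of the anchored comparison); the percentile (credible)
#' interval is kept in \code{meta$ci_percentile}.
#'
#' @inheritParams fit_q_model_bayes
#' @param agg an [aggregate_data()] for the BC trial.
#' @param n_star pseudo-population size.
#' @return An [itc_estimate()] on the marginal scale with \code{meta}
#'   fields \code{n_degenerate_draws}, \code{diagnostics},
#'   \code{ci_percentile}.
#' @examples
#' \donttest{
#' cfg <- scenario_config(n_ac = 200)
#' ac <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' bc <- aggregate_trial(simulate_trial(cfg, cfg$mu_bc, n = 600, seed = 2))
#' gcomp_bayes_estimate(ac, bc, iterations = 1000, warmup = 500, seed = 3)
#' }
#' @export
gcomp_bayes_estimate <- function(ipd, agg, priors = prior_spec(),
                                 em_idx = attr(ipd, "em_idx"),
                                 chains = 2, iterations = 4000,
                                 warmup = 2000, n_star = 1000, seed = NULL) {
  stopifnot(inherits(ipd, "trial_ipd"), inherits(agg, "aggregate_data"))
  if (is.null(em_idx)) stop("`em_idx` is required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pseudo <- copula_population(agg, n_star = n_star, em_idx = em_idx)
  mcmc_seed <- sample.int(.Machine$integer.max %/% 2L, 1L)
  post <- fit_q_model_bayes(ipd, priors, em_idx, chains = chains,
                            iterations = iterations, warmup = warmup,
                            seed = mcmc_seed)
  contrasts <- posterior_marginal_contrasts(post, pseudo)
  est <- mean(contrasts)
  se <- stats::sd(contrasts)
  itc_estimate(est, se, "marginal", "gcomp-bayes",
               meta = list(
                 n_degenerate_draws = attr(contrasts, "n_degenerate"),
                 diagnostics = post$diagnostics,
                 converged = post$converged,
                 ci_percentile = unname(stats::quantile(contrasts,
                                                        c(0.025, 0.975)))))
}
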