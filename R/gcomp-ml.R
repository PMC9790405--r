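#' Fit the Q-model (covariate-adjusted outcome regression)
#'
#' Maximum-likelihood logistic regression of outcome on the uncentered
#' covariates, treatment, and treatment-by-effect-modifier interactions:
#' \deqn{g(\mu_n) = \beta_0 + x_n\beta_1 +
#'   (\beta_z + x^{EM}_n\beta_2) 1[z_n = 1].}
#' In G-computation this regression is a nuisance model: its conditional
#' coefficients are not of direct interest but are used to predict potential
#' outcomes in the target pseudo-population.
#'
#' @param ipd a [trial_ipd()] with both arms present.
#' @param em_idx effect-modifier column indices; defaults to the indices
#'   attached to \code{ipd}.
#' @return An object of class \code{"q_model_fit"}: list with
#'   \code{beta_hat} (order: intercept, K prognostic terms, treatment,
#'   |EM| interactions), \code{vcov}, \code{converged}, \code{em_idx},
#'   \code{k}.
#' @examples
#' cfg <- scenario_config(n_ac = 400)
#' ac <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' fit_q_model(ac)
#' @export
fit_q_model <- function(ipd, em_idx = attr(ipd, "em_idx")) {
  stopifnot(inherits(ipd, "trial_ipd"))
  if (is.null(em_idx)) stop("`em_idx` is required", call. = FALSE)
  if (length(unique(ipd$z)) < 2L)
    stop("both treatment arms must be present", call. = FALSE)
  d <- .q_design(ipd$x, ipd$z, em_idx)
  fit <- .logistic_fit(d, ipd$y)
  structure(list(beta_hat = fit$beta, vcov = fit$vcov,
                 converged = fit$converged,
                 em_idx = as.integer(em_idx), k = ncol(ipd$x)),
            class = "q_model_fit")
}

#' @export
print.q_model_fit <- function(x, ...) {
  cat(sprintf("Q-model fit (logistic): %d coefficients, %s\n",
              length(x$beta_hat),
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$beta_hat, 4))
  invisible(x)
}

# linear predictors of a coefficient vector over a pseudo-population,
# under active treatment and under the comparator; beta ordered as in
# fit_q_model. Returns a list(eta1, eta0).
.potential_lp <- function(beta, x_star, em_idx) {
  k <- ncol(x_star)
  b0 <- beta[1]
  b1 <- beta[2:(k + 1)]
  bz <- beta[k + 2]
  b2 <- beta[(k + 3):(k + 2 + length(em_idx))]
  eta0 <- b0 + drop(x_star %*% b1)
  eta1 <- eta0 + bz + drop(x_star[, em_idx, drop = FALSE] %*% b2)
  list(eta1 = eta1, eta0 = eta0)
}

#' Marginal mean potential outcomes by standardization
#'
#' Averages the Q-model's predicted outcome probabilities over the
#' pseudo-population, once with every simulated subject set to the active
#' treatment and once with everyone set to the comparator:
#' \deqn{\hat\mu_1 = \frac{1}{N^*}\sum_i g^{-1}(\hat\beta_0 +
#'   x^*_i\hat\beta_1 + \hat\beta_z + x^{*EM}_i\hat\beta_2), \qquad
#'   \hat\mu_0 = \frac{1}{N^*}\sum_i g^{-1}(\hat\beta_0 + x^*_i\hat\beta_1).}
#' The computation is deterministic given the fit and the pseudo-population.
#'
#' @param fit a [fit_q_model()] result (need not have converged, but a
#'   warning-free analysis requires it).
#' @param pseudo a pseudo-population from [copula_population()] or
#'   [factorized_population()], with compatible dimension.
#' @return A list of class \code{"marginal_means"} with \code{mu1} and
#'   \code{mu0} on the probability scale.
#' @examples
#' cfg <- scenario_config(n_ac = 400)
#' ac <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' agg <- aggregate_trial(simulate_trial(cfg, cfg$mu_bc, n = 600, seed = 2))
#' pp <- copula_population(agg, n_star = 1000, em_idx = cfg$em_idx, seed = 3)
#' marginal_means(fit_q_model(ac), pp)
#' @export
marginal_means <- function(fit, pseudo) {
  stopifnot(inherits(fit, "q_model_fit"), inherits(pseudo, "pseudo_population"))
  if (ncol(pseudo$x_star) != fit$k)
    stop("pseudo-population dimension does not match the Q-model", call. = FALSE)
  lp <- .potential_lp(fit$beta_hat, pseudo$x_star, fit$em_idx)
  structure(list(mu1 = mean(.expit(lp$eta1)), mu0 = mean(.expit(lp$eta0))),
            class = "marginal_means")
}

#' @export
print.marginal_means <- function(x, ...) {
  cat(sprintf("Marginal mean outcomes: mu1 = %.4f (active), mu0 = %.4f (comparator)\n",
              x$mu1, x$mu0))
  invisible(x)
}

#' Marginal treatment-effect contrast on the linear predictor scale
#'
#' Back-transforms the marginal mean outcomes to the linear predictor scale
#' and contrasts them: \eqn{\hat\Delta = g(\hat\mu_1) - g(\hat\mu_0)}, the
#' marginal log-odds ratio for the logit link.
#'
#' @param m a [marginal_means()] result (or any list with \code{mu1},
#'   \code{mu0} in (0, 1)).
#' @return The marginal log-odds ratio (scalar).
#' @examples
#' marginal_contrast(list(mu1 = 0.75, mu0 = 0.5))  # log(3)
#' @export
marginal_contrast <- function(m) {
  if (!all(is.finite(c(m$mu1, m$mu0))) ||
      m$mu1 <= 0 || m$mu1 >= 1 || m$mu0 <= 0 || m$mu0 >= 1)
    stop(structure(class = c("popitc_degenerate_estimate", "error", "condition"),
                   list(message = "marginal means must lie strictly in (0, 1)",
                        call = NULL)))
  .logit(m$mu1) - .logit(m$mu0)
}

#' @rdname marginal_contrast
#' @return \code{marginal_or()} returns the marginal odds ratio
#'   \eqn{[\hat\mu_1/(1-\hat\mu_1)] / [\hat\mu_0/(1-\hat\mu_0)]}.
#' @export
marginal_or <- function(m) exp(marginal_contrast(m))

#' Maximum-likelihood parametric G-computation for A vs C
#'
#' Marginalizes the covariate-adjusted A-vs-C effect into the aggregate
#' trial's population: the Q-model ([fit_q_model()]) is fitted to the AC
#' IPD, a Gaussian-copula pseudo-population with normal marginals
#' moment-matched to the aggregate summaries is simulated once
#' ([copula_population()]), and the fitted model's predictions are
#' standardized over it ([marginal_means()], [marginal_contrast()]).
#'
#' Inference is by ordinary non-parametric bootstrap: whole rows of the AC
#' IPD are resampled, the Q-model is refitted per resample, and the contrast
#' is recomputed over the \emph{fixed} pseudo-population (only the IPD are
#' resampled; the target population definition is held constant). The SE is
#' the SD of the bootstrap contrasts and the 95\% interval is Wald-type
#' (percentile bounds are also reported in \code{meta}). Alternatively,
#' \code{inference = "mvn-sim"} simulates coefficient vectors from the
#' asymptotic multivariate normal distribution of the ML fit instead of
#' resampling.
#'
#' @param ipd a [trial_ipd()] for the AC trial.
#' @param agg an [aggregate_data()] for the BC trial.
#' @param em_idx effect-modifier column indices; defaults to the indices
#'   attached to \code{ipd}.
#' @param n_star pseudo-population size.
#' @param n_boot bootstrap resamples (or MVN simulation draws); 0 skips
#'   inference.
#' @param inference \code{"bootstrap"} (default) or \code{"mvn-sim"}.
#' @param point \code{"plug-in"} (default) reports the full-sample
#'   standardized contrast as the point estimate; \code{"boot-mean"}
#'   reports the mean of the bootstrap (or MVN-simulation) distribution
#'   instead.
#' @param seed optional integer seed (pseudo-population and resampling).
#' @return An [itc_estimate()] on the marginal scale with \code{meta}
#'   fields \code{mu1}, \code{mu0}, \code{n_boot_failed},
#'   \code{ci_percentile}.
#' @examples
#' cfg <- scenario_config(n_ac = 200)
#' ac <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' bc <- aggregate_trial(simulate_trial(cfg, cfg$mu_bc, n = 600, seed = 2))
#' gcomp_ml_estimate(ac, bc, n_boot = 50, seed = 3)
#' @export
gcomp_ml_estimate <- function(ipd, agg, em_idx = attr(ipd, "em_idx"),
                              n_star = 1000, n_boot = 1000,
                              inference = c("bootstrap", "mvn-sim"),
                              point = c("plug-in", "boot-mean"),
                              seed = NULL) {
  stopifnot(inherits(ipd, "trial_ipd"), inherits(agg, "aggregate_data"))
  inference <- match.arg(inference)
  point <- match.arg(point)
  if (point == "boot-mean" && n_boot < 2)
    stop("`point = \"boot-mean\"` requires `n_boot >= 2`", call. = FALSE)
  if (is.null(em_idx)) stop("`em_idx` is required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pseudo <- copula_population(agg, n_star = n_star, em_idx = em_idx)
  fit <- fit_q_model(ipd, em_idx)
  if (!fit$converged)
    stop(structure(class = c("popitc_nonconverged_fit", "error", "condition"),
                   list(message = "Q-model fit did not converge (possible separation)",
                        call = NULL)))
  mm <- marginal_means(fit, pseudo)
  est <- marginal_contrast(mm)
  se <- NA_real_
  n_failed <- 0L
  ci_pct <- c(NA_real_, NA_real_)
  if (n_boot >= 2) {
    draws <- numeric(n_boot)
    if (inference == "bootstrap") {
      n <- length(ipd$y)
      d_full <- .q_design(ipd$x, ipd$z, em_idx)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        bfit <- .logistic_fit(d_full[idx, , drop = FALSE], ipd$y[idx])
        draws[b] <- if (!bfit$converged) NA_real_ else tryCatch({
          lp <- .potential_lp(bfit$beta, pseudo$x_star, em_idx)
          marginal_contrast(list(mu1 = mean(.expit(lp$eta1)),
                                 mu0 = mean(.expit(lp$eta0))))
        }, popitc_degenerate_estimate = function(e) NA_real_)
      }
    } else {
      bdraws <- .rmvnorm(n_boot, fit$beta_hat, fit$vcov)
      for (b in seq_len(n_boot)) {
        lp <- .potential_lp(bdraws[b, ], pseudo$x_star, em_idx)
        draws[b] <- marginal_contrast(list(mu1 = mean(.expit(lp$eta1)),
                                           mu0 = mean(.expit(lp$eta0))))
      }
    }
    ok <- !is.na(draws)
    n_failed <- sum(!ok)
    if (sum(ok) < 2)
      stop("fewer than two successful bootstrap resamples", call. = FALSE)
    se <- stats::sd(draws[ok])
    ci_pct <- unname(stats::quantile(draws[ok], c(0.025, 0.975)))
    if (point == "boot-mean") est <- mean(draws[ok])
  }
  itc_estimate(est, se, "marginal", paste0("gcomp-ml/", inference),
               meta = list(mu1 = mm$mu1, mu0 = mm$mu0, point = point,
                           plug_in = marginal_contrast(mm),
                           n_boot = n_boot, n_boot_failed = n_failed,
                           ci_percentile = ci_pct))
}
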