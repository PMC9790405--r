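# logistic ML fit on a prebuilt design matrix; returns coef, vcov, converged
.logistic_fit <- function(d, y, max_iter = 100L) {
  fit <- suppressWarnings(
    stats::glm.fit(d, y, family = stats::binomial(),
                   control = list(maxit = max_iter))
  )
  # separation heuristic: fitted probabilities numerically at 0/1 with huge
  # coefficients make the information matrix singular
  w <- fit$weights
  xw <- d * w
  info <- crossprod(d, xw)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  converged <- fit$converged && !is.null(vc) &&
    all(is.finite(fit$coefficients)) && max(abs(fit$coefficients)) < 50
  list(beta = fit$coefficients,
       vcov = if (is.null(vc)) matrix(NA_real_, ncol(d), ncol(d)) else vc,
       converged = converged)
}

# design matrix of the covariate-adjusted outcome model:
# intercept | x (K prognostic terms) | z | z * x_em (interactions)
.q_design <- function(x, z, em_idx, center = NULL, center_em = NULL) {
  if (!is.null(center)) x <- sweep(x, 2, center)
  xem <- x[, em_idx, drop = FALSE]
  # when interactions are centered at a different point than the prognostic
  # terms (not used by default), shift the EM columns accordingly
  if (!is.null(center_em) && !is.null(center))
    xem <- sweep(xem, 2, center_em - center[em_idx])
  d <- cbind(1, x, z, xem * z)
  colnames(d) <- c("(intercept)", colnames(x), "z",
                   paste0(colnames(x)[em_idx], ":z"))
  d
}

#' Conventional simulated treatment comparison (STC)
#'
#' The conventional outcome-regression adjustment: a maximum-likelihood
#' logistic regression is fitted to the AC IPD with every covariate centered
#' at the aggregate-trial means \eqn{\theta},
#' \deqn{g(\mu_n) = \beta_0 + (x_n - \theta)\beta_1 +
#'   \{\beta_z + (x^{EM}_n - \theta^{EM})\beta_2\} 1[z_n = 1],}
#' and the treatment coefficient \eqn{\hat\beta_z} is returned with its
#' model-based standard error. Because the coefficient is conditional on the
#' adjustment covariates, the estimate carries scale tag
#' \code{"conditional"}: with a non-collapsible effect measure such as the
#' odds ratio it does not target the marginal estimand required by the
#' anchored comparison, and [bucher_combine()] will warn when it is used.
#' The method is included as the benchmark's negative control.
#'
#' One shared centering is applied to both arms (arm-specific centering
#' would break randomization).
#'
#' @param ipd a [trial_ipd()] for the AC trial.
#' @param theta length-K centering values, normally the aggregate-trial
#'   covariate means (an [aggregate_data()] may be passed directly).
#' @param em_idx effect-modifier column indices; defaults to the indices
#'   attached to \code{ipd}.
#' @return An [itc_estimate()] on the conditional scale; \code{meta} holds
#'   the full coefficient vector, covariance matrix and convergence flag.
#'   Non-convergence (e.g. separation) raises an error of class
#'   \code{"popitc_nonconverged_fit"}.
#' @examples
#' cfg <- scenario_config(n_ac = 400)
#' ac <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' stc_estimate(ac, theta = cfg$mu_bc)
#' @export
stc_estimate <- function(ipd, theta, em_idx = attr(ipd, "em_idx")) {
  stopifnot(inherits(ipd, "trial_ipd"))
  if (inherits(theta, "aggregate_data")) theta <- theta$theta
  if (is.null(em_idx)) stop("`em_idx` is required", call. = FALSE)
  stopifnot(length(theta) == ncol(ipd$x))
  d <- .q_design(ipd$x, ipd$z, em_idx, center = theta)
  fit <- .logistic_fit(d, ipd$y)
  if (!fit$converged)
    stop(structure(class = c("popitc_nonconverged_fit", "error", "condition"),
                   list(message = "STC outcome regression did not converge (possible separation)",
                        call = NULL)))
  j <- ncol(ipd$x) + 2L   # position of the treatment main effect
  itc_estimate(fit$beta[j], sqrt(fit$vcov[j, j]), "conditional", "stc",
               meta = list(beta = fit$beta, vcov = fit$vcov,
                           converged = fit$converged))
}
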