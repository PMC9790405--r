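#' Method-of-moments MAIC weights
#'
#' Estimates matching-adjusted indirect comparison weights for the pooled
#' (both arms) IPD so that the weighted effect-modifier means equal the
#' aggregate-trial means. The weight model is logistic in the trial-selection
#' odds; its coefficients solve the convex program
#' \deqn{\min_\alpha \sum_n \exp\{(x^{EM}_n - \theta^{EM}) \alpha\},}
#' whose first-order condition is exact balance of the weighted
#' effect-modifier means. The weights are
#' \eqn{w_n = \exp\{(x^{EM}_n - \theta^{EM})\hat\alpha\}} (normalized to sum
#' to the sample size for reporting; all downstream estimates are invariant
#' to normalization).
#'
#' When an aggregate mean lies outside the convex hull of the observed
#' effect-modifier values the objective decreases without bound and no
#' feasible weighting solution exists; this is detected (diverging
#' \eqn{\|\alpha\|}) and raised as an error of class
#' \code{"popitc_infeasible_weights"} so a simulation harness can count the
#' failure.
#'
#' @param x_em N x |EM| matrix of effect-modifier values for the pooled
#'   trial arms.
#' @param theta_em length-|EM| aggregate-trial effect-modifier means.
#' @param tol convergence tolerance on the balance residual (weighted mean
#'   deviation from \code{theta_em}).
#' @param max_iter maximum Newton iterations.
#' @return An object of class \code{"maic_weights"}: list with coefficient
#'   vector \code{alpha}, normalized weights \code{w}, effective sample size
#'   \code{ess} \eqn{= (\sum w)^2 / \sum w^2}, and the balance residual.
#' @examples
#' x <- matrix(rnorm(200, 0.3, 0.4), 100, 2)
#' wts <- estimate_weights(x, theta_em = c(0.5, 0.5))
#' wts$ess
#' @export
estimate_weights <- function(x_em, theta_em, tol = 1e-11, max_iter = 100L) {
  x_em <- as.matrix(x_em)
  stopifnot(length(theta_em) == ncol(x_em))
  xc <- sweep(x_em, 2, theta_em)
  n <- nrow(xc)
  p <- ncol(xc)
  alpha <- rep(0, p)
  # damped Newton on the strictly convex objective sum(exp(xc %*% alpha))
  obj <- function(a) sum(exp(drop(xc %*% a)))
  f <- obj(alpha)
  for (it in seq_len(max_iter)) {
    w <- exp(drop(xc %*% alpha))
    g <- drop(crossprod(xc, w))
    bal <- g / sum(w)                    # weighted mean deviation from theta
    if (max(abs(bal)) < tol) break
    h <- crossprod(xc, xc * w)
    step <- tryCatch(solve(h, g), error = function(e) g / max(diag(h)))
    lam <- 1
    repeat {
      cand <- alpha - lam * step
      fc <- obj(cand)
      if (is.finite(fc) && fc <= f) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    alpha <- alpha - lam * step
    f <- obj(alpha)
    if (!all(is.finite(alpha)) || sqrt(sum(alpha^2)) > 100)
      stop(structure(class = c("popitc_infeasible_weights", "error", "condition"),
                     list(message = "no feasible weighting solution: aggregate effect-modifier means lie outside the observed covariate space",
                          call = NULL)))
  }
  w <- exp(drop(xc %*% alpha))
  bal <- drop(crossprod(xc, w)) / sum(w)
  if (max(abs(bal)) > 1e-6)
    stop(structure(class = c("popitc_infeasible_weights", "error", "condition"),
                   list(message = "weight estimation did not converge to balance",
                        call = NULL)))
  w <- w * n / sum(w)
  structure(list(alpha = alpha, w = w, ess = sum(w)^2 / sum(w^2),
                 balance = bal, iterations = it),
            class = "maic_weights")
}

#' @export
print.maic_weights <- function(x, ...) {
  cat(sprintf("MAIC weights: N = %d, ESS = %.1f (%.1f%% reduction)\n",
              length(x$w), x$ess, 100 * (1 - x$ess / length(x$w))))
  cat("  alpha:", paste(format(x$alpha, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Weighted marginal log-odds ratio of a trial
#'
#' The treatment coefficient of a weighted logistic regression of outcome on
#' treatment alone, which equals the log of the weighted odds ratio
#' \eqn{\log\{\tilde p_1/(1-\tilde p_1)\} - \log\{\tilde p_0/(1-\tilde p_0)\}}
#' with \eqn{\tilde p_z} the weighted event proportion in arm \eqn{z}. With
#' unit weights this is the crude marginal log-odds ratio. The estimate is
#' invariant to rescaling the weights.
#'
#' @param ipd a [trial_ipd()].
#' @param w nonnegative weights aligned with the IPD rows (a numeric vector
#'   or a [estimate_weights()] result).
#' @return The weighted marginal log-odds ratio (scalar).
#' @examples
#' cfg <- scenario_config(n_ac = 300)
#' ipd <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' weighted_marginal_logor(ipd, rep(1, 300))
#' @export
weighted_marginal_logor <- function(ipd, w) {
  stopifnot(inherits(ipd, "trial_ipd"))
  if (inherits(w, "maic_weights")) w <- w$w
  if (length(w) != length(ipd$y) || any(w < 0))
    stop("`w` must be nonnegative weights aligned with the IPD rows",
         call. = FALSE)
  a <- ipd$z == 1L
  s1 <- sum(w[a])
  s0 <- sum(w[!a])
  if (s1 <= 0 || s0 <= 0)
    stop(structure(class = c("popitc_degenerate_estimate", "error", "condition"),
                   list(message = "an arm has zero total weight", call = NULL)))
  p1 <- sum(w[a] * ipd$y[a]) / s1
  p0 <- sum(w[!a] * ipd$y[!a]) / s0
  if (p1 <= 0 || p1 >= 1 || p0 <= 0 || p0 >= 1)
    stop(structure(class = c("popitc_degenerate_estimate", "error", "condition"),
                   list(message = "weighted event proportion of 0 or 1 in an arm",
                        call = NULL)))
  .logit(p1) - .logit(p0)
}

#' Matching-adjusted indirect comparison of A vs C
#'
#' Full MAIC analysis of the IPD trial against the aggregate trial's
#' effect-modifier means: method-of-moments weights ([estimate_weights()]),
#' weighted marginal log-odds ratio for A vs C, and a bootstrap standard
#' error from ordinary non-parametric resampling of whole IPD rows
#' (covariates, treatment and outcome jointly), with the weights
#' re-estimated within every resample. Resamples in which weight estimation
#' is infeasible or the weighted estimate is degenerate are dropped from the
#' bootstrap distribution and counted in \code{meta$n_boot_failed}.
#'
#' @param ipd a [trial_ipd()] for the AC trial.
#' @param agg an [aggregate_data()] for the BC trial.
#' @param em_idx effect-modifier column indices; defaults to the indices
#'   attached to \code{ipd}.
#' @param n_boot number of bootstrap resamples (0 skips inference and
#'   returns the point estimate with \code{se = NA}).
#' @param point \code{"plug-in"} (default) reports the full-sample weighted
#'   estimate as the point estimate; \code{"boot-mean"} reports the mean of
#'   the bootstrap distribution instead (the convention of some published
#'   implementations; it folds the bootstrap bias estimate into the point
#'   estimate and requires \code{n_boot >= 2}).
#' @param seed optional integer seed for the bootstrap.
#' @return An [itc_estimate()] on the marginal scale, with \code{meta}
#'   fields \code{ess}, \code{ess_reduction}, \code{alpha},
#'   \code{n_boot_failed}, \code{plug_in} (the full-sample estimate).
#' @examples
#' cfg <- scenario_config(n_ac = 200, mu_ac = 0.3)
#' ac <- simulate_trial(cfg, cfg$mu_ac, seed = 1)
#' bc <- aggregate_trial(simulate_trial(cfg, cfg$mu_bc, n = 600, seed = 2))
#' maic_estimate(ac, bc, n_boot = 50, seed = 3)
#' @export
maic_estimate <- function(ipd, agg, em_idx = attr(ipd, "em_idx"),
                          n_boot = 1000, point = c("plug-in", "boot-mean"),
                          seed = NULL) {
  stopifnot(inherits(ipd, "trial_ipd"), inherits(agg, "aggregate_data"))
  point <- match.arg(point)
  if (is.null(em_idx)) stop("`em_idx` is required", call. = FALSE)
  if (point == "boot-mean" && n_boot < 2)
    stop("`point = \"boot-mean\"` requires `n_boot >= 2`", call. = FALSE)
  theta_em <- agg$theta[em_idx]
  x_em <- ipd$x[, em_idx, drop = FALSE]
  wts <- estimate_weights(x_em, theta_em)   # propagates infeasibility
  est <- weighted_marginal_logor(ipd, wts$w)
  n <- length(ipd$y)
  se <- NA_real_
  n_failed <- 0L
  if (n_boot >= 2) {
    if (!is.null(seed)) set.seed(seed)
    boot <- numeric(n_boot)
    a <- ipd$z == 1L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot[b] <- tryCatch({
        bw <- estimate_weights(x_em[idx, , drop = FALSE], theta_em)$w
        ba <- a[idx]
        by <- ipd$y[idx]
        p1 <- sum(bw[ba] * by[ba]) / sum(bw[ba])
        p0 <- sum(bw[!ba] * by[!ba]) / sum(bw[!ba])
        if (!is.finite(p1) || !is.finite(p0) ||
            p1 <= 0 || p1 >= 1 || p0 <= 0 || p0 >= 1) NA_real_
        else .logit(p1) - .logit(p0)
      }, popitc_infeasible_weights = function(e) NA_real_)
    }
    ok <- !is.na(boot)
    n_failed <- sum(!ok)
    if (sum(ok) < 2)
      stop("fewer than two successful bootstrap resamples", call. = FALSE)
    se <- stats::sd(boot[ok])
    if (point == "boot-mean") est <- mean(boot[ok])
  }
  itc_estimate(est, se, "marginal", "maic",
               meta = list(ess = wts$ess,
                           ess_reduction = 100 * (1 - wts$ess / n),
                           alpha = wts$alpha, point = point,
                           plug_in = weighted_marginal_logor(ipd, wts$w),
                           n_boot = n_boot, n_boot_failed = n_failed))
}
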