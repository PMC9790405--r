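#' Benchmark scenario grid
#'
#' The nine-scenario grid crossing the AC trial size with the degree of
#' covariate overlap (AC covariate means 0.45 / 0.30 / 0.15 against BC
#' means of 0.6, i.e. strong / moderate / poor overlap).
#'
#' @param n_ac AC sample sizes to cross.
#' @param mu_ac AC covariate mean settings to cross.
#' @param ... further arguments passed to [scenario_config()].
#' @return Named list of [scenario_config()] objects; names look like
#'   \code{"N200_mu0.15"}.
#' @examples
#' names(benchmark_scenarios())
#' @export
benchmark_scenarios <- function(n_ac = c(200, 400, 600),
                                mu_ac = c(0.45, 0.30, 0.15), ...) {
  grid <- expand.grid(n_ac = n_ac, mu_ac = mu_ac)
  out <- lapply(seq_len(nrow(grid)), function(i)
    scenario_config(n_ac = grid$n_ac[i], mu_ac = grid$mu_ac[i], ...))
  names(out) <- sprintf("N%d_mu%.2f", grid$n_ac, grid$mu_ac)
  out
}

# run one method on one simulated dataset; returns list(est, status)
.run_method <- function(method, ac, agg_bc, n_boot, n_star, chains,
                        iterations, warmup, point, seed) {
  tryCatch({
    est <- switch(method,
      maic = maic_estimate(ac, agg_bc, n_boot = n_boot, point = point,
                           seed = seed),
      stc = stc_estimate(ac, agg_bc),
      `gcomp-ml` = gcomp_ml_estimate(ac, agg_bc, n_star = n_star,
                                     n_boot = n_boot, point = point,
                                     seed = seed),
      `gcomp-bayes` = gcomp_bayes_estimate(ac, agg_bc, chains = chains,
                                           iterations = iterations,
                                           warmup = warmup,
                                           n_star = n_star, seed = seed),
      bucher = bc_marginal_logor(aggregate_trial(ac)),
      stop("unknown method: ", method))
    list(est = est, status = "ok")
  },
  popitc_infeasible_weights = function(e) list(est = NULL, status = "infeasible"),
  popitc_nonconverged_fit = function(e) list(est = NULL, status = "non-converged"),
  popitc_degenerate_estimate = function(e) list(est = NULL, status = "degenerate"))
}

#' Run the simulation study
#'
#' ADEMP-style harness: for each scenario and Monte Carlo replicate, an AC
#' IPD trial and a BC trial are simulated from the scenario's
#' data-generating process, the BC trial is reduced to aggregate summaries,
#' every requested method estimates the A-vs-C effect on the identical
#' simulated data, and each is combined with the count-based B-vs-C
#' estimate via [bucher_combine()]. Replicates where a method fails
#' (infeasible MAIC weights, non-convergence, degenerate estimates) are
#' recorded with a status and excluded from performance summaries.
#'
#' Each replicate uses the derived seed \code{base_seed + scenario_index *
#' 100000 + replicate}, and each method within a replicate a further fixed
#' offset, so results are independent of execution order and any subset of
#' scenarios or replicates is exactly reproducible.
#'
#' @param methods character vector among \code{"maic"}, \code{"stc"},
#'   \code{"gcomp-ml"}, \code{"gcomp-bayes"}, \code{"bucher"} (the
#'   unadjusted anchored comparison).
#' @param scenarios named list of [scenario_config()] objects (e.g. from
#'   [benchmark_scenarios()]).
#' @param n_reps Monte Carlo replicates per scenario.
#' @param base_seed integer base seed.
#' @param n_boot bootstrap resamples for MAIC / ML G-computation (0 for
#'   point estimates only).
#' @param n_star pseudo-population size for G-computation.
#' @param chains,iterations,warmup MCMC settings for Bayesian
#'   G-computation.
#' @param point point-estimate convention for MAIC and ML G-computation
#'   when bootstrapping (see [maic_estimate()]); ignored with
#'   \code{n_boot = 0}.
#' @param progress print a line per scenario.
#' @return A data frame of class \code{"replicate_results"} with columns
#'   \code{scenario}, \code{method}, \code{rep}, \code{estimate},
#'   \code{se}, \code{ci_low}, \code{ci_high}, \code{status}, \code{seed}.
#' @examples
#' res <- run_study(c("maic", "stc"),
#'                  benchmark_scenarios(n_ac = 200, mu_ac = 0.3),
#'                  n_reps = 5, base_seed = 1, n_boot = 0)
#' performance_metrics(res)
#' @export
run_study <- function(methods, scenarios, n_reps, base_seed = 1,
                      n_boot = 1000, n_star = 1000,
                      chains = 2, iterations = 4000, warmup = 2000,
                      point = c("plug-in", "boot-mean"),
                      progress = FALSE) {
  methods <- match.arg(methods,
                       c("maic", "stc", "gcomp-ml", "gcomp-bayes", "bucher"),
                       several.ok = TRUE)
  point <- match.arg(point)
  stopifnot(n_reps >= 1, is.list(scenarios))
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  rows <- vector("list", length(scenarios) * n_reps * length(methods))
  ri <- 0L
  for (s in seq_along(scenarios)) {
    cfg <- scenarios[[s]]
    if (progress)
      message(sprintf("scenario %s (%d replicates)", names(scenarios)[s], n_reps))
    for (r in seq_len(n_reps)) {
      rep_seed <- as.integer(base_seed + s * 100000L + r)
      set.seed(rep_seed)
      ac <- simulate_trial(cfg, cfg$mu_ac)
      bc <- simulate_trial(cfg, cfg$mu_bc, n = cfg$n_bc)
      agg_bc <- aggregate_trial(bc)
      bc_est <- bc_marginal_logor(agg_bc)
      for (m in seq_along(methods)) {
        res <- .run_method(methods[m], ac, agg_bc, n_boot, n_star,
                           chains, iterations, warmup, point,
                           seed = rep_seed + 7919L * m)
        ri <- ri + 1L
        if (res$status == "ok") {
          cmp <- suppressWarnings(bucher_combine(res$est, bc_est))
          rows[[ri]] <- data.frame(
            scenario = names(scenarios)[s], method = methods[m], rep = r,
            estimate = cmp$delta_ab, se = cmp$se,
            ci_low = cmp$ci_low, ci_high = cmp$ci_high,
            status = "ok", seed = rep_seed)
        } else {
          rows[[ri]] <- data.frame(
            scenario = names(scenarios)[s], method = methods[m], rep = r,
            estimate = NA_real_, se = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_,
            status = res$status, seed = rep_seed)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("replicate_results", "data.frame")
  out
}

#' Performance measures with Monte Carlo standard errors
#'
#' Summarizes replicate-level estimates per scenario and method with the
#' standard simulation-study measures: bias (mean estimate minus truth),
#' empirical standard error (ESE, the SD of the estimates), mean square
#' error, variability ratio (average model SE / ESE), empirical coverage of
#' the 95\% intervals, and standardized bias (100 * bias / ESE). Each
#' measure carries its Monte Carlo standard error:
#' \code{mcse_bias = ese/sqrt(n)}, \code{mcse_ese = ese/sqrt(2(n-1))},
#' \code{mcse_coverage = sqrt(c(1-c)/n)}, and for the MSE the SD of the
#' squared errors over \code{sqrt(n)}. A leave-one-out influence
#' diagnostic for the variability ratio (\code{vr_influence}, the largest
#' absolute change in VR when a single replicate is removed) is reported so
#' that single-outlier distortion is visible without silently removing
#' anything.
#'
#' Replicates whose status is not \code{"ok"} are excluded and counted in
#' \code{n_failed}.
#'
#' @param results a [run_study()] result (or a data frame with the same
#'   columns).
#' @param truth true effect; 0 for the benchmark A-vs-B comparison.
#' @return A data frame of class \code{"performance_table"} with one row
#'   per scenario x method.
#' @export
performance_metrics <- function(results, truth = 0) {
  stopifnot(all(c("scenario", "method", "estimate", "status") %in% names(results)))
  cells <- split(results, list(results$scenario, results$method), drop = TRUE)
  out <- lapply(cells, function(cell) {
    ok <- cell[cell$status == "ok" & !is.na(cell$estimate), ]
    n <- nrow(ok)
    base <- data.frame(scenario = cell$scenario[1], method = cell$method[1],
                       n_used = n, n_failed = nrow(cell) - n)
    if (n < 2) {
      return(cbind(base, bias = NA_real_, mcse_bias = NA_real_,
                   ese = NA_real_, mcse_ese = NA_real_,
                   mse = NA_real_, mcse_mse = NA_real_,
                   variability_ratio = NA_real_, vr_influence = NA_real_,
                   coverage = NA_real_, mcse_coverage = NA_real_,
                   standardized_bias_pct = NA_real_))
    }
    e <- ok$estimate
    bias <- mean(e) - truth
    ese <- stats::sd(e)
    sqerr <- (e - truth)^2
    mse <- mean(sqerr)
    have_se <- !anyNA(ok$se)
    vr <- if (have_se) mean(ok$se) / ese else NA_real_
    vr_infl <- if (have_se) {
      # exact leave-one-out VR for each replicate
      sum_se <- sum(ok$se); sum_e <- sum(e); sum_e2 <- sum(e^2)
      mean_loo <- (sum_se - ok$se) / (n - 1)
      m_loo <- (sum_e - e) / (n - 1)
      var_loo <- (sum_e2 - e^2 - (n - 1) * m_loo^2) / (n - 2)
      max(abs(mean_loo / sqrt(var_loo) - vr))
    } else NA_real_
    cov <- if (have_se) mean(ok$ci_low <= truth & truth <= ok$ci_high) else NA_real_
    cbind(base,
          bias = bias, mcse_bias = ese / sqrt(n),
          ese = ese, mcse_ese = ese / sqrt(2 * (n - 1)),
          mse = mse, mcse_mse = stats::sd(sqerr) / sqrt(n),
          variability_ratio = vr, vr_influence = vr_infl,
          coverage = cov,
          mcse_coverage = if (have_se) sqrt(cov * (1 - cov) / n) else NA_real_,
          standardized_bias_pct = 100 * bias / ese)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("performance_table", "data.frame")
  out
}
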