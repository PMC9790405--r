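#' Treatment-effect estimate with standard error
#'
#' Container for a log-odds ratio estimate with its standard error, Wald
#' 95\% interval, and a scale tag recording whether the estimand is marginal
#' (population-average) or conditional. The scale tag is what allows the
#' anchored comparison to warn when a conditional estimate is combined with
#' a marginal one, which targets an incompatible estimand.
#'
#' @param estimate log-odds ratio point estimate.
#' @param se nonnegative standard error (may be \code{NA} when inference was
#'   not performed).
#' @param scale \code{"marginal"} or \code{"conditional"}.
#' @param method short label of the producing method.
#' @param meta optional named list of method details (ESS, failure counts,
#'   seed, ...).
#' @return An object of class \code{"itc_estimate"} with elements
#'   \code{estimate}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{scale}, \code{method}, \code{meta}.
#' @examples
#' itc_estimate(-1.2, 0.3, "marginal", "maic")
#' @export
itc_estimate <- function(estimate, se, scale = c("marginal", "conditional"),
                         method = "", meta = list()) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(estimate), length(estimate) == 1L)
  estimate <- unname(estimate)
  se <- unname(se)
  if (!is.na(se) && se < 0) stop("`se` must be nonnegative", call. = FALSE)
  structure(list(estimate = estimate, se = se,
                 ci_low = estimate - 1.96 * se,
                 ci_high = estimate + 1.96 * se,
                 scale = scale, method = method, meta = meta),
            class = "itc_estimate")
}

#' @export
print.itc_estimate <- function(x, ...) {
  lab <- paste0(toupper(substr(x$scale, 1, 1)), substring(x$scale, 2))
  cat(sprintf("%s log-OR estimate%s: %.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
              lab,
              if (nzchar(x$method)) paste0(" [", x$method, "]") else "",
              x$estimate, x$se, x$ci_low, x$ci_high))
  invisible(x)
}

#' Marginal B-vs-C log-odds ratio from aggregate event counts
#'
#' The unadjusted marginal log-odds ratio of the aggregate-data trial,
#' computed directly from the cells of its 2x2 events table, with the
#' delta-method standard error
#' \eqn{\sqrt{1/y_B + 1/(n_B - y_B) + 1/y_C + 1/(n_C - y_C)}}.
#' Any zero cell triggers a Haldane-Anscombe continuity correction (0.5
#' added to all four cells) and is flagged in \code{meta$continuity}.
#'
#' @param counts a 2x2 matrix of event / non-event counts by arm (rows
#'   events/nonevents, columns active/control), or an [aggregate_data()]
#'   whose \code{counts} are used.
#' @return An [itc_estimate()] on the marginal scale.
#' @examples
#' bc_marginal_logor(matrix(c(120, 280, 70, 130), 2, 2))
#' @export
bc_marginal_logor <- function(counts) {
  if (inherits(counts, "aggregate_data")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0))
    stop("`counts` must be a nonnegative 2x2 table", call. = FALSE)
  continuity <- any(counts == 0)
  if (continuity) counts <- counts + 0.5
  est <- log((counts[1, 1] / counts[2, 1]) / (counts[1, 2] / counts[2, 2]))
  se <- sqrt(sum(1 / counts))
  itc_estimate(est, se, "marginal", "counts",
               meta = list(continuity = continuity))
}

#' Anchored (Bucher) indirect comparison
#'
#' Combines the A-vs-C estimate (mapped into the BC population by one of the
#' adjustment methods) with the B-vs-C estimate from the aggregate trial:
#' \eqn{\hat\Delta_{AB} = \hat\Delta_{AC} - \hat\Delta_{BC}}. The two
#' estimates come from different trials and are treated as statistically
#' independent, so their variances are summed, and a Wald 95\% interval
#' \eqn{\hat\Delta_{AB} \pm 1.96\sqrt{\hat V}} is formed. If either input
#' is on the conditional scale a warning is issued: conditional and
#' marginal log-odds ratios are different estimands and combining them
#' produces an incompatible comparison.
#'
#' @param ac A-vs-C [itc_estimate()].
#' @param bc B-vs-C [itc_estimate()].
#' @return An object of class \code{"itc_comparison"}: list with
#'   \code{delta_ab}, \code{var_ab}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{scale_warning} and the two \code{components}.
#' @examples
#' ac <- itc_estimate(-1.0, 0.2, "marginal", "gcomp-ml")
#' bc <- itc_estimate(-0.5, 0.3, "marginal", "counts")
#' bucher_combine(ac, bc)
#' @export
bucher_combine <- function(ac, bc) {
  stopifnot(inherits(ac, "itc_estimate"), inherits(bc, "itc_estimate"))
  mismatch <- ac$scale == "conditional" || bc$scale == "conditional"
  if (mismatch)
    warning("combining a conditional-scale estimate: the resulting indirect ",
            "comparison mixes incompatible estimands", call. = FALSE)
  delta <- ac$estimate - bc$estimate
  v <- ac$se^2 + bc$se^2
  structure(list(delta_ab = delta, var_ab = v, se = sqrt(v),
                 ci_low = delta - 1.96 * sqrt(v),
                 ci_high = delta + 1.96 * sqrt(v),
                 scale_warning = mismatch,
                 components = list(ac = ac, bc = bc)),
            class = "itc_comparison")
}

#' @export
print.itc_comparison <- function(x, ...) {
  cat(sprintf("A vs B indirect comparison: %.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
              x$delta_ab, x$se, x$ci_low, x$ci_high))
  if (x$scale_warning)
    cat("  note: built from a conditional-scale component (incompatible estimands)\n")
  invisible(x)
}
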