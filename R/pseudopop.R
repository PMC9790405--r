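#' Marginal distribution specification for covariate simulation
#'
#' Describes the assumed marginal distribution of one covariate in the
#' aggregate-data trial, with parameters solved analytically (or
#' numerically for the truncated normal) so that the distribution's mean and
#' SD equal the published summary values. Supported families:
#' \describe{
#'   \item{normal}{mean/sd used directly.}
#'   \item{lognormal}{\eqn{\sigma^2_{\log} = \log(1 + sd^2/mean^2)},
#'     \eqn{\mu_{\log} = \log(mean) - \sigma^2_{\log}/2}; requires
#'     \code{mean > 0}.}
#'   \item{gamma}{shape \eqn{(mean/sd)^2}, rate \eqn{mean/sd^2}; requires
#'     \code{mean > 0}.}
#'   \item{bernoulli}{success probability \code{mean}; \code{sd} ignored
#'     (it is determined by the mean).}
#'   \item{truncated-normal}{location/scale of the underlying normal solved
#'     numerically so the truncated distribution on \code{[lower, upper]}
#'     has the published mean and SD.}
#' }
#'
#' @param family one of \code{"normal"}, \code{"lognormal"}, \code{"gamma"},
#'   \code{"bernoulli"}, \code{"truncated-normal"}.
#' @param mean,sd published marginal mean and standard deviation.
#' @param lower,upper truncation bounds (truncated-normal only).
#' @return An object of class \code{"marginal_spec"} carrying the solved
#'   parameters and the target moments.
#' @examples
#' marginal_spec("lognormal", mean = 2, sd = 1)
#' @export
marginal_spec <- function(family = c("normal", "lognormal", "gamma",
                                     "bernoulli", "truncated-normal"),
                          mean, sd = NULL, lower = -Inf, upper = Inf) {
  family <- match.arg(family)
  if (family != "bernoulli" && (is.null(sd) || sd <= 0))
    stop("`sd` must be positive", call. = FALSE)
  par <- switch(family,
    normal = list(mean = mean, sd = sd),
    lognormal = {
      if (mean <= 0) stop("lognormal requires mean > 0", call. = FALSE)
      s2 <- log(1 + (sd / mean)^2)
      list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    },
    gamma = {
      if (mean <= 0) stop("gamma requires mean > 0", call. = FALSE)
      list(shape = (mean / sd)^2, rate = mean / sd^2)
    },
    bernoulli = {
      if (!.is_prob(mean)) stop("bernoulli requires mean in [0, 1]", call. = FALSE)
      list(prob = mean)
    },
    `truncated-normal` = .solve_truncnorm(mean, sd, lower, upper)
  )
  structure(list(family = family, mean = mean, sd = sd,
                 lower = lower, upper = upper, par = par),
            class = "marginal_spec")
}

#' @export
print.marginal_spec <- function(x, ...) {
  cat(sprintf("Marginal spec: %s (mean %.4g%s)\n", x$family, x$mean,
              if (x$family == "bernoulli") "" else sprintf(", sd %.4g", x$sd)))
  invisible(x)
}

# mean and sd of a normal(mu, s) truncated to [a, b]
.truncnorm_moments <- function(mu, s, a, b) {
  al <- (a - mu) / s
  be <- (b - mu) / s
  zden <- stats::pnorm(be) - stats::pnorm(al)
  d <- (stats::dnorm(al) - stats::dnorm(be)) / zden
  m <- mu + s * d
  # second-moment term; dnorm(+-Inf) and al*dnorm(al) at infinite bounds are 0
  t1 <- ifelse(is.finite(al), al * stats::dnorm(al), 0)
  t2 <- ifelse(is.finite(be), be * stats::dnorm(be), 0)
  v <- s^2 * (1 + (t1 - t2) / zden - d^2)
  c(mean = m, sd = sqrt(v))
}

# solve (mu, s) of the underlying normal so the truncated moments match
.solve_truncnorm <- function(mean, sd, lower, upper) {
  if (!is.finite(lower) && !is.finite(upper))
    return(list(mu = mean, s = sd))
  obj <- function(p) {
    m <- .truncnorm_moments(p[1], exp(p[2]), lower, upper)
    (m[1] - mean)^2 + (m[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  m <- .truncnorm_moments(fit$par[1], exp(fit$par[2]), lower, upper)
  if (max(abs(c(m[1] - mean, m[2] - sd))) > 1e-6)
    stop("could not match truncated-normal moments to the published values",
         call. = FALSE)
  list(mu = fit$par[1], s = exp(fit$par[2]))
}

# inverse CDF of a marginal_spec, applied to uniforms
.spec_quantile <- function(spec, u) {
  p <- spec$par
  switch(spec$family,
    normal = stats::qnorm(u, p$mean, p$sd),
    lognormal = stats::qlnorm(u, p$meanlog, p$sdlog),
    gamma = stats::qgamma(u, shape = p$shape, rate = p$rate),
    bernoulli = as.numeric(u > 1 - p$prob),
    `truncated-normal` = {
      pa <- stats::pnorm(spec$lower, p$mu, p$s)
      pb <- stats::pnorm(spec$upper, p$mu, p$s)
      stats::qnorm(pa + u * (pb - pa), p$mu, p$s)
    })
}

.pseudo_population <- function(x_star, em_idx) {
  if (anyNA(x_star)) stop("pseudo-population contains missing values", call. = FALSE)
  colnames(x_star) <- paste0("x", seq_len(ncol(x_star)))
  structure(list(x_star = x_star, em_idx = as.integer(em_idx),
                 n_star = nrow(x_star)),
            class = "pseudo_population")
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat(sprintf("Pseudo-population: %d simulated subjects, %d covariates\n",
              x$n_star, ncol(x$x_star)))
  cat(sprintf("  effect modifiers: %s\n",
              paste(colnames(x$x_star)[x$em_idx], collapse = ", ")))
  invisible(x)
}

#' Simulate a pseudo-population from a Gaussian copula
#'
#' Reconstructs an individual-level covariate cohort for the aggregate-data
#' trial. A latent multivariate normal vector with the aggregate correlation
#' matrix is drawn for each simulated subject, each latent coordinate is
#' mapped to a uniform through the standard normal CDF, and then through the
#' inverse CDF of the covariate's assumed marginal distribution. The
#' correlation structure and the marginal distributions are thereby
#' specified separately; with all-normal marginals the construction is
#' exactly multivariate normal sampling with the Pearson correlations of
#' \code{agg$corr}. For non-normal marginals the latent correlation is used
#' directly as an approximation to the target Pearson correlation.
#'
#' @param agg an [aggregate_data()] providing the correlation matrix (and
#'   the default moments for \code{marginals}).
#' @param marginals list of [marginal_spec()] objects, one per covariate;
#'   by default normal marginals moment-matched to \code{agg$theta} /
#'   \code{agg$sd}.
#' @param n_star number of simulated subjects.
#' @param em_idx effect-modifier column indices recorded on the result.
#' @param seed optional integer seed.
#' @return A \code{"pseudo_population"}: list with the \code{n_star} x K
#'   matrix \code{x_star}, \code{em_idx} and \code{n_star}.
#' @examples
#' agg <- aggregate_data(rep(0.6, 4), rep(0.4, 4), diag(4),
#'                       matrix(c(90, 310, 95, 105), 2, 2))
#' pp <- copula_population(agg, n_star = 500, em_idx = c(3, 4), seed = 1)
#' colMeans(pp$x_star)
#' @export
copula_population <- function(agg, marginals = NULL, n_star = 1000,
                              em_idx = integer(), seed = NULL) {
  stopifnot(inherits(agg, "aggregate_data"), .is_count(n_star))
  k <- length(agg$theta)
  if (is.null(marginals))
    marginals <- lapply(seq_len(k), function(j)
      marginal_spec("normal", agg$theta[j], agg$sd[j]))
  if (length(marginals) != k)
    stop("need one marginal spec per covariate", call. = FALSE)
  if (!all(vapply(marginals, inherits, logical(1), "marginal_spec")))
    stop("`marginals` must be a list of marginal_spec objects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z <- .rmvnorm(n_star, rep(0, k), agg$corr)
  x <- vapply(seq_len(k),
              function(j) .spec_quantile(marginals[[j]], stats::pnorm(z[, j])),
              numeric(n_star))
  .pseudo_population(matrix(x, nrow = n_star), em_idx)
}

#' Conditional distribution specification for factorized simulation
#'
#' One node of a factorized (sequential conditional) covariate model: a
#' Bernoulli covariate whose success probability is a link-transformed
#' linear function of already-simulated parent covariates,
#' \deqn{\pi_i = g^{-1}(\alpha_0 + \sum_p \alpha_{1p} (x_{ip} - \bar x_p)).}
#' Parents are centered so that \eqn{g^{-1}(\alpha_0)} is interpretable as
#' the covariate's approximate marginal proportion.
#'
#' @param response index of the covariate this spec simulates.
#' @param parents indices of its parent covariates (must be simulated
#'   earlier in the ordering); may be empty.
#' @param alpha0 intercept on the link scale.
#' @param alpha1 slope per parent (length \code{length(parents)}).
#' @param link \code{"logit"}, \code{"probit"} or \code{"identity"}.
#' @param centers optional fixed centering values for the parents; by
#'   default the empirical means of the simulated parent columns.
#' @return An object of class \code{"conditional_spec"}.
#' @examples
#' conditional_spec(2, parents = 1, alpha0 = 0, alpha1 = 1.2)
#' @export
conditional_spec <- function(response, parents = integer(), alpha0,
                             alpha1 = numeric(),
                             link = c("logit", "probit", "identity"),
                             centers = NULL) {
  link <- match.arg(link)
  if (length(alpha1) != length(parents))
    stop("`alpha1` must have one slope per parent", call. = FALSE)
  if (!is.null(centers) && length(centers) != length(parents))
    stop("`centers` must match `parents`", call. = FALSE)
  structure(list(response = as.integer(response),
                 parents = as.integer(parents),
                 alpha0 = alpha0, alpha1 = alpha1, link = link,
                 centers = centers),
            class = "conditional_spec")
}

.linkinv <- function(link) {
  switch(link,
         logit = .expit,
         probit = stats::pnorm,
         identity = function(x) x)
}

#' Simulate a pseudo-population by factorizing the joint distribution
#'
#' Alternative to the copula: the joint covariate distribution is written as
#' a product of a root marginal and a sequence of conditional distributions,
#' each simulated given the covariates already drawn (e.g.
#' \eqn{p(age, c, d) = p(d \mid c, age)\, p(c \mid age)\, p(age)}).
#' Covariate 1 is drawn from \code{root}; each subsequent covariate is a
#' Bernoulli draw from its [conditional_spec()].
#'
#' @param root a [marginal_spec()] for the first covariate.
#' @param conditionals list of [conditional_spec()] for covariates
#'   \code{2, ..., K}, in simulation order; each spec may only reference
#'   parents with smaller indices.
#' @param n_star number of simulated subjects.
#' @param em_idx effect-modifier column indices recorded on the result.
#' @param seed optional integer seed.
#' @return A \code{"pseudo_population"}.
#' @examples
#' pp <- factorized_population(
#'   marginal_spec("normal", 0.6, 0.4),
#'   list(conditional_spec(2, parents = 1, alpha0 = 0, alpha1 = 1.5)),
#'   n_star = 500, seed = 1)
#' @export
factorized_population <- function(root, conditionals, n_star = 1000,
                                  em_idx = integer(), seed = NULL) {
  stopifnot(inherits(root, "marginal_spec"), .is_count(n_star))
  if (!all(vapply(conditionals, inherits, logical(1), "conditional_spec")))
    stop("`conditionals` must be a list of conditional_spec objects",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- length(conditionals) + 1L
  x <- matrix(NA_real_, n_star, k)
  x[, 1] <- .spec_quantile(root, stats::runif(n_star))
  done <- 1L
  for (cs in conditionals) {
    if (cs$response != done + 1L)
      stop("conditionals must be ordered by response index 2..K", call. = FALSE)
    if (length(cs$parents) && any(cs$parents > done))
      stop(sprintf("covariate %d conditions on a not-yet-simulated parent",
                   cs$response), call. = FALSE)
    eta <- rep(cs$alpha0, n_star)
    if (length(cs$parents)) {
      par_x <- x[, cs$parents, drop = FALSE]
      ctr <- if (is.null(cs$centers)) colMeans(par_x) else cs$centers
      eta <- eta + drop(sweep(par_x, 2, ctr) %*% cs$alpha1)
    }
    x[, cs$response] <- stats::rbinom(n_star, 1L, .linkinv(cs$link)(eta))
    done <- done + 1L
  }
  .pseudo_population(x, em_idx)
}
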