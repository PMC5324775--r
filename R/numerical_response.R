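#' Numerical-response parameters
#'
#' Bundles the coefficients of the predator--prey numerical response used as
#' the Poisson mean model. Under the type III (sigmoidal) family the mean
#' predator strike count at prey count `x` is
#' \deqn{\mu = \beta_0 x^2 / (\beta_1^2 + x^2),}
#' and under the simpler type II (hyperbolic) family
#' \deqn{\mu = \beta_0 x / (\beta_1 + x).}
#' `beta0` is the asymptotic (maximum) predator strike count per period;
#' `beta1` is the prey count at which the predator rate is half of `beta0`.
#'
#' `beta0` may be non-positive (the prior admits it); the likelihood assigns
#' such values probability zero whenever any prey count is positive, so the
#' posterior support is effectively positive.
#'
#' @param beta0 real; predator-rate asymptote.
#' @param beta1 strictly positive real; half-saturation prey count.
#' @param family `"holling3"` (default) or `"holling2"`.
#' @return An object of class `response_params`.
#' @examples
#' response_params(10, 6.2)
#' @export
response_params <- function(beta0, beta1, family = c("holling3", "holling2")) {
  family <- match.arg(family)
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0),
            is.numeric(beta1), length(beta1) == 1L, is.finite(beta1))
  if (beta1 <= 0) {
    stop("beta1 must be strictly positive (half-saturation constant)",
         call. = FALSE)
  }
  structure(list(beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
                 family = family),
            class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  cat(sprintf("response_params [%s]: beta0 = %g, beta1 = %g\n",
              x$family, x$beta0, x$beta1))
  invisible(x)
}

#' Mean numerical response
#'
#' Expected predator strike count at prey strike count `x`. Vectorised over
#' `x`. At `x = 0` the response is exactly 0; as `x` grows it saturates at
#' `beta0`, and at `x = beta1` the type III response equals `beta0 / 2`
#' exactly.
#'
#' @param x non-negative prey strike count(s).
#' @param params a [response_params()], or anything coercible via
#'   `params$beta0`, `params$beta1`, `params$family`.
#' @return Numeric vector of mean rates, same length as `x`.
#' @examples
#' mean_response(c(0, 6.2, 15), response_params(10, 6.2))
#' @export
mean_response <- function(x, params) {
  if (any(x < 0)) stop("prey counts must be non-negative", call. = FALSE)
  if (params$beta1 <= 0) stop("beta1 must be > 0", call. = FALSE)
  .mu(x, params$beta0, params$beta1, params$family)
}

# internal fast path: no validation, vectorised over x
.mu <- function(x, beta0, beta1, family) {
  if (family == "holling3") {
    beta0 * x^2 / (beta1^2 + x^2)
  } else {
    beta0 * x / (beta1 + x)
  }
}

#' Poisson log-likelihood of a strike dataset
#'
#' Sum over units of the Poisson log-pmf of the predator count at the mean
#' given by the numerical response of the unit's prey count. Conventions at
#' the boundary: a unit with `mu = 0` and `y = 0` contributes exactly 0 (the
#' Poisson mass at zero is one); `mu = 0` with `y > 0` gives `-Inf`; a
#' non-positive `beta0` with any positive prey count gives `-Inf` (negative
#' rates have likelihood zero). Infinities are valid return values.
#'
#' @param ds a `strike_dataset` with no held-out unit.
#' @param params a [response_params()].
#' @return A single numeric log-likelihood (possibly `-Inf`).
#' @examples
#' ds <- strike_dataset(c("A", "B"), c(2, 5), c(6, 30))
#' log_likelihood(ds, response_params(10, 6))
#' @export
log_likelihood <- function(ds, params) {
  .check_fit_data(ds)
  y <- ds$records$fox_strikes
  x <- ds$records$lagomorph_strikes
  .loglik(y, x, params$beta0, params$beta1, params$family)
}

# internal: vectorised log-likelihood kernel shared by MCMC and grid code
.loglik <- function(y, x, beta0, beta1, family) {
  mu <- .mu(x, beta0, beta1, family)
  if (any(mu < 0)) return(-Inf)
  zero <- mu == 0
  if (any(y[zero] > 0)) return(-Inf)
  yp <- y[!zero]
  mup <- mu[!zero]
  if (!length(yp)) return(0)
  sum(yp * log(mup) - mup - lgamma(yp + 1))
}

#' Log prior density of the response parameters
#'
#' The stated priors: `beta0 ~ Normal(0, 1000^2)` (untruncated) and
#' `beta1 ~ Normal(0, 1000^2)` truncated to the positive half-line, with its
#' normalising factor of 2 included. Returns `-Inf` for `beta1 <= 0`.
#'
#' @param params a [response_params()] or a list with `beta0`, `beta1`.
#' @param prior_sd prior standard deviation for both coefficients
#'   (default 1000).
#' @return Log prior density (possibly `-Inf`).
#' @export
log_prior <- function(params, prior_sd = 1000) {
  .logprior(params$beta0, params$beta1, prior_sd)
}

.logprior <- function(beta0, beta1, prior_sd = 1000) {
  if (beta1 <= 0) return(-Inf)
  stats::dnorm(beta0, 0, prior_sd, log = TRUE) +
    log(2) + stats::dnorm(beta1, 0, prior_sd, log = TRUE)
}

#' Unnormalised log posterior
#'
#' `log_likelihood(ds, params) + log_prior(params)`; `-Inf` propagates.
#'
#' @inheritParams log_likelihood
#' @param prior_sd prior standard deviation (see [log_prior()]).
#' @return A single numeric (possibly `-Inf`).
#' @export
log_posterior <- function(ds, params, prior_sd = 1000) {
  lp <- log_prior(params, prior_sd)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(ds, params)
}
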