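#' MCMC chain configuration
#'
#' Settings for the random-walk Metropolis--Hastings sampler. Defaults
#' follow the case-study design: three parallel chains with overdispersed
#' starting values, 5,000 burn-in iterations and 50,000 retained draws per
#' chain, and diagonal Gaussian proposals on the untransformed
#' `(beta0, beta1)` scale.
#'
#' @param n_chains number of parallel chains (default 3; at least 2 are
#'   needed for the Gelman--Rubin diagnostic).
#' @param n_iterations retained (post burn-in) iterations per chain.
#' @param n_burnin discarded initial iterations per chain.
#' @param proposal_scales length-2 positive numeric: random-walk standard
#'   deviations for `beta0` and `beta1`.
#' @param initial_values `n_chains x 2` matrix of starting values
#'   (columns `beta0`, `beta1`); rows must differ. `NULL` uses built-in
#'   overdispersed starts.
#' @param seed integer seed; all chain randomness derives from it.
#' @return An object of class `chain_config`.
#' @examples
#' chain_config(seed = 1, n_iterations = 2000, n_burnin = 500)
#' @export
chain_config <- function(n_chains = 3, n_iterations = 50000, n_burnin = 5000,
                         proposal_scales = c(1.5, 2.0),
                         initial_values = NULL, seed = 1) {
  stopifnot(n_chains >= 1, n_iterations >= 1, n_burnin >= 0,
            length(proposal_scales) == 2, all(proposal_scales > 0))
  if (is.null(initial_values)) {
    initial_values <- .default_inits(n_chains)
  }
  initial_values <- as.matrix(initial_values)
  if (nrow(initial_values) != n_chains || ncol(initial_values) != 2) {
    stop("initial_values must be an n_chains x 2 matrix", call. = FALSE)
  }
  if (anyDuplicated(initial_values)) {
    stop("initial values must differ across chains", call. = FALSE)
  }
  if (any(initial_values[, 2] <= 0)) {
    stop("initial beta1 values must be positive", call. = FALSE)
  }
  colnames(initial_values) <- c("beta0", "beta1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 proposal_scales = as.numeric(proposal_scales),
                 initial_values = initial_values,
                 seed = as.integer(seed)),
            class = "chain_config")
}

# overdispersed default starts; extended deterministically past 3 chains
.default_inits <- function(n_chains) {
  b0 <- c(2, 10, 25)
  b1 <- c(1, 6, 20)
  i <- seq_len(n_chains) - 1L
  cbind(beta0 = b0[i %% 3L + 1L] + 30 * (i %/% 3L),
        beta1 = b1[i %% 3L + 1L] + 20 * (i %/% 3L))
}

#' Run the random-walk Metropolis--Hastings sampler
#'
#' Samples the joint posterior of `(beta0, beta1)` under the Poisson
#' numerical-response model. Proposals are independent Gaussian increments
#' on each coordinate; a proposal with `beta1 <= 0` (or a negative implied
#' rate) has log-posterior `-Inf` and is rejected, which preserves detailed
#' balance because the proposal is symmetric. Burn-in draws are discarded.
#' Runs are exactly reproducible from `cfg$seed`.
#'
#' Passing `ds = NULL` samples the prior alone (the likelihood term is
#' dropped); this supports prior-recovery checks of the sampler.
#'
#' @param ds a `strike_dataset` with the held-out unit already removed (see
#'   [mainland_subset()]), or `NULL` for prior-only sampling.
#' @param cfg a [chain_config()].
#' @param family response family, `"holling3"` (default) or `"holling2"`.
#' @param prior_sd prior standard deviation (see [log_prior()]).
#' @return An object of class `posterior_chains`: list with `draws` (a list
#'   of `n_iterations x 2` matrices, one per chain), `acceptance_rate` (per
#'   chain), `config`, `family`.
#' @examples
#' ds <- mainland_subset(fox_lagomorph_strikes())
#' fit <- run_mcmc(ds, chain_config(seed = 1, n_iterations = 2000,
#'                                  n_burnin = 500))
#' @export
run_mcmc <- function(ds, cfg = chain_config(), family = c("holling3",
                     "holling2"), prior_sd = 1000) {
  family <- match.arg(family)
  stopifnot(inherits(cfg, "chain_config"))
  if (!is.null(ds)) {
    .check_fit_data(ds)
    y <- ds$records$fox_strikes
    x <- ds$records$lagomorph_strikes
    if (any(y > 0 & x == 0)) {
      stop("data impossible under the model: a unit has predator strikes ",
           "but zero prey strikes (the response forces mu = 0 there)",
           call. = FALSE)
    }
    # records with x = 0 (and so y = 0) contribute exactly 0 for all params
    keep <- x > 0
    y <- y[keep]
    x <- x[keep]
  } else {
    y <- x <- numeric(0)
  }
  logpost <- function(b0, b1) {
    if (b1 <= 0) return(-Inf)
    lp <- .logprior(b0, b1, prior_sd)
    if (length(y)) lp <- lp + .loglik(y, x, b0, b1, family)
    lp
  }
  n_total <- cfg$n_burnin + cfg$n_iterations
  set.seed(cfg$seed)
  draws <- vector("list", cfg$n_chains)
  acc <- numeric(cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    out <- .mh_chain(logpost, cfg$initial_values[ch, ], n_total,
                     cfg$proposal_scales)
    draws[[ch]] <- out$draws[(cfg$n_burnin + 1):n_total, , drop = FALSE]
    acc[ch] <- out$acceptance
    if (out$acceptance == 0) {
      stop("chain ", ch, " accepted no proposals; adjust proposal_scales",
           call. = FALSE)
    }
  }
  structure(list(draws = draws, acceptance_rate = acc, config = cfg,
                 family = family),
            class = "posterior_chains")
}

# one Metropolis-Hastings chain; innovations pre-generated for speed
.mh_chain <- function(logpost, init, n_total, scales) {
  eps0 <- stats::rnorm(n_total, 0, scales[1])
  eps1 <- stats::rnorm(n_total, 0, scales[2])
  logu <- log(stats::runif(n_total))
  out <- matrix(NA_real_, n_total, 2,
                dimnames = list(NULL, c("beta0", "beta1")))
  b0 <- init[1]
  b1 <- init[2]
  lp <- logpost(b0, b1)
  if (!is.finite(lp)) {
    stop("initial values have zero posterior density", call. = FALSE)
  }
  n_acc <- 0L
  for (t in seq_len(n_total)) {
    p0 <- b0 + eps0[t]
    p1 <- b1 + eps1[t]
    lp_new <- logpost(p0, p1)
    if (lp_new > -Inf && logu[t] < lp_new - lp) {
      b0 <- p0
      b1 <- p1
      lp <- lp_new
      n_acc <- n_acc + 1L
    }
    out[t, 1] <- b0
    out[t, 2] <- b1
  }
  list(draws = out, acceptance = n_acc / n_total)
}

#' Pool posterior draws into a matrix
#'
#' @param x a `posterior_chains` object.
#' @param ... unused.
#' @return A matrix with columns `beta0`, `beta1`, chains stacked in order.
#' @export
as.matrix.posterior_chains <- function(x, ...) {
  do.call(rbind, x$draws)
}

#' Flatten chains to a long data.frame
#'
#' @param x a `posterior_chains` object.
#' @param ... unused.
#' @return A data.frame with columns `iteration`, `chain`, `beta0`, `beta1`.
#' @export
as.data.frame.posterior_chains <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$draws), function(ch) {
    d <- x$draws[[ch]]
    data.frame(iteration = seq_len(nrow(d)), chain = ch,
               beta0 = d[, 1], beta1 = d[, 2])
  }))
}

#' Export chains to CSV
#'
#' Writes the long format (`iteration`, `chain`, `beta0`, `beta1`) for
#' external diagnostics.
#'
#' @param chains a `posterior_chains` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chains_csv <- function(chains, path) {
  utils::write.csv(as.data.frame(chains), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf(
    "posterior_chains [%s]: %d chains x %d draws, acceptance %s\n",
    x$family, length(x$draws), nrow(x$draws[[1]]),
    paste(sprintf("%.2f", x$acceptance_rate), collapse = "/")))
  invisible(x)
}

#' Gelman--Rubin potential scale reduction factor
#'
#' The classical (non-split) diagnostic: with `m` chains of length `n`,
#' within-chain variance `W` (mean of the per-chain sample variances) and
#' between-chain variance `B = n * var(chain means)`, the statistic is
#' \deqn{\hat R = \sqrt{ \frac{(n-1)/n \; W + B/n}{W} }.}
#' Values near 1 indicate that the chains have mixed; values well above 1
#' indicate non-convergence. No degrees-of-freedom correction is applied.
#'
#' @param chains a `posterior_chains` object, or a list of equal-length
#'   numeric vectors (one parameter, one vector per chain).
#' @return Named numeric vector of per-parameter statistics.
#' @examples
#' gelman_rubin(list(rnorm(100), rnorm(100)))
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "posterior_chains")) {
    mats <- chains$draws
    return(vapply(c(beta0 = 1L, beta1 = 2L), function(j) {
      .psrf(lapply(mats, function(m) m[, j]))
    }, numeric(1)))
  }
  if (is.list(chains) && all(vapply(chains, is.numeric, logical(1)))) {
    return(c(psrf = .psrf(chains)))
  }
  stop("chains must be a posterior_chains object or a list of numeric ",
       "vectors", call. = FALSE)
}

.psrf <- function(vecs) {
  m <- length(vecs)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  n <- unique(vapply(vecs, length, integer(1)))
  if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
  if (n < 10) stop("chains too short (need length >= 10)", call. = FALSE)
  W <- mean(vapply(vecs, stats::var, numeric(1)))
  if (W == 0) {
    stop("zero within-chain variance: degenerate chains", call. = FALSE)
  }
  B_over_n <- stats::var(vapply(vecs, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Deterministic grid approximation of the posterior
#'
#' Evaluates the log posterior on a rectangular `(beta0, beta1)` grid,
#' stabilises by subtracting the maximum, exponentiates and normalises with
#' trapezoidal quadrature weights. This is a brute-force oracle: at two
#' parameters it computes posterior summaries to quadrature accuracy with no
#' Monte Carlo error, and is used to cross-check the sampler.
#'
#' An error is raised if the estimated posterior mass lying beyond any grid
#' boundary exceeds `1e-4` (the ranges are then too narrow), or if the
#' posterior is identically zero on the grid. For an upper boundary the
#' outermost row/column mass proxies the unresolved tail; for a lower
#' boundary the missed mass is bounded by the edge density times the
#' distance to the support edge at zero, since both parameters have zero
#' posterior density below it.
#'
#' @param ds a `strike_dataset` with no held-out unit.
#' @param beta0_range,beta1_range length-2 numeric ranges; `beta1_range`
#'   must be strictly positive.
#' @param resolution grid points per axis (scalar or length 2; minimum 100).
#' @param family response family.
#' @param prior_sd prior standard deviation.
#' @return An object of class `grid_posterior`: `beta0_grid`, `beta1_grid`,
#'   `log_density` (unnormalised), `cell_mass` (sums to 1), `family`.
#' @examples
#' ds <- mainland_subset(fox_lagomorph_strikes())
#' gp <- grid_posterior(ds, resolution = 150)
#' @export
grid_posterior <- function(ds, beta0_range = c(0.01, 60),
                           beta1_range = c(0.001, 80), resolution = 400,
                           family = c("holling3", "holling2"),
                           prior_sd = 1000) {
  family <- match.arg(family)
  .check_fit_data(ds)
  resolution <- rep_len(as.integer(resolution), 2)
  stopifnot(diff(beta0_range) > 0, diff(beta1_range) > 0,
            all(resolution >= 100))
  if (beta1_range[1] <= 0) {
    stop("beta1_range must be strictly positive", call. = FALSE)
  }
  b0 <- seq(beta0_range[1], beta0_range[2], length.out = resolution[1])
  b1 <- seq(beta1_range[1], beta1_range[2], length.out = resolution[2])
  y <- ds$records$fox_strikes
  x <- ds$records$lagomorph_strikes
  if (any(y > 0 & x == 0)) {
    stop("data impossible under the model: predator strikes with zero ",
         "prey strikes", call. = FALSE)
  }
  keep <- x > 0
  y <- y[keep]
  x <- x[keep]
  ld <- matrix(0, resolution[1], resolution[2])
  for (i in seq_along(y)) {
    # saturation fraction over the beta1 axis, scaled by beta0 via outer()
    frac <- if (family == "holling3") x[i]^2 / (b1^2 + x[i]^2)
            else x[i] / (b1 + x[i])
    mu <- outer(b0, frac)
    term <- matrix(-Inf, resolution[1], resolution[2])
    pos <- mu > 0  # x > 0 here, so mu <= 0 iff beta0 <= 0: likelihood zero
    term[pos] <- y[i] * log(mu[pos]) - mu[pos]
    if (y[i] == 0) term[mu == 0] <- 0
    ld <- ld + term
  }
  ld <- ld + stats::dnorm(b0, 0, prior_sd, log = TRUE) +
    rep(log(2) + stats::dnorm(b1, 0, prior_sd, log = TRUE),
        each = resolution[1])
  if (all(ld == -Inf)) {
    stop("log posterior is -Inf over the whole grid; check ranges",
         call. = FALSE)
  }
  w0 <- .trap_weights(b0)
  w1 <- .trap_weights(b1)
  mass <- exp(ld - max(ld)) * outer(w0, w1)
  mass <- mass / sum(mass)
  # estimated mass beyond each boundary: upper tails via the outermost
  # row/column mass; lower edges via edge density x distance to support (0)
  missed <- c(
    beta0_lower = sum(mass[1, ]) / w0[1] * max(0, b0[1]),
    beta0_upper = sum(mass[resolution[1], ]),
    beta1_lower = sum(mass[, 1]) / w1[1] * max(0, b1[1]),
    beta1_upper = sum(mass[, resolution[2]]))
  if (any(missed > 1e-4)) {
    stop("estimated posterior mass beyond the ",
         paste(names(missed)[missed > 1e-4], collapse = ", "),
         " grid boundary exceeds 1e-4; widen beta0_range/beta1_range",
         call. = FALSE)
  }
  structure(list(beta0_grid = b0, beta1_grid = b1, log_density = ld,
                 cell_mass = mass, family = family),
            class = "grid_posterior")
}

.trap_weights <- function(g) {
  h <- diff(g)
  c(h[1] / 2, (h[-length(h)] + h[-1]) / 2, h[length(h)] / 2)
}

#' Marginal distribution from a grid posterior
#'
#' @param gp a `grid_posterior`.
#' @param parameter `"beta0"` or `"beta1"`.
#' @return A data.frame with columns `value` and `mass` (sums to 1).
#' @export
grid_marginal <- function(gp, parameter = c("beta0", "beta1")) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(gp, "grid_posterior"))
  if (parameter == "beta0") {
    data.frame(value = gp$beta0_grid, mass = rowSums(gp$cell_mass))
  } else {
    data.frame(value = gp$beta1_grid, mass = colSums(gp$cell_mass))
  }
}

#' Marginal quantiles from a grid posterior
#'
#' Quantiles are located where the cumulative marginal cell mass first
#' crosses each probability.
#'
#' @param gp a `grid_posterior`.
#' @param parameter `"beta0"` or `"beta1"`.
#' @param probs probabilities in (0, 1).
#' @return Named numeric vector of quantiles.
#' @export
grid_quantile <- function(gp, parameter = c("beta0", "beta1"),
                          probs = c(0.025, 0.5, 0.975)) {
  marg <- grid_marginal(gp, parameter)
  stopifnot(all(probs > 0), all(probs < 1))
  cm <- cumsum(marg$mass)
  out <- vapply(probs, function(p) marg$value[which(cm >= p)[1]], numeric(1))
  names(out) <- paste0(format(100 * probs, trim = TRUE), "%")
  out
}

#' Posterior expectation of a functional on the grid
#'
#' @param gp a `grid_posterior`.
#' @param fn vectorised function of `(beta0, beta1)`.
#' @return The expectation `E[fn(beta0, beta1)]` by cell-mass summation.
#' @examples
#' \dontrun{grid_expectation(gp, function(b0, b1) b0 * 225 / (b1^2 + 225))}
#' @export
grid_expectation <- function(gp, fn) {
  stopifnot(inherits(gp, "grid_posterior"))
  B0 <- matrix(gp$beta0_grid, nrow = length(gp$beta0_grid),
               ncol = length(gp$beta1_grid))
  B1 <- matrix(gp$beta1_grid, nrow = length(gp$beta0_grid),
               ncol = length(gp$beta1_grid), byrow = TRUE)
  sum(fn(B0, B1) * gp$cell_mass)
}

#' @export
print.grid_posterior <- function(x, ...) {
  cat(sprintf(
    "grid_posterior [%s]: %d x %d grid, beta0 in [%g, %g], beta1 in [%g, %g]\n",
    x$family, length(x$beta0_grid), length(x$beta1_grid),
    min(x$beta0_grid), max(x$beta0_grid),
    min(x$beta1_grid), max(x$beta1_grid)))
  invisible(x)
}

#' Summarise a posterior
#'
#' Equal-tailed credible intervals, medians and means per parameter, from
#' either pooled MCMC draws or a grid posterior. For chains the quantiles
#' use linear interpolation of order statistics (`stats::quantile` type 7)
#' and the Gelman--Rubin statistic is included; for a grid the quantiles are
#' cumulative-mass crossings and `rhat` is `NA`.
#'
#' @param posterior a `posterior_chains` or `grid_posterior` object.
#' @param levels credible levels in (0, 1); default 0.95.
#' @return An object of class `posterior_summary`: a data.frame with one row
#'   per parameter and columns `mean`, `median`, `lower_*`/`upper_*` per
#'   level, and `rhat`.
#' @export
summarize_posterior <- function(posterior, levels = 0.95) {
  if (any(levels <= 0) || any(levels >= 1)) {
    stop("credible levels must lie strictly between 0 and 1", call. = FALSE)
  }
  UseMethod("summarize_posterior")
}

#' @export
summarize_posterior.posterior_chains <- function(posterior, levels = 0.95) {
  pooled <- as.matrix(posterior)
  rhat <- if (length(posterior$draws) >= 2) gelman_rubin(posterior)
          else c(beta0 = NA_real_, beta1 = NA_real_)
  out <- do.call(rbind, lapply(c("beta0", "beta1"), function(p) {
    v <- pooled[, p]
    row <- data.frame(parameter = p, mean = mean(v),
                      median = stats::median(v))
    for (l in levels) {
      q <- stats::quantile(v, c((1 - l) / 2, 1 - (1 - l) / 2), names = FALSE)
      row[[.lv_name("lower", l)]] <- q[1]
      row[[.lv_name("upper", l)]] <- q[2]
    }
    row$rhat <- unname(rhat[p])
    row
  }))
  structure(out, class = c("posterior_summary", "data.frame"))
}

#' @export
summarize_posterior.grid_posterior <- function(posterior, levels = 0.95) {
  out <- do.call(rbind, lapply(c("beta0", "beta1"), function(p) {
    marg <- grid_marginal(posterior, p)
    row <- data.frame(parameter = p,
                      mean = sum(marg$value * marg$mass),
                      median = unname(grid_quantile(posterior, p, 0.5)))
    for (l in levels) {
      q <- grid_quantile(posterior, p, c((1 - l) / 2, 1 - (1 - l) / 2))
      row[[.lv_name("lower", l)]] <- unname(q[1])
      row[[.lv_name("upper", l)]] <- unname(q[2])
    }
    row$rhat <- NA_real_
    row
  }))
  structure(out, class = c("posterior_summary", "data.frame"))
}

.lv_name <- function(side, level) {
  paste0(side, "_", gsub("\\.", "", format(100 * level, trim = TRUE)))
}

#' @export
print.posterior_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
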