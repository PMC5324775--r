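# Posterior predictive inference for a held-out unit.
#
# All predictive quantities are Rao-Blackwellized: each posterior draw (or
# grid cell) contributes its exact Poisson pmf at mu(x_new), and the
# predictive pmf is the mass-weighted average. No predictive counts are
# sampled, so tail probabilities such as P(y = 0) carry no extra Monte
# Carlo noise beyond the posterior itself.

# internal: posterior of mu(x_new) as values + normalised weights
.posterior_mu_weights <- function(posterior, x_new) {
  stopifnot(length(x_new) == 1L, x_new >= 0)
  if (inherits(posterior, "posterior_chains")) {
    pooled <- as.matrix(posterior)
    mu <- .mu(x_new, pooled[, "beta0"], pooled[, "beta1"], posterior$family)
    list(mu = mu, w = rep(1 / length(mu), length(mu)))
  } else if (inherits(posterior, "grid_posterior")) {
    B0 <- matrix(posterior$beta0_grid, nrow = length(posterior$beta0_grid),
                 ncol = length(posterior$beta1_grid))
    B1 <- matrix(posterior$beta1_grid, nrow = length(posterior$beta0_grid),
                 ncol = length(posterior$beta1_grid), byrow = TRUE)
    list(mu = as.vector(.mu(x_new, B0, B1, posterior$family)),
         w = as.vector(posterior$cell_mass))
  } else {
    stop("posterior must be a posterior_chains or grid_posterior object",
         call. = FALSE)
  }
}

# weighted type-7-free quantile: smallest value with weighted CDF >= p
.weighted_quantile <- function(v, w, probs) {
  o <- order(v)
  cw <- cumsum(w[o])
  vapply(probs, function(p) v[o][which(cw >= p)[1]], numeric(1))
}

#' Posterior predictive distribution for a held-out unit
#'
#' Probability mass function of the predator strike count for a unit with
#' prey count `x_new`, averaging exact Poisson pmfs over the posterior of
#' `mu(x_new) = beta0 * x_new^2 / (beta1^2 + x_new^2)` (type III family).
#' The support cap `y_max` is grown adaptively until the truncated mass is
#' below `tol`.
#'
#' @param posterior a `posterior_chains` or `grid_posterior` object.
#' @param x_new non-negative prey strike count of the held-out unit.
#' @param level credible level for the `mu(x_new)` interval summary.
#' @param tol maximum predictive mass allowed beyond `y_max`.
#' @param y_max_cap hard cap on the support; exceeding it is an error.
#' @return An object of class `predictive_pmf`: list with `x_new`, `y`
#'   (support `0:y_max`), `pmf`, and `mu_summary` (posterior mean, median
#'   and equal-tailed interval of the unit's mean rate).
#' @examples
#' ds <- mainland_subset(fox_lagomorph_strikes())
#' gp <- grid_posterior(ds, resolution = 150)
#' pp <- posterior_predictive(gp, x_new = 15)
#' @export
posterior_predictive <- function(posterior, x_new, level = 0.95,
                                 tol = 1e-9, y_max_cap = 10000L) {
  mw <- .posterior_mu_weights(posterior, x_new)
  mu <- mw$mu
  w <- mw$w
  q <- .weighted_quantile(mu, w, c((1 - level) / 2, 0.5, 1 - (1 - level) / 2))
  mu_summary <- list(mean = sum(w * mu), median = q[2],
                     lower = q[1], upper = q[3], level = level)
  # grow the support until < tol mass remains beyond the cap
  y_max <- max(16L, ceiling(stats::qpois(0.9999, max(mu))))
  repeat {
    pmf <- vapply(0:y_max, function(k) sum(w * stats::dpois(k, mu)),
                  numeric(1))
    if (1 - sum(pmf) < tol) break
    if (y_max >= y_max_cap) {
      stop("predictive support exceeded y_max_cap before reaching the ",
           "mass tolerance; raise y_max_cap", call. = FALSE)
    }
    y_max <- min(y_max_cap, 2L * y_max)
  }
  structure(list(x_new = x_new, y = 0:y_max, pmf = pmf,
                 mu_summary = mu_summary),
            class = "predictive_pmf")
}

#' @export
print.predictive_pmf <- function(x, ...) {
  cat(sprintf(
    "predictive_pmf at x_new = %g: support 0..%d, P(0) = %.4g\n",
    x$x_new, max(x$y), x$pmf[1]))
  cat(sprintf("  mu(x_new): mean %.3g, median %.3g, %g%% CI [%.3g, %.3g]\n",
              x$mu_summary$mean, x$mu_summary$median,
              100 * x$mu_summary$level, x$mu_summary$lower,
              x$mu_summary$upper))
  invisible(x)
}

#' Posterior predictive probability of observing zero strikes
#'
#' The posterior expectation of `exp(-mu(x_new))`, i.e. the predictive mass
#' at zero. For the case study this is the probability of recording no
#' predator strikes at the held-out unit given its prey strike count —
#' small values argue against a resident predator population consistent
#' with the prey base.
#'
#' @inheritParams posterior_predictive
#' @return A probability.
#' @examples
#' \dontrun{prob_zero(fit, x_new = 15)}
#' @export
prob_zero <- function(posterior, x_new) {
  mw <- .posterior_mu_weights(posterior, x_new)
  sum(mw$w * exp(-mw$mu))
}

#' Equal-tailed discrete prediction interval
#'
#' For level `1 - alpha`: the lower bound is the smallest count whose
#' predictive CDF reaches `alpha/2`, the upper bound the smallest count
#' whose CDF reaches `1 - alpha/2`.
#'
#' @param pmf a `predictive_pmf`.
#' @param level interval level in (0, 1).
#' @return Named integer vector `c(lower, upper)`.
#' @export
prediction_interval <- function(pmf, level = 0.95) {
  stopifnot(inherits(pmf, "predictive_pmf"))
  if (level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  cdf <- cumsum(pmf$pmf)
  alpha <- 1 - level
  c(lower = pmf$y[which(cdf >= alpha / 2)[1]],
    upper = pmf$y[which(cdf >= 1 - alpha / 2)[1]])
}

#' Fitted-response band across prey counts
#'
#' For each prey count in `x_values`, computes the posterior credible
#' interval of the mean rate `mu(x)` and discrete prediction intervals for
#' the observed count at each requested level — the ingredients of the
#' fitted-curve figure (response curve, credible band, prediction bands,
#' data points).
#'
#' @param posterior a `posterior_chains` or `grid_posterior` object.
#' @param x_values ordered non-negative prey counts.
#' @param levels prediction-interval levels.
#' @param mu_level credible level for the mean-rate band.
#' @return An object of class `prediction_band`: a data.frame with one row
#'   per `x` and columns `mu_mean`, `mu_median`, `mu_lower`, `mu_upper`,
#'   and `pi_lower_*`/`pi_upper_*` per level.
#' @examples
#' \dontrun{prediction_band(fit, 0:45)}
#' @export
prediction_band <- function(posterior, x_values, levels = c(0.95, 0.99),
                            mu_level = 0.95) {
  if (!length(x_values)) stop("x_values must be non-empty", call. = FALSE)
  rows <- lapply(x_values, function(x) {
    pp <- posterior_predictive(posterior, x, level = mu_level)
    row <- data.frame(x = x, mu_mean = pp$mu_summary$mean,
                      mu_median = pp$mu_summary$median,
                      mu_lower = pp$mu_summary$lower,
                      mu_upper = pp$mu_summary$upper)
    for (l in levels) {
      pi <- prediction_interval(pp, l)
      row[[.lv_name("pi_lower", l)]] <- pi[["lower"]]
      row[[.lv_name("pi_upper", l)]] <- pi[["upper"]]
    }
    row
  })
  structure(do.call(rbind, rows),
            class = c("prediction_band", "data.frame"),
            levels_used = levels, mu_level = mu_level)
}

#' Plot a prediction band
#'
#' Base-graphics rendering of the fitted numerical response: posterior
#' median curve of `mu(x)`, credible band for the mean, stepped prediction
#' bands for counts, observed units, and the held-out unit highlighted.
#'
#' @param x a `prediction_band`.
#' @param ds optional `strike_dataset` whose points (and held-out unit, if
#'   flagged) are overlaid.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.prediction_band <- function(x, ds = NULL, ...) {
  levels_used <- attr(x, "levels_used")
  ymax <- max(x[[.lv_name("pi_upper", max(levels_used))]], x$mu_upper,
              if (!is.null(ds)) ds$records$fox_strikes)
  plot(x$x, x$mu_median, type = "l", lwd = 2, ylim = c(0, ymax * 1.05),
       xlab = "prey strikes per period", ylab = "predator strikes per period",
       ...)
  graphics::polygon(c(x$x, rev(x$x)), c(x$mu_lower, rev(x$mu_upper)),
                    col = grDevices::adjustcolor("grey50", 0.3), border = NA)
  ltys <- c(3, 2, 4, 5)
  for (i in seq_along(levels_used)) {
    graphics::lines(x$x, x[[.lv_name("pi_lower", levels_used[i])]],
                    lty = ltys[i])
    graphics::lines(x$x, x[[.lv_name("pi_upper", levels_used[i])]],
                    lty = ltys[i])
  }
  if (!is.null(ds)) {
    rec <- ds$records
    held <- if (!is.null(ds$held_out))
      .unit_key(rec$unit) == .unit_key(ds$held_out) else rep(FALSE, nrow(rec))
    graphics::points(rec$lagomorph_strikes[!held], rec$fox_strikes[!held],
                     pch = 16)
    graphics::points(rec$lagomorph_strikes[held], rec$fox_strikes[held],
                     pch = 1, cex = 1.4)
  }
  invisible(x)
}
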