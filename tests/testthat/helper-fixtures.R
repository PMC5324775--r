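# Shared fixtures. The full-length case-study fit and grid oracle are
# expensive enough to share across test files; they are computed once per
# test run and memoised here.

.cache <- new.env(parent = emptyenv())

case_data <- function() fox_lagomorph_strikes()

case_mainland <- function() mainland_subset(case_data())

# default-settings sampler fit: 3 chains x 50,000 retained (150,000 pooled)
case_fit <- function() {
  if (is.null(.cache$fit)) {
    .cache$fit <- run_mcmc(case_mainland(), chain_config(seed = 1))
  }
  .cache$fit
}

# deterministic grid oracle at the default 400 x 400 resolution
case_grid <- function() {
  if (is.null(.cache$grid)) {
    .cache$grid <- grid_posterior(case_mainland())
  }
  .cache$grid
}

# small sampler settings for tests that only need a working posterior
quick_config <- function(seed = 1, ...) {
  chain_config(seed = seed, n_iterations = 2000, n_burnin = 500, ...)
}

tiny_ds <- function() {
  strike_dataset(c("a", "b", "c"), c(2, 5, 0), c(6, 30, 0))
}

# degenerate one-draw posterior at fixed params, for closed-form checks
point_posterior <- function(beta0, beta1, family = "holling3") {
  structure(list(
    draws = list(matrix(c(beta0, beta1), 1, 2,
                        dimnames = list(NULL, c("beta0", "beta1")))),
    acceptance_rate = 1,
    config = NULL, family = family),
    class = "posterior_chains")
}
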