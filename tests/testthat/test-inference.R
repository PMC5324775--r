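test_that("run_mcmc is deterministic given (seed, config, data) and obeys
           chain contracts", {
  cfg <- quick_config(seed = 7)
  a <- run_mcmc(case_mainland(), cfg)
  b <- run_mcmc(case_mainland(), cfg)
  expect_identical(a$draws, b$draws)
  expect_identical(a$acceptance_rate, b$acceptance_rate)

  expect_length(a$draws, 3)
  for (d in a$draws) {
    expect_equal(nrow(d), cfg$n_iterations)
    expect_true(all(d[, "beta1"] > 0))
  }
  # a different seed gives different draws
  expect_false(identical(a$draws,
                         run_mcmc(case_mainland(), quick_config(seed = 8))$draws))
})

test_that("chain_config validates its invariants", {
  expect_error(chain_config(initial_values = cbind(c(2, 2, 2), c(1, 1, 1))),
               "differ")
  expect_error(chain_config(n_chains = 2,
                            initial_values = cbind(c(2, 5), c(-1, 3))),
               "positive")
  expect_error(chain_config(proposal_scales = c(1, -1)))
  expect_error(run_mcmc(case_mainland(), quick_config(),
                        family = "holling4"))
})

test_that("impossible data (predator strikes at zero prey) is rejected", {
  bad <- strike_dataset(c("a", "b", "z"), c(2, 1, 3), c(6, 12, 0))
  expect_error(run_mcmc(bad, quick_config()), "impossible")
  expect_error(grid_posterior(bad), "impossible")
})

test_that("gelman_rubin matches closed-form behaviour", {
  n <- 100
  set.seed(1)
  v <- rnorm(n)
  # identical chains: B = 0, statistic = sqrt((n-1)/n) < 1
  expect_equal(unname(gelman_rubin(list(v, v, v))), sqrt((n - 1) / n))

  # well-separated chains: statistic computed from W and B by hand
  a <- rnorm(n, 0, 1)
  b <- rnorm(n, 100, 1)
  W <- (var(a) + var(b)) / 2
  B_over_n <- var(c(mean(a), mean(b)))
  expect_equal(unname(gelman_rubin(list(a, b))),
               sqrt(((n - 1) / n * W + B_over_n) / W))
  expect_gt(gelman_rubin(list(a, b)), 10)

  # same-distribution chains converge to 1 as n grows
  set.seed(2)
  big <- replicate(3, rnorm(50000), simplify = FALSE)
  expect_lt(abs(gelman_rubin(big) - 1), 0.005)

  expect_error(gelman_rubin(list(v)), "at least 2")
  expect_error(gelman_rubin(list(v, v[1:50])), "equal length")
  expect_error(gelman_rubin(list(rep(1, 20), rep(1, 20))), "degenerate")
  expect_error(gelman_rubin(list(1:5, 1:5)), "too short")
})

test_that("case-study sampler converges with sensible acceptance", {
  fit <- case_fit()
  rhat <- gelman_rubin(fit)
  expect_true(all(rhat < 1.05))
  expect_true(all(fit$acceptance_rate > 0.1 & fit$acceptance_rate < 0.6))
})

test_that("grid_posterior satisfies normalization and range diagnostics", {
  gp <- case_grid()
  expect_equal(sum(gp$cell_mass), 1, tolerance = 1e-12)
  expect_true(all(gp$cell_mass >= 0))

  # a region where the posterior is identically zero
  expect_error(grid_posterior(case_mainland(), beta0_range = c(-50, -10),
                              beta1_range = c(1, 10), resolution = 100),
               "-Inf")
  # ranges that clip the posterior
  expect_error(grid_posterior(case_mainland(), beta0_range = c(0.01, 8),
                              beta1_range = c(0.001, 80), resolution = 100),
               "widen")
  expect_error(grid_posterior(case_mainland(), resolution = 50))
  expect_error(grid_posterior(case_mainland(), beta1_range = c(-1, 80)),
               "positive")
})

test_that("sampler and grid oracle agree on marginal summaries", {
  s_mcmc <- summarize_posterior(case_fit())
  s_grid <- summarize_posterior(case_grid())
  for (col in c("median", "lower_95", "upper_95")) {
    for (i in 1:2) {
      a <- s_mcmc[[col]][i]
      b <- s_grid[[col]][i]
      expect_lt(abs(a - b), max(0.05 * abs(b), 0.3))
    }
  }
})

test_that("prior-only sampling recovers the stated priors", {
  cfg <- chain_config(n_chains = 3, n_iterations = 20000, n_burnin = 2000,
                      proposal_scales = c(800, 800),
                      initial_values = cbind(c(-500, 0, 500),
                                             c(100, 800, 2000)),
                      seed = 42)
  fit <- run_mcmc(NULL, cfg)
  pooled <- as.matrix(fit)
  idx <- seq(1, nrow(pooled), by = 40)  # thin to near-independence
  half_normal_cdf <- function(q) 2 * pnorm(q, 0, 1000) - 1
  expect_gt(ks.test(pooled[idx, "beta1"], half_normal_cdf)$p.value, 0.01)
  expect_gt(ks.test(pooled[idx, "beta0"], pnorm, 0, 1000)$p.value, 0.01)
})

test_that("summarize_posterior quantile contracts", {
  expect_error(summarize_posterior(case_grid(), levels = 1.2), "between")
  expect_error(summarize_posterior(case_fit(), levels = 0), "between")

  s <- summarize_posterior(case_grid(), levels = c(0.5, 0.95))
  expect_true(all(s$lower_95 <= s$lower_50))
  expect_true(all(s$lower_50 <= s$median))
  expect_true(all(s$median <= s$upper_50))
  expect_true(all(s$upper_50 <= s$upper_95))

  # degenerate one-draw posterior: every quantile equals the draw
  one <- point_posterior(4, 15)
  s1 <- summarize_posterior(one)
  expect_equal(s1$median, c(4, 15))
  expect_equal(s1$lower_95, c(4, 15))
  expect_equal(s1$upper_95, c(4, 15))
})

test_that("chains export to long CSV and back", {
  fit <- run_mcmc(case_mainland(), quick_config(seed = 3))
  p <- withr::local_tempfile(fileext = ".csv")
  write_chains_csv(fit, p)
  back <- read.csv(p)
  expect_equal(names(back), c("iteration", "chain", "beta0", "beta1"))
  expect_equal(nrow(back), 3 * 2000)
  expect_equal(back$beta0[back$chain == 2], fit$draws[[2]][, "beta0"])
})
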