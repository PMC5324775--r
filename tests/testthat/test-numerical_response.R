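test_that("mean_response matches closed forms at anchor points", {
  p3 <- response_params(10, 6.2)
  expect_equal(mean_response(0, p3), 0)
  # half-saturation: x = beta1 gives exactly beta0 / 2 in both families
  expect_equal(mean_response(6.2, p3), 5)
  expect_equal(mean_response(6.2, response_params(10, 6.2, "holling2")), 5)
  # hand evaluation: 10 * 15^2 / (6.2^2 + 15^2) = 2250 / 263.44
  expect_equal(mean_response(15, p3), 2250 / 263.44)

  expect_error(response_params(10, 0), "beta1")
  expect_error(response_params(10, -3), "beta1")
  expect_error(mean_response(-1, p3), "non-negative")
})

test_that("mean_response shape: monotone, saturating, III below II before
           the half-saturation point and above it after", {
  for (pars in list(c(10, 6.2), c(3, 1), c(25, 40))) {
    p3 <- response_params(pars[1], pars[2], "holling3")
    p2 <- response_params(pars[1], pars[2], "holling2")
    xs <- seq(0, 20 * pars[2], length.out = 200)
    for (p in list(p3, p2)) {
      mu <- mean_response(xs, p)
      expect_true(all(diff(mu) >= 0))
      expect_true(all(mu <= pars[1]))
      # saturation: far beyond beta1 the response approaches the asymptote
      expect_equal(mean_response(1e9, p), pars[1], tolerance = 1e-6)
    }
    below <- xs[xs > 0 & xs < pars[2]]
    above <- xs[xs > pars[2]]
    expect_true(all(mean_response(below, p3) < mean_response(below, p2)))
    expect_true(all(mean_response(above, p3) > mean_response(above, p2)))
  }
})

test_that("log_likelihood matches hand-computed Poisson terms and boundary
           conventions", {
  p <- response_params(4, 6)
  # mu = 0 with y = 0 contributes exactly 0
  two_pos <- strike_dataset(c("a", "b", "z"), c(2, 1, 0), c(6, 12, 0))
  # record z adds nothing; a: mu = 2 (x = beta1), b: mu = 4*144/180 = 3.2
  expect_equal(log_likelihood(two_pos, p),
               (2 * log(2) - 2 - log(2)) + (1 * log(3.2) - 3.2))

  just_zero <- strike_dataset(c("a", "b", "z"), c(0, 0, 0), c(6, 12, 0))
  expect_equal(log_likelihood(just_zero, p), -2 - 3.2)

  # zero-mean Poisson cannot produce a positive count
  impossible <- strike_dataset(c("a", "b", "z"), c(2, 1, 1), c(6, 12, 0))
  expect_identical(log_likelihood(impossible, p), -Inf)

  # negative asymptote means negative rates: likelihood zero
  neg <- list(beta0 = -1, beta1 = 6, family = "holling3")
  expect_identical(.loglik(c(2, 1), c(6, 12), -1, 6, "holling3"), -Inf)
  expect_equal(log_likelihood(two_pos, response_params(1e-9, 6)),
               2 * log(1e-9 * 36 / 72) - 1e-9 * 36 / 72 - log(2) +
                 log(1e-9 * 144 / 180) - 1e-9 * 144 / 180,
               tolerance = 1e-9)
})

test_that("log_likelihood is invariant under record permutation", {
  p <- response_params(9, 5.5)
  ds <- case_mainland()
  ref <- log_likelihood(ds, p)
  set.seed(1)
  for (i in 1:5) {
    perm <- ds
    o <- sample(nrow(ds$records))
    perm$records <- perm$records[o, , drop = FALSE]
    expect_equal(log_likelihood(perm, p), ref)
  }
})

test_that("log_prior: closed forms, truncation, and unit total mass", {
  # one-sigma point of the beta0 normal
  p <- response_params(1000, 1)
  expect_equal(log_prior(p),
               dnorm(1000, 0, 1000, log = TRUE) +
                 log(2) + dnorm(1, 0, 1000, log = TRUE))
  expect_identical(.logprior(0, -1), -Inf)
  expect_identical(.logprior(0, 0), -Inf)
  # density at the mode: N(0) for beta0 and 2 N(0) for truncated beta1
  expect_equal(.logprior(0, 1e-12),
               dnorm(0, 0, 1000, log = TRUE) + log(2) +
                 dnorm(0, 0, 1000, log = TRUE),
               tolerance = 1e-9)

  # quadrature over [-5000, 5000] x (0, 5000]: the prior mass inside the
  # box, computed from the joint density alone, must match the boxed mass
  # of the stated normal x half-normal product
  b0 <- seq(-5000, 5000, length.out = 1201)
  b1 <- seq(1e-9, 5000, length.out = 601)
  f <- outer(b0, b1, function(a, b) {
    mapply(function(ai, bi) exp(.logprior(ai, bi)), a, b)
  })
  tw <- function(g) {
    h <- diff(g)
    c(h[1] / 2, (h[-length(h)] + h[-1]) / 2, h[length(h)] / 2)
  }
  got <- sum(f * outer(tw(b0), tw(b1)))
  expected <- (pnorm(5000, 0, 1000) - pnorm(-5000, 0, 1000)) *
    (2 * pnorm(5000, 0, 1000) - 1)
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("log_posterior adds likelihood and prior; -Inf propagates", {
  ds <- case_mainland()
  p <- response_params(10, 6.2)
  # independent term-by-term oracle with stats::dpois
  y <- ds$records$fox_strikes
  x <- ds$records$lagomorph_strikes
  mu <- 10 * x^2 / (6.2^2 + x^2)
  oracle <- sum(ifelse(mu == 0 & y == 0, 0, dpois(y, mu, log = TRUE))) +
    dnorm(10, 0, 1000, log = TRUE) + log(2) + dnorm(6.2, 0, 1000, log = TRUE)
  expect_equal(log_posterior(ds, p), oracle)

  expect_identical(
    log_posterior(ds, list(beta0 = 10, beta1 = -2, family = "holling3")),
    -Inf)
  impossible <- strike_dataset(c("a", "b", "z"), c(2, 1, 1), c(6, 12, 0))
  expect_identical(log_posterior(impossible, p), -Inf)
})
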