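test_that("log posterior matches hand-computed Gaussian densities", {
  # single observation R = 0 at the covariate origin, sigma = 1
  spec <- growth_model_spec(fixed = character(0), group = NULL)
  d <- data.frame(growth_rate = 0)
  lp <- log_posterior(spec, list(beta = 0, sigma = 1), d)
  expected <- dnorm(0, 0, 1, log = TRUE) +          # likelihood
    dnorm(0, 0, 2, log = TRUE) +                    # intercept prior
    dnorm(1, 0, 2, log = TRUE) + log(2)             # half-normal prior on sigma
  expect_equal(lp, expected)

  # additivity: a duplicated row adds exactly its own likelihood term
  spec2 <- growth_model_spec(fixed = "rodent", group = NULL)
  d2 <- data.frame(growth_rate = c(0.3, -0.1), rodent = c(1, -1))
  pars <- list(beta = c(0.1, 0.2), sigma = 0.8)
  lp2 <- log_posterior(spec2, pars, d2)
  lp3 <- log_posterior(spec2, pars, rbind(d2, d2[2, ]))
  mu2 <- 0.1 + 0.2 * (-1)
  expect_equal(lp3 - lp2, dnorm(-0.1, mu2, 0.8, log = TRUE))

  # outside the support
  expect_equal(log_posterior(spec, list(beta = 0, sigma = -1), d), -Inf)
  spec_nb <- abundance_model_spec(fixed = character(0), group = NULL)
  d_nb <- data.frame(tracks = 2L, offset_log = log(3))
  expect_equal(log_posterior(spec_nb, list(beta = 0, theta = -2), d_nb), -Inf)
  # and a finite NB value equal to dnbinom plus priors
  lp_nb <- log_posterior(spec_nb, list(beta = 0.5, theta = 2), d_nb)
  expect_equal(lp_nb,
               dnbinom(2, size = 2, mu = 3 * exp(0.5), log = TRUE) +
                 dnorm(0.5, 0, 2, log = TRUE) + (-1 / 2 + log(1 / 2)))
})

test_that("sampler agrees with the conjugate normal posterior", {
  set.seed(8)
  y <- rnorm(50, 0.7, 1)
  # known sigma = 1, prior N(0, 2^2): posterior mean = sum(y) / (n + 1/4)
  post_mean <- sum(y) / (length(y) + 1 / 4)
  post_sd <- 1 / sqrt(length(y) + 1 / 4)
  spec <- growth_model_spec(fixed = character(0), group = NULL, fixed_sigma = 1)
  f <- fit_model(spec, data.frame(growth_rate = y), chains = 2,
                 iterations = 2500, warmup = 500, seed = 4)
  est <- f$summary$mean[1]
  mcse <- post_sd / sqrt(f$ess_bulk[1])
  expect_lt(abs(est - post_mean), 3 * mcse + 1e-4)
  # posterior sd as well
  expect_equal(sd(as.vector(f$draws[, , 1])), post_sd, tolerance = 0.05)
})

test_that("draws are reproducible given seed and settings", {
  set.seed(2)
  d <- data.frame(growth_rate = rnorm(40), rodent = rnorm(40),
                  group_id = rep(c("a", "b", "c", "d"), 10))
  spec <- growth_model_spec(fixed = "rodent")
  f1 <- suppressWarnings(fit_model(spec, d, chains = 2, iterations = 400,
                                   warmup = 200, seed = 9))
  f2 <- suppressWarnings(fit_model(spec, d, chains = 2, iterations = 400,
                                   warmup = 200, seed = 9))
  expect_identical(f1$draws, f2$draws)
})

test_that("NB posterior means agree with an independent ML fit", {
  sim <- simulate_abundance_data(n = 400, n_years = 5, seed = 3)
  f <- fit_model(abundance_model_spec(), sim$data, chains = 2,
                 iterations = 2000, warmup = 1000, seed = 2)
  d <- sim$data
  d$yf <- factor(d$year)
  m <- glmmTMB::glmmTMB(
    tracks ~ rodent + elevation + rodent_x_elevation + snow + spruce + agri +
      offset(offset_log) + (1 | yf),
    family = glmmTMB::nbinom2, data = d)
  mle <- unname(glmmTMB::fixef(m)$cond)
  expect_true(all(abs(f$summary$mean[1:7] - mle) < 0.08))
  expect_equal(f$summary$mean[f$summary$parameter == "theta"],
               glmmTMB::sigma(m), tolerance = 0.15)
  # posterior predictive calibration on self-generated data
  ppc <- posterior_predictive_check(f, n_rep = 150, seed = 5)
  expect_true(all(ppc$quantile > 0.01 & ppc$quantile < 0.99))
  expect_equal(ppc$statistic, c("mean", "sd", "prop_zero"))
})

test_that("credible intervals are equal-tailed quantiles", {
  set.seed(123)
  z <- rnorm(1e6)
  ci <- credible_interval(z, level = 0.80)
  expect_equal(ci$lower, qnorm(0.1), tolerance = 0.01)
  expect_equal(ci$upper, qnorm(0.9), tolerance = 0.01)
  expect_false(ci$excludes_zero)
  const <- credible_interval(rep(3.5, 200))
  expect_equal(c(const$lower, const$upper), c(3.5, 3.5))
  expect_true(const$excludes_zero)
  full <- credible_interval(z, level = 1)
  expect_equal(c(full$lower, full$upper), range(z))
  expect_error(credible_interval(rnorm(10)), "100 draws")
})

test_that("prior-only sampling recovers the Normal(0, 2) slope prior", {
  spec <- growth_model_spec(fixed = "rodent", group = NULL)
  f <- fit_model(spec, data.frame(growth_rate = numeric(0),
                                  rodent = numeric(0)),
                 chains = 4, iterations = 6000, warmup = 1000,
                 prior_only = TRUE, seed = 6)
  slope <- as.vector(f$draws[, , "rodent"])
  ks <- suppressWarnings(ks.test(slope, "pnorm", 0, 2))
  expect_lt(unname(ks$statistic), 0.05)
  sig <- as.vector(f$draws[, , "sigma"])
  # half-normal marginal for the SD
  ks2 <- suppressWarnings(ks.test(sig, function(q) 2 * pnorm(q, 0, 2) - 1))
  expect_lt(unname(ks2$statistic), 0.05)
})

test_that("standardized and raw covariate fits are related by the linear map", {
  set.seed(14)
  n <- 400
  x_raw <- rnorm(n, 2, 0.5)
  y <- 0.2 + 0.8 * x_raw + rnorm(n, 0, 0.4)
  zs <- z_standardize(x_raw)
  spec <- growth_model_spec(fixed = "rodent", group = NULL)
  fz <- fit_model(spec, data.frame(growth_rate = y, rodent = zs$z),
                  chains = 2, iterations = 2000, warmup = 500, seed = 3)
  fr <- fit_model(spec, data.frame(growth_rate = y, rodent = x_raw),
                  chains = 2, iterations = 2000, warmup = 500, seed = 3)
  b_z <- fz$summary$mean[2]; a_z <- fz$summary$mean[1]
  b_r <- fr$summary$mean[2]; a_r <- fr$summary$mean[1]
  expect_lt(abs(b_r - b_z / zs$scale), 0.02)
  expect_lt(abs(a_r - (a_z - b_z * zs$center / zs$scale)), 0.02)
})

test_that("posterior predictive check degenerates correctly", {
  sim <- simulate_abundance_data(n = 300, n_years = 5, seed = 9)
  spec <- abundance_model_spec()
  ctx_truth <- list(beta = sim$truth$delta, u = unname(sim$truth$v_year),
                    theta = sim$truth$theta, sigma_group = 0.3)
  # a fake fit whose draws sit exactly at the generating parameters
  fake <- structure(list(
    draws = array(rep(c(sim$truth$delta, unname(sim$truth$v_year), 2, 0.3),
                      each = 200),
                  dim = c(100, 2, 14),
                  dimnames = list(NULL, NULL,
                                  c("(Intercept)", spec$fixed,
                                    paste0("u[", sort(unique(sim$data$year)), "]"),
                                    "theta", "sigma_group"))),
    spec = spec, data = sim$data), class = "marten_fit")
  ppc <- posterior_predictive_check(fake, n_rep = 400, seed = 2)
  expect_equal(ppc$rep_mean[1], mean(sim$data$tracks), tolerance = 0.15)
  # a dataset without zeros has observed zero-proportion exactly 0
  d2 <- sim$data; d2$tracks <- d2$tracks + 1L
  fake2 <- fake; fake2$data <- d2
  ppc2 <- posterior_predictive_check(fake2, n_rep = 50, seed = 2)
  expect_equal(ppc2$observed[ppc2$statistic == "prop_zero"], 0)
})
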