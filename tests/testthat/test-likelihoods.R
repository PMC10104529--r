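test_that("relative abundance composes the curve scalar with the log-linear term", {
  d <- tiny_design(5)
  # beta = 0, flat curve: lambda = 1
  expect_equal(relative_abundance(c(0, 0), d), rep(1, 5))
  # P = 1 at the optimum; intercept ln 2 doubles lambda
  cv <- thermal_curve(4, 22, 30)
  expect_equal(relative_abundance(c(log(2), 0), d, cv), rep(2, 5))
  # above ct_max the floor rule applies
  d_hot <- tiny_design(3, temp = rep(35, 3))
  lam <- relative_abundance(c(0.3, 0), d_hot, cv, performance_floor = 1e-10)
  expect_equal(lam, rep(1e-10 * exp(0.3), 3))
  # unfloored predictions are exactly zero there
  expect_equal(relative_abundance(c(0.3, 0), d_hot, cv), rep(0, 3))
  expect_error(relative_abundance(c(0, 0, 0), d), "length")
})

test_that("the Poisson log-likelihood matches hand arithmetic", {
  d <- tiny_design(1, x = 0)
  catch0 <- data.frame(lake_id = "T001", gear = "gear1", year = 2020,
                       count = 0L, effort_net_nights = 3)
  # C = 0, mu = 3 => log-lik -3 (beta chosen so lambda = 1)
  expect_equal(log_likelihood(c(0, 0), 1, catch0, d), -3)
  catch2 <- data.frame(lake_id = "T001", gear = "gear1", year = 2020,
                       count = 2L, effort_net_nights = 1)
  expect_equal(log_likelihood(c(0, 0), 1, catch2, d), -1 - log(2))
  # doubling effort with the count fixed changes log-lik by C*ln2 - mu_old
  base <- log_likelihood(c(0, 0), 1, catch2, d)
  catch2b <- catch2
  catch2b$effort_net_nights <- 2
  expect_equal(log_likelihood(c(0, 0), 1, catch2b, d) - base,
               2 * log(2) - 1)
})

test_that("the log-likelihood is invariant to record order and misalignment errors", {
  sim <- small_survey()
  d <- sim$design
  catch <- sim$catch
  beta <- rep(0.1, 7)
  theta <- c(1.1, 0.9)
  cv <- sim$truth$curve
  ll1 <- log_likelihood(beta, theta, catch, d, cv)
  perm <- sample(nrow(catch))
  ll2 <- log_likelihood(beta, theta, catch[perm, ], d, cv)
  expect_equal(ll1, ll2, tolerance = 1e-12)
  bad <- catch
  bad$lake_id[1] <- "NOPE"
  expect_error(log_likelihood(beta, theta, bad, d, cv), "misalignment")
})

test_that("with the curve disabled the model reduces to the plain log-linear Poisson", {
  sim <- small_survey()
  beta <- c(0.4, 0.2, -0.1, 0.05, 0, 0.1, -0.2)
  theta <- c(1.3, 0.7)
  ll_flat <- log_likelihood(beta, theta, sim$catch, sim$design, curve = NULL)
  # a curve evaluating to 1 at every observed temperature gives the same value
  flat_curve <- thermal_curve(ct_min = -1e12, t_opt = 1e3, ct_max = 2e3)
  ll_pga <- log_likelihood(beta, theta, sim$catch, sim$design, flat_curve)
  expect_equal(ll_pga, ll_flat, tolerance = 1e-8)
})

test_that("the catchability constraint removes the intercept-scaling flat direction", {
  sim <- small_survey()
  beta <- c(0.4, 0.2, -0.1, 0.05, 0, 0.1, -0.2)
  theta <- c(1.3, 0.7)
  c0 <- 1.5
  beta2 <- beta
  beta2[1] <- beta[1] - log(c0)
  # the likelihood itself cannot tell (theta, beta) from (c*theta, beta - ln c)
  ll_a <- log_likelihood(beta, theta, sim$catch, sim$design, validate = FALSE)
  ll_b <- log_likelihood(beta2, c0 * theta, sim$catch, sim$design,
                         validate = FALSE)
  expect_equal(ll_a, ll_b, tolerance = 1e-10)
  # but the scaled state is off the constraint surface and is rejected
  expect_error(log_likelihood(beta2, c0 * theta, sim$catch, sim$design),
               "scaled simplex")
  expect_error(log_prior(beta2, c0 * theta), "scaled simplex")
})

test_that("the log prior matches normal and scaled-Dirichlet arithmetic", {
  expect_equal(log_prior(c(0, 0, 0), 1), 3 * log(1 / (10 * sqrt(2 * pi))))
  # uniform Dirichlet: any two valid theta share the prior contribution
  expect_equal(log_prior(rep(0, 3), c(1.5, 0.5)),
               log_prior(rep(0, 3), c(0.2, 1.8)))
  # a single coefficient moved to 10 costs (10/10)^2 / 2
  d1 <- log_prior(c(10, 0), c(1, 1)) - log_prior(c(0, 0), c(1, 1))
  expect_equal(d1, -0.5)
  expect_error(log_prior(0, c(2, 1)), "scaled simplex")
  expect_error(log_prior(0, c(-0.5, 2.5)), "positive")
})

test_that("pointwise log-likelihood rows reproduce the totals", {
  fit <- small_fit()
  ll <- pointwise_loglik(fit)
  expect_equal(dim(ll), c(nrow(fit$draws), nrow(fit$catch)))
  # row sums equal the total log-likelihood draw by draw
  for (s in c(1, nrow(ll))) {
    beta <- fit$draws[s, fit$beta_cols]
    theta <- fit$draws[s, fit$theta_cols]
    cv <- fit$curves[[fit$realization[s]]]
    tot <- log_likelihood(beta, theta, fit$catch, fit$design, cv,
                          performance_floor = fit$control$performance_floor)
    expect_equal(sum(ll[s, ]), tot, tolerance = 1e-10)
  }
  # duplicating a record duplicates its column
  catch2 <- rbind(fit$catch, fit$catch[3, ])
  ll2 <- pointwise_loglik(fit, catch = catch2)
  expect_equal(ll2[, ncol(ll2)], ll2[, 3])
  expect_equal(ll2[, 3], ll[, 3])
})
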