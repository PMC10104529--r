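test_that("retained-draw bookkeeping follows the chain settings", {
  expect_equal(retained_draws(pga_control())$per_realization, 200)
  expect_equal(retained_draws(pga_control())$total, 20000)
  ctrl <- pga_control(n_iter = 300, n_burnin = 200, thin = 5,
                      n_realizations = 4)
  expect_equal(retained_draws(ctrl)$per_realization, 20)
  expect_equal(retained_draws(ctrl)$total, 80)
  expect_error(pga_control(n_iter = 100, n_burnin = 200), "n_burnin")
})

test_that("an ensemble aggregates the advertised number of tagged draws", {
  fit <- small_fit()
  per <- retained_draws(fit$control)$per_realization
  expect_equal(nrow(fit$draws), per * 3)
  expect_equal(fit$realization, rep(1:3, each = per))
  expect_length(fit$curves, 3)
  # every draw satisfies the parameter-state invariants
  theta <- fit$draws[, fit$theta_cols, drop = FALSE]
  expect_true(all(theta > 0))
  expect_true(all(abs(rowSums(theta) - 2) < 1e-10))
})

test_that("identical configuration and seed give a bit-identical ensemble", {
  sim <- small_survey()
  ctrl <- pga_control(n_iter = 250, n_burnin = 150, thin = 2,
                      n_realizations = 2, n_adapt = 200)
  f1 <- pga(sim$catch, sim$covariates, prior = sim$truth$prior,
            control = ctrl, seed = 31)
  f2 <- pga(sim$catch, sim$covariates, prior = sim$truth$prior,
            control = ctrl, seed = 31)
  expect_identical(f1$draws, f2$draws)
  expect_identical(lapply(f1$curves, unclass), lapply(f2$curves, unclass))
  f3 <- pga(sim$catch, sim$covariates, prior = sim$truth$prior,
            control = ctrl, seed = 32)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("flat-curve posterior means match the IRLS Poisson fit", {
  # single gear so beta is directly comparable to glm coefficients
  set.seed(61)
  d <- tiny_design(120, x = rnorm(120))
  catch <- tiny_catch(d, beta = c(0.8, 0.5), theta = 1, seed = 62)
  flat <- thermal_curve(-1e12, 1e3, 2e3)
  ctrl <- pga_control(n_iter = 2200, n_burnin = 1200, thin = 2, n_adapt = 500)
  draws <- fit_realization(d, catch, curve = flat, control = ctrl,
                           seed = 63)
  glm_fit <- stats::glm(catch$count ~ d$x,
                        offset = log(catch$effort_net_nights),
                        family = stats::poisson())
  for (j in 1:2) {
    ess <- max(coda::effectiveSize(coda::mcmc(draws[, j])), 10)
    mcse <- stats::sd(draws[, j]) / sqrt(ess)
    expect_lt(abs(mean(draws[, j]) - unname(coef(glm_fit))[j]), 3 * mcse)
  }
})

test_that("degenerate trait priors make the ensemble one long chain in distribution", {
  sim <- small_survey()
  pr0 <- thermal_prior(t_opt_mean = 24, t_opt_sd = 0, ct_max_mean = 31,
                       ct_max_sd = 0, ct_min_mean = 4)
  ctrl_ens <- pga_control(n_iter = 400, n_burnin = 200, thin = 2,
                          n_realizations = 5, n_adapt = 300)
  ctrl_one <- pga_control(n_iter = 1200, n_burnin = 200, thin = 2,
                          n_realizations = 1, n_adapt = 300)
  f_ens <- pga(sim$catch, sim$covariates, prior = pr0, control = ctrl_ens,
               seed = 71)
  f_one <- pga(sim$catch, sim$covariates, prior = pr0, control = ctrl_one,
               seed = 72)
  expect_equal(nrow(f_ens$draws), 500)
  expect_equal(nrow(f_one$draws), 500)
  ks <- stats::ks.test(f_ens$draws[, 1], f_one$draws[, 1])
  expect_gt(ks$p.value, 0.01)
})

test_that("prior-only sampling recovers the prior moments of beta", {
  sim <- small_survey()
  ctrl <- pga_control(n_iter = 4200, n_burnin = 200, thin = 1,
                      n_realizations = 1, n_adapt = 200, prior_only = TRUE,
                      beta_prior_sd = 10)
  fit <- pga(sim$catch, sim$covariates, prior = sim$truth$prior,
             control = ctrl, seed = 81)
  b1 <- fit$draws[, 1]
  ess <- max(coda::effectiveSize(coda::mcmc(b1)), 50)
  expect_lt(abs(mean(b1)), 4 * 10 / sqrt(ess))
  expect_lt(abs(stats::sd(b1) - 10), 3)
  # theta draws populate the scaled simplex uniformly enough to cover it
  th <- fit$draws[, fit$theta_cols[1]]
  expect_gt(max(th), 1.5)
  expect_lt(min(th), 0.5)
})

test_that("convergence diagnostics flag split chains and pass healthy ones", {
  fit <- small_fit()
  dg <- convergence_summary(fit)
  expect_true(all(c("realization", "parameter", "ess", "split_rhat",
                    "flagged") %in% names(dg)))
  expect_equal(nrow(dg), 3 * length(c(fit$beta_cols, fit$theta_cols)))
  # iid pseudo-draws: split-Rhat near 1
  set.seed(5)
  expect_lt(abs(pgabund:::split_rhat(rnorm(2000)) - 1), 0.02)
  # two halves with different means must be flagged
  broken <- c(rnorm(500, 0), rnorm(500, 3))
  expect_gt(pgabund:::split_rhat(broken), 1.05)
})

test_that("credible intervals shrink as the data grow tenfold", {
  ctrl <- pga_control(n_iter = 700, n_burnin = 300, thin = 2,
                      n_realizations = 1, n_adapt = 300)
  widths <- vapply(c(15, 150), function(n_lakes) {
    sim <- simulate_survey(n_lakes = n_lakes, n_years = 2, seed = 91)
    fit <- pga(sim$catch, sim$covariates, prior = sim$truth$prior,
               control = ctrl, seed = 92)
    q <- stats::quantile(fit$draws[, 2], c(0.025, 0.975))
    unname(diff(q))
  }, 0)
  expect_lt(widths[2], widths[1])
})
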