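test_that("a zero-degree scenario changes nothing", {
  fit <- small_fit()
  pr <- project(fit, delta_t = 0)
  expect_true(all(abs(pr$pct_change_mean) < 1e-10))
  expect_true(all(abs(pr$pct_change_lo) < 1e-10))
  expect_true(all(pr$n_excluded == 0))
  prn <- project(small_naive_fit(), delta_t = 0)
  expect_true(all(abs(prn$pct_change_mean) < 1e-10))
})

test_that("degenerate ensembles give the textbook performance summaries", {
  cv <- thermal_curve(4, 22, 30)
  d <- tiny_design(3, temp = c(22, 28, 35))
  fit <- fake_ensemble(rep(list(cv), 50), d)
  ps <- performance_summary(fit, delta_t = 0)
  expect_equal(ps$perf_mean, performance(c(22, 28, 35), cv))
  # at the optimum: mean 1 with CI [1, 1]
  expect_equal(unlist(ps[1, c("perf_mean", "perf_lo", "perf_hi")]),
               c(perf_mean = 1, perf_lo = 1, perf_hi = 1))
  # above ct_max: mean 0 (unfloored)
  expect_equal(ps$perf_mean[3], 0)
})

test_that("extinction probability counts the realizations whose ct_max is exceeded", {
  d1 <- tiny_design(1, temp = 20)
  cvs <- lapply(c(25, 27, 29), function(cm) thermal_curve(4, 22, cm))
  fit <- fake_ensemble(cvs, d1)
  # below every realization's ct_max
  expect_equal(unname(extinction_probability(fit, 0)), 0)
  # above all of them
  expect_equal(unname(extinction_probability(fit, 15)), 1)
  # crossing one of three
  expect_equal(unname(extinction_probability(fit, 6)), 1 / 3)
})

test_that("extinction probability matches the normal-tail Monte Carlo oracle", {
  pr <- thermal_prior(t_opt_mean = 20, t_opt_sd = 0, ct_max_mean = 26,
                      ct_max_sd = 1, ct_min_mean = 4)
  cvs <- sample_curves(pr, 10000, seed = 55)
  d1 <- tiny_design(1, temp = 26)   # lake sits exactly at the ct_max mean
  fit <- fake_ensemble(cvs, d1)
  p <- unname(extinction_probability(fit, 0))
  expect_lt(abs(p - 0.5), 0.015)
  # and it is non-decreasing in the warming offset
  ps <- vapply(0:4, function(dt) unname(extinction_probability(fit, dt)), 0)
  expect_true(all(diff(ps) >= 0))
})

test_that("percent change cancels the covariate term for a fixed curve", {
  cv <- thermal_curve(4, 22, 30)
  set.seed(77)
  d <- tiny_design(4, temp = c(20, 24, 27, 29), x = rnorm(4))
  beta_draws <- cbind(rnorm(40, 0.5, 0.2), rnorm(40, 0.3, 0.1))
  fit <- fake_ensemble(rep(list(cv), 40), d, beta_draws = beta_draws)
  pc <- percent_change(fit, delta_t = 2)
  expected <- 100 * (performance(c(20, 24, 27, 29) + 2, cv) /
                       performance(c(20, 24, 27, 29), cv) - 1)
  expect_equal(pc$pct_change_mean, expected, tolerance = 1e-10)
  # a lake pushed past ct_max loses everything: -100 exactly
  pc4 <- percent_change(fit, delta_t = 4)
  expect_equal(pc4$pct_change_mean[4], -100)
})

test_that("naive-model percent change matches its closed form", {
  fit <- small_naive_fit()
  dt <- 4
  pr <- project(fit, dt)
  st <- design_stats(fit$design)
  rows <- pgabund:::lake_rows(fit$design)
  z <- fit$design$temp[rows]
  dz <- dt / unname(st$sd["temp"])
  z2_cur <- (z^2 - unname(st$mean["temp_sq"])) / unname(st$sd["temp_sq"])
  z2_scn <- ((z + dz)^2 - unname(st$mean["temp_sq"])) / unname(st$sd["temp_sq"])
  bt <- fit$draws[, "temp"]
  bt2 <- fit$draws[, "temp_sq"]
  pct_draws <- 100 * (exp(outer(bt, dz * rep(1, length(z))) +
                            outer(bt2, z2_scn - z2_cur)) - 1)
  expect_equal(pr$pct_change_mean, colMeans(pct_draws), tolerance = 1e-8)
})

test_that("the naive model refuses extinction questions and never predicts zero", {
  fitn <- small_naive_fit()
  expect_error(extinction_probability(fitn, 4), "cannot provide")
  expect_error(performance_summary(fitn, 4), "physiologically guided")
  pr <- project(fitn, delta_t = 4)
  expect_true(all(is.na(pr$p_extinct)))
  expect_true(all(pr$pct_change_mean > -100))
  lam <- pgabund:::naive_scenario_lambda(fitn, 4)
  expect_true(all(lam > 0))
})

test_that("revived draws are excluded and doubly-extinct draws count as -100%", {
  # one realization already extinct at current temperature, one never extinct
  cv_lo <- thermal_curve(4, 16, 21)   # ct_max below current temp
  cv_hi <- thermal_curve(4, 22, 40)
  d <- tiny_design(1, temp = 25)
  fit <- fake_ensemble(c(rep(list(cv_lo), 30), rep(list(cv_hi), 10)), d)
  # cooling scenario revives the low-ct_max realizations: excluded
  pr_cool <- project(fit, delta_t = -5)
  expect_equal(pr_cool$n_excluded, 30)
  # warming keeps them extinct: each contributes exactly -100
  pr_warm <- project(fit, delta_t = 2)
  expect_equal(pr_warm$n_excluded, 0)
  expect_equal(pr_warm$pct_change_lo, -100)
})

test_that("the extirpation census counts flags overall and among inhabited lakes", {
  cv <- thermal_curve(4, 22, 30)
  d <- tiny_design(10, temp = c(rep(20, 5), rep(29, 5)))
  fit <- fake_ensemble(rep(list(cv), 30), d,
                       catch = data.frame(
                         lake_id = d$lake_id, gear = "gear1", year = d$year,
                         count = c(rep(1L, 4), rep(0L, 6)),
                         effort_net_nights = 1
                       ))
  pr <- project(fit, delta_t = 3)   # pushes the warm half past ct_max
  cs <- extirpation_census(pr)
  expect_equal(cs$n_lakes, c(10, 4))
  expect_equal(cs$n_flagged[1], 5)
  expect_equal(cs$pct_flagged[1], 50)
  # no flags under no warming
  cs0 <- extirpation_census(project(fit, 0))
  expect_equal(cs0$n_flagged, c(0, 0))
  # all flagged
  cs_all <- extirpation_census(project(fit, 15))
  expect_equal(cs_all$pct_flagged, c(100, 100))
  expect_error(extirpation_census(pr, inhabited = c("L0001", "NOPE")),
               "ID mismatch")
})
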