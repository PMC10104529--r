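# Synthetic survey generator: lakes, covariates, thermal regimes, and Poisson
# catches with known truth, emulating the structure of a statewide multi-gear
# inland-lake fish survey (tens to ~1,300 lakes, gill and trap nets,
# multi-year sampling, July surface temperatures mostly 20-30 degC).

#' Preset thermal-trait priors for three thermal guilds
#'
#' Cold-, cool-, and warm-water archetypes whose thermal optima are ordered
#' cold < cool < warm, patterned on laboratory tolerance values typical of
#' the corresponding inland-lake fish guilds (cisco-like, yellow-perch-like,
#' bluegill-like). The exact numbers are package defaults for simulation and
#' illustration, not literature estimates.
#'
#' @param guild One of `"cold"`, `"cool"`, `"warm"`.
#' @return A [thermal_prior()].
#' @export
species_archetype <- function(guild = c("cold", "cool", "warm")) {
  guild <- match.arg(guild)
  switch(guild,
    cold = thermal_prior(t_opt_mean = 16, t_opt_sd = 1.5,
                         ct_max_mean = 24, ct_max_sd = 1.5,
                         ct_min_mean = 2, species = "cold-water archetype"),
    cool = thermal_prior(t_opt_mean = 24, t_opt_sd = 1.5,
                         ct_max_mean = 31, ct_max_sd = 1.5,
                         ct_min_mean = 4, species = "cool-water archetype"),
    warm = thermal_prior(t_opt_mean = 29, t_opt_sd = 1.5,
                         ct_max_mean = 35, ct_max_sd = 1.5,
                         ct_min_mean = 6, species = "warm-water archetype")
  )
}

#' Simulate lake covariate records
#'
#' Generates one covariate row per lake-year: lognormal lake areas and
#' maximum depths, beta-distributed land use/cover proportions (all static
#' across years), and normally distributed July surface temperatures with a
#' lake-level mean plus small interannual noise; Secchi depth is lognormal
#' with small interannual noise. The default temperature regime (mean 24,
#' SD 2.5 degC) emulates a unimodal statewide distribution of mean July
#' surface temperatures spanning roughly 20-30 degC.
#'
#' @param n_lakes Number of lakes (>= 1).
#' @param n_years Sampling years per lake.
#' @param temp_mean,temp_sd Mean and SD of lake-level mean July temperature.
#' @param year_start First calendar year.
#' @param seed Optional seed.
#' @return A covariate data.frame suitable for [build_design()].
#' @export
simulate_lakes <- function(n_lakes, n_years = 3, temp_mean = 24,
                           temp_sd = 2.5, year_start = 2015, seed = NULL) {
  stopifnot(n_lakes >= 1, n_years >= 1)
  with_seed(seed, {
    lake_id <- sprintf("L%04d", seq_len(n_lakes))
    lake_temp <- stats::rnorm(n_lakes, temp_mean, temp_sd)
    area <- stats::rlnorm(n_lakes, meanlog = 4.5, sdlog = 1.1)       # ha
    depth <- stats::rlnorm(n_lakes, meanlog = 2.3, sdlog = 0.7)      # m
    secchi0 <- stats::rlnorm(n_lakes, meanlog = 0.8, sdlog = 0.45)   # m
    p_dev <- stats::rbeta(n_lakes, 1.2, 8)
    p_agr <- stats::rbeta(n_lakes, 1.5, 5)
    p_wet <- stats::rbeta(n_lakes, 2, 8)
    years <- year_start + seq_len(n_years) - 1L
    grid <- expand.grid(lake = seq_len(n_lakes), year = years,
                        KEEP.OUT.ATTRS = FALSE)
    n <- nrow(grid)
    data.frame(
      lake_id = lake_id[grid$lake],
      year = grid$year,
      temp_july = lake_temp[grid$lake] + stats::rnorm(n, 0, 0.6),
      area = area[grid$lake],
      max_depth = depth[grid$lake],
      secchi = pmax(0.2, secchi0[grid$lake] + stats::rnorm(n, 0, 0.15)),
      prop_developed = p_dev[grid$lake],
      prop_agriculture = p_agr[grid$lake],
      prop_wetland = p_wet[grid$lake]
    )
  })
}

#' Simulate survey catches from a known truth
#'
#' Forward-simulates the observation model: for every lake-year row of the
#' design and every gear, `count ~ Poisson(effort * theta_j * lambda)` with
#' `lambda = P(T) * exp(X beta)` under the supplied truth curve.
#'
#' @param design A `"pga"` [build_design()] result.
#' @param curve The generating [thermal_curve()].
#' @param beta True coefficient vector (intercept first), aligned with
#'   `design_matrix(design)`.
#' @param theta True catchability vector (positive, summing to its length);
#'   gears are labelled `gear1..gearJ` unless `gear_labels` is given.
#' @param effort Effort (net-nights) per record, recycled; default one net
#'   set for a 24-h period per sample.
#' @param gear_labels Optional gear names.
#' @param seed Optional seed.
#' @return A catch data.frame (`lake_id`, `gear`, `year`, `count`,
#'   `effort_net_nights`).
#' @export
simulate_catches <- function(design, curve, beta, theta = 1, effort = 1,
                             gear_labels = NULL, seed = NULL) {
  stopifnot(inherits(design, "pga_design"))
  if (any(effort <= 0)) stop_pga("effort must be positive")
  validate_theta(theta)
  J <- length(theta)
  gear_labels <- gear_labels %||%
    (if (J == 2) c("gillnet", "trapnet") else paste0("gear", seq_len(J)))
  lam <- relative_abundance(beta, design, curve)
  n <- nrow(design)
  out <- do.call(rbind, lapply(seq_len(J), function(j) {
    data.frame(lake_id = design$lake_id, gear = gear_labels[j],
               year = design$year, count = NA_integer_,
               effort_net_nights = rep_len(effort, n))
  }))
  mu <- out$effort_net_nights *
    rep(theta, each = n) * rep.int(lam, J)
  out$count <- with_seed(seed, stats::rpois(nrow(out), mu))
  out
}

#' Simulate a complete survey with known truth
#'
#' Convenience wrapper: simulates lakes ([simulate_lakes()]), builds the
#' physiologically guided design, and simulates catches
#' ([simulate_catches()]) under a truth curve taken from the prior means of
#' `species` (an archetype name or a [thermal_prior()]).
#'
#' @param n_lakes,n_years,temp_mean,temp_sd Passed to [simulate_lakes()].
#' @param species Archetype name or [thermal_prior()]; the truth curve is
#'   the curve at its prior means.
#' @param beta True coefficients (intercept first; length 7 for the default
#'   design).
#' @param theta True catchability vector.
#' @param effort Effort per record.
#' @param seed Master seed (sub-seeds are derived for lakes and catches).
#' @return A list with `catch`, `covariates`, `design`, and `truth` (a list
#'   with `beta`, `theta`, `curve`, `effort`, `seed`).
#' @export
simulate_survey <- function(n_lakes = 100, n_years = 3, temp_mean = 24,
                            temp_sd = 2.5, species = "cool",
                            beta = c(1, 0.3, -0.2, 0.2, -0.1, -0.1, 0.1),
                            theta = c(1.2, 0.8), effort = 1, seed = 1L) {
  prior <- if (inherits(species, "thermal_prior")) species else
    species_archetype(species)
  curve <- thermal_curve(ct_min = prior$ct_min_mean,
                         t_opt = prior$t_opt_mean,
                         ct_max = prior$ct_max_mean)
  seeds <- derive_seeds(seed, 2)
  covariates <- simulate_lakes(n_lakes, n_years, temp_mean, temp_sd,
                               seed = seeds[1])
  design <- build_design(covariates, model = "pga")
  catch <- simulate_catches(design, curve, beta, theta, effort,
                            seed = seeds[2])
  names(beta) <- colnames(design_matrix(design))
  list(catch = catch, covariates = covariates, design = design,
       truth = list(beta = beta, theta = theta, curve = curve, prior = prior,
                    effort = effort, seed = seed))
}

#' Truncated-temperature-range extrapolation experiment
#'
#' The central model-contrast experiment: both models are trained only on
#' lakes whose temperatures stay below a ceiling (emulating survey data that
#' do not span the species' tolerable range) and then projected under a
#' warming offset that pushes some lakes past the generating curve's
#' `ct_max`. The physiologically guided model can predict extinction there;
#' the naive quadratic-temperature model, with no thermal limit, predicts
#' persistence.
#'
#' @param n_lakes Number of simulated lakes (before truncation).
#' @param train_temp_ceiling Lakes whose lake-level temperature exceeds this
#'   value (degrees C) are dropped from training.
#' @param delta_t Warming offset for the projection.
#' @param species Archetype name or [thermal_prior()] used both as the truth
#'   (at prior means) and as the fitting prior.
#' @param beta,theta,effort Truth parameters, as in [simulate_survey()].
#' @param temp_mean,temp_sd,n_years Lake generation settings.
#' @param control A [pga_control()]; keep realizations/chains modest here.
#' @param seed Master seed.
#' @return A list of class `pga_trunc_experiment`: per-lake table (`lakes`:
#'   scenario temperature, truth percent change, both models' predicted
#'   percent change, the physiologically guided extinction probability, the
#'   naive scenario abundance), the fitted models, and bias summaries
#'   (`bias`: mean absolute error of percent-change predictions against
#'   truth, overall and for lakes beyond the generating `ct_max`).
#' @export
truncated_range_experiment <- function(n_lakes = 120, train_temp_ceiling = 26,
                                       delta_t = 4, species = "cool",
                                       beta = c(1, 0.3, -0.2, 0.2, -0.1, -0.1, 0.1),
                                       theta = c(1.2, 0.8), effort = 1,
                                       temp_mean = 24, temp_sd = 2.5,
                                       n_years = 2,
                                       control = pga_control(
                                         n_iter = 1200, n_burnin = 600,
                                         thin = 3, n_realizations = 8
                                       ),
                                       seed = 1L) {
  prior <- if (inherits(species, "thermal_prior")) species else
    species_archetype(species)
  truth_curve <- thermal_curve(ct_min = prior$ct_min_mean,
                               t_opt = prior$t_opt_mean,
                               ct_max = prior$ct_max_mean)
  if (train_temp_ceiling >= truth_curve$ct_max) {
    warning("training ceiling at or above the generating ct_max: ",
            "little extrapolation will occur")
  }
  seeds <- derive_seeds(seed, 4)
  covariates <- simulate_lakes(n_lakes, n_years, temp_mean, temp_sd,
                               seed = seeds[1])
  lake_mean_t <- tapply(covariates$temp_july, covariates$lake_id, mean)
  keep <- names(lake_mean_t)[lake_mean_t <= train_temp_ceiling]
  if (length(keep) == 0) stop_pga("ceiling too low: empty training set")
  covariates <- covariates[covariates$lake_id %in% keep, ]
  design <- build_design(covariates, model = "pga")
  catch <- simulate_catches(design, truth_curve, beta, theta, effort,
                            seed = seeds[2])

  fit_pga <- pga(catch, covariates, prior = prior, model = "pga",
                 control = control, seed = seeds[3])
  fit_naive <- pga(catch, covariates, model = "naive", control = control,
                   seed = seeds[4])

  proj_pga <- project(fit_pga, delta_t)
  proj_naive <- project(fit_naive, delta_t)

  rows <- lake_rows(design)
  temp_now <- attr(design, "temp_c")[rows]
  p_now <- performance(temp_now, truth_curve)
  p_scn <- performance(temp_now + delta_t, truth_curve)
  truth_pct <- ifelse(p_now > 0, 100 * (p_scn / p_now - 1), NA_real_)

  naive_lambda_scn <- naive_scenario_lambda(fit_naive, delta_t)[rows]

  lakes <- data.frame(
    lake_id = proj_pga$lake_id,
    temp_scenario = proj_pga$temp_scenario,
    beyond_ctmax = proj_pga$temp_scenario > truth_curve$ct_max,
    truth_pct_change = truth_pct,
    pga_pct_change = proj_pga$pct_change_mean,
    naive_pct_change = proj_naive$pct_change_mean,
    pga_p_extinct = proj_pga$p_extinct,
    naive_lambda_scenario = naive_lambda_scn
  )
  ok <- !is.na(lakes$truth_pct_change)
  bias <- data.frame(
    subset = c("all", "beyond_ctmax"),
    pga_abs_bias = c(
      mean(abs(lakes$pga_pct_change - lakes$truth_pct_change)[ok]),
      mean(abs(lakes$pga_pct_change - lakes$truth_pct_change)[ok & lakes$beyond_ctmax])
    ),
    naive_abs_bias = c(
      mean(abs(lakes$naive_pct_change - lakes$truth_pct_change)[ok]),
      mean(abs(lakes$naive_pct_change - lakes$truth_pct_change)[ok & lakes$beyond_ctmax])
    )
  )
  structure(list(lakes = lakes, bias = bias, truth_curve = truth_curve,
                 fit_pga = fit_pga, fit_naive = fit_naive,
                 delta_t = delta_t, train_temp_ceiling = train_temp_ceiling),
            class = "pga_trunc_experiment")
}

# Posterior-mean naive-model relative abundance under a scenario, per
# design row (used to show the naive model predicts persistence).
naive_scenario_lambda <- function(fit, delta_t) {
  stopifnot(fit$model == "naive")
  cov_scn <- fit$covariates
  cov_scn$temp_july <- cov_scn$temp_july + delta_t
  design_scn <- build_design(cov_scn, model = "naive",
                             stats = design_stats(fit$design))
  B <- fit$draws[, fit$beta_cols, drop = FALSE]
  colMeans(exp(B %*% t(design_matrix(design_scn))))
}

#' @export
print.pga_trunc_experiment <- function(x, ...) {
  cat(sprintf("Truncated-range extrapolation experiment (+%g degC, training ceiling %g degC)\n",
              x$delta_t, x$train_temp_ceiling))
  nb <- sum(x$lakes$beyond_ctmax)
  cat(sprintf("  %d of %d lakes pushed beyond the generating CT_max (%.1f degC)\n",
              nb, nrow(x$lakes), x$truth_curve$ct_max))
  if (nb > 0) {
    b <- x$lakes[x$lakes$beyond_ctmax, ]
    cat(sprintf("  beyond CT_max: PGA mean P(extinction) %.2f; naive mean scenario abundance %.3f (never 0)\n",
                mean(b$pga_p_extinct), mean(b$naive_lambda_scenario)))
  }
  cat("  mean absolute percent-change bias vs truth:\n")
  print(x$bias, row.names = FALSE)
  invisible(x)
}
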