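#' Control settings for MCMC fitting
#'
#' Defaults mirror the reference fitting scheme: per curve realization a
#' single chain of 3,000 iterations, the first 2,000 discarded as burn-in,
#' every 5th retained (200 draws), repeated over 100 curve realizations for
#' 20,000 aggregated draws.
#'
#' @param n_iter Total MCMC iterations per realization.
#' @param n_burnin Burn-in iterations discarded.
#' @param thin Thinning interval for the retained draws.
#' @param n_realizations Number of thermal-curve prior realizations to
#'   integrate over (physiologically guided model only).
#' @param n_adapt JAGS adaptation iterations (sampler tuning, separate from
#'   `n_iter`).
#' @param beta_prior_sd Prior SD for each coefficient (prior variance 100 by
#'   default).
#' @param performance_floor Floor for the performance scalar inside
#'   likelihood evaluation (see [relative_abundance()]).
#' @param theta_alpha Dirichlet concentration for the catchability prior
#'   (scalar, recycled over gears).
#' @param retry_max Re-initialization attempts if a realization fails to
#'   initialize.
#' @param prior_only Drop the likelihood and sample from the priors (for
#'   validation).
#' @param quiet Suppress JAGS progress output.
#' @return A list of class `pga_control`.
#' @export
pga_control <- function(n_iter = 3000, n_burnin = 2000, thin = 5,
                        n_realizations = 100, n_adapt = 1000,
                        beta_prior_sd = 10, performance_floor = 1e-10,
                        theta_alpha = 1, retry_max = 5, prior_only = FALSE,
                        quiet = TRUE) {
  stopifnot(n_burnin < n_iter, thin >= 1, n_realizations >= 1,
            beta_prior_sd > 0, performance_floor >= 0, theta_alpha > 0,
            n_adapt >= 0)
  structure(
    list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
         thin = as.integer(thin),
         n_realizations = as.integer(n_realizations),
         n_adapt = as.integer(n_adapt), beta_prior_sd = beta_prior_sd,
         performance_floor = performance_floor, theta_alpha = theta_alpha,
         retry_max = as.integer(retry_max), prior_only = isTRUE(prior_only),
         quiet = isTRUE(quiet)),
    class = "pga_control"
  )
}

#' Retained draws implied by control settings
#'
#' @param control A [pga_control()].
#' @return A list with `per_realization` and `total` retained draw counts.
#' @export
retained_draws <- function(control) {
  per <- (control$n_iter - control$n_burnin) %/% control$thin
  list(per_realization = per, total = per * control$n_realizations)
}

jags_model_string <- function(J, prior_only) {
  lik <- "
  for (n in 1:N) {
    C[n] ~ dpois(mu[n])
    log(mu[n]) <- off[n] + log(theta[gear[n]]) + inprod(X[n, ], beta)
  }"
  theta_block <- if (J > 1) "
  d ~ ddirch(alpha)
  for (j in 1:J) { theta[j] <- J * d[j] }" else "
  theta[1] <- 1"
  paste0("model {", if (!prior_only) lik, theta_block, "
  for (l in 1:L) { beta[l] ~ dnorm(0, prec_beta) }
}")
}

#' Fit one model realization by MCMC
#'
#' Runs a single chain for the Poisson catch model with the thermal curve
#' held fixed (or absent, for the naive variant) and returns the retained
#' draws. [pga()] calls this once per curve realization; it is exported for
#' oracle checks and custom integration schemes.
#'
#' @param design A [build_design()] result.
#' @param catch Catch table.
#' @param curve A fixed [thermal_curve()], or `NULL` for no curve.
#' @param control A [pga_control()].
#' @param seed Chain seed.
#' @param gear_levels Optional explicit gear ordering.
#' @return Matrix of retained draws, beta columns (named after the design
#'   columns, intercept first) then `theta[...]` columns.
#' @export
fit_realization <- function(design, catch, curve = NULL, control = pga_control(),
                            seed = 1L, gear_levels = NULL) {
  validate_catch(catch)
  X <- design_matrix(design)
  idx <- align_catch(catch, design)
  gi <- gear_index(catch, gear_levels)
  J <- length(gi$levels)
  L <- ncol(X)

  off <- log(catch$effort_net_nights)
  if (!is.null(curve)) {
    p <- performance(attr(design, "temp_c")[idx], curve)
    off <- off + log(pmax(p, control$performance_floor))
  }

  data <- list(N = nrow(catch), C = catch$count, off = off, gear = gi$index,
               X = X[idx, , drop = FALSE], L = L,
               prec_beta = 1 / control$beta_prior_sd^2)
  if (J > 1) {
    data$J <- J
    data$alpha <- rep(control$theta_alpha, J)
  }
  if (control$prior_only) {
    data <- data[intersect(names(data), c("L", "prec_beta", "J", "alpha"))]
  }

  model_txt <- jags_model_string(J, control$prior_only)
  vars <- c("beta", "theta")

  attempt <- 0L
  draws <- NULL
  while (is.null(draws)) {
    attempt <- attempt + 1L
    init_seed <- as.integer((seed + (attempt - 1L) * 7919L) %% 2147483647L)
    inits <- with_seed(init_seed, {
      ii <- list(beta = stats::rnorm(L, 0, 0.1),
                 .RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = init_seed)
      if (J > 1) {
        d0 <- rep(1, J) + abs(stats::rnorm(J, 0, 0.05))
        ii$d <- d0 / sum(d0)
      }
      ii
    })
    draws <- tryCatch({
      m <- withCallingHandlers(
        rjags::jags.model(textConnection(model_txt), data = data,
                          inits = inits, n.chains = 1,
                          n.adapt = control$n_adapt,
                          quiet = control$quiet),
        warning = function(w) {
          # short adaptation is deliberate at reduced chain lengths
          if (grepl("Adaptation incomplete", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
      if (control$n_burnin > 0) {
        stats::update(m, n.iter = control$n_burnin,
                      progress.bar = if (control$quiet) "none" else "text")
      }
      samp <- rjags::coda.samples(
        m, vars, n.iter = control$n_iter - control$n_burnin,
        thin = control$thin,
        progress.bar = if (control$quiet) "none" else "text"
      )
      as.matrix(samp[[1]])
    }, error = function(e) {
      if (attempt > control$retry_max) {
        stop_pga("MCMC failed after ", attempt, " initializations: ",
                 conditionMessage(e))
      }
      NULL
    })
  }

  beta_names <- colnames(X)
  theta_names <- paste0("theta[", gi$levels, "]")
  bcols <- grep("^beta", colnames(draws))
  tcols <- grep("^theta", colnames(draws))
  out <- cbind(draws[, bcols, drop = FALSE], draws[, tcols, drop = FALSE])
  colnames(out) <- c(beta_names, theta_names)
  attr(out, "gear_levels") <- gi$levels
  out
}

#' Fit a physiologically guided or naive Bayesian abundance model
#'
#' The main fitting interface. For `model = "pga"` the fit integrates over
#' uncertainty in the thermal performance curve: `n_realizations` curves are
#' drawn from the trait priors ([sample_curves()]), the Poisson catch model is
#' fitted by MCMC with each curve held fixed, and the per-realization
#' posteriors are aggregated (tagged by realization) into one ensemble. For
#' `model = "naive"` the curve is dropped, the design matrix carries
#' standardized temperature and temperature-squared columns, and a single
#' chain is run.
#'
#' @param catch Catch table (`lake_id`, `gear`, `year`, `count`,
#'   `effort_net_nights`), e.g. from [read_catch_csv()] or
#'   [simulate_survey()].
#' @param covariates Lake-year covariate table (see [build_design()]).
#' @param prior A [thermal_prior()]; required for `model = "pga"` unless
#'   `curves` is given.
#' @param model `"pga"` or `"naive"`.
#' @param curves Optional list of fixed [thermal_curve()] objects to use as
#'   the realizations (overrides `prior` sampling; its length overrides
#'   `control$n_realizations`).
#' @param control A [pga_control()].
#' @param seed Integer master seed; curve sampling and every chain derive
#'   their own sub-seeds from it, so a fit is bit-reproducible.
#' @param dry_run If `TRUE`, skip all sampling and return only the draw-count
#'   bookkeeping implied by `control` (a list, not a fit).
#' @return An object of class `pga_fit`: aggregated draws (`$draws`, one row
#'   per retained draw; beta columns then theta columns), the realization
#'   index of each draw (`$realization`), the curve realizations (`$curves`),
#'   the design and catch used, per-realization convergence diagnostics, and
#'   the control/seed for provenance.
#' @seealso [summary.pga_fit()], [predict.pga_fit()], [pga_loo()],
#'   [project()]
#' @export
pga <- function(catch, covariates, prior = NULL, model = c("pga", "naive"),
                curves = NULL, control = pga_control(), seed = 1L,
                dry_run = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(control, "pga_control"))
  cl <- match.call()

  if (model == "pga") {
    if (is.null(curves) && is.null(prior)) {
      stop_pga("the physiologically guided model needs `prior` (or `curves`)")
    }
  }

  n_real <- if (model == "naive") 1L else {
    if (!is.null(curves)) length(curves) else control$n_realizations
  }

  if (dry_run) {
    per <- retained_draws(control)$per_realization
    return(list(n_realizations = n_real, per_realization = per,
                total = per * n_real))
  }

  design <- build_design(covariates, model = model)
  validate_catch(catch)
  gi <- gear_index(catch)

  seeds <- derive_seeds(seed, n_real + 1L)
  if (model == "pga" && is.null(curves)) {
    curves <- sample_curves(prior, n_real, seed = seeds[n_real + 1L])
  }
  if (model == "naive") curves <- NULL

  per <- retained_draws(control)$per_realization
  draws_list <- vector("list", n_real)
  diag_list <- vector("list", n_real)
  for (r in seq_len(n_real)) {
    d <- fit_realization(design, catch,
                         curve = if (model == "pga") curves[[r]] else NULL,
                         control = control, seed = seeds[r],
                         gear_levels = gi$levels)
    draws_list[[r]] <- d
    diag_list[[r]] <- realization_diagnostics(d, r)
  }
  draws <- do.call(rbind, draws_list)
  rownames(draws) <- NULL
  realization <- rep(seq_len(n_real), each = per)

  n_beta <- ncol(design_matrix(design))
  fit <- structure(
    list(call = cl, model = model, draws = draws,
         realization = realization, curves = curves, prior = prior,
         design = design, catch = catch, covariates = covariates,
         control = control, seed = seed,
         gear_levels = gi$levels,
         beta_cols = seq_len(n_beta),
         theta_cols = n_beta + seq_along(gi$levels),
         diagnostics = do.call(rbind, diag_list)),
    class = "pga_fit"
  )
  fit
}
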