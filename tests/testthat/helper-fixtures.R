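# Shared fixtures, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A standard small synthetic survey with known truth.
small_survey <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- simulate_survey(n_lakes = 30, n_years = 2, seed = 42)
    }
    memo
  }
})

fast_control <- function(...) {
  pga_control(n_iter = 600, n_burnin = 300, thin = 3, n_realizations = 3,
              n_adapt = 300, ...)
}

# A cached small ensemble fit shared by tests that only need *a* fit.
small_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sim <- small_survey()
      memo <<- pga(sim$catch, sim$covariates, prior = sim$truth$prior,
                   model = "pga", control = fast_control(), seed = 7)
    }
    memo
  }
})

small_naive_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sim <- small_survey()
      memo <<- pga(sim$catch, sim$covariates, model = "naive",
                   control = fast_control(), seed = 8)
    }
    memo
  }
})

# Hand-built minimal design: one covariate column, one row per lake-year.
# Used by oracle tests that need a low-dimensional model.
tiny_design <- function(n, temp = rep(22, n), x = NULL, seed = 1) {
  x <- x %||% with_seed_test(seed, stats::rnorm(n))
  d <- data.frame(lake_id = sprintf("T%03d", seq_len(n)), year = 2020, x = x)
  attr(d, "stats") <- list(mean = c(x = 0), sd = c(x = 1))
  attr(d, "model") <- "pga"
  attr(d, "temp_c") <- temp
  class(d) <- c("pga_design", "data.frame")
  d
}

with_seed_test <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Poisson catches for a tiny design under known beta/theta and a flat curve.
tiny_catch <- function(design, beta = c(0.5, 0.4), theta = 1, effort = 1,
                       curve = NULL, seed = 2) {
  lam <- relative_abundance(beta, design, curve)
  J <- length(theta)
  gears <- paste0("gear", seq_len(J))
  out <- do.call(rbind, lapply(seq_len(J), function(j) {
    data.frame(lake_id = design$lake_id, gear = gears[j], year = design$year,
               count = NA_integer_, effort_net_nights = effort)
  }))
  mu <- out$effort_net_nights * rep(theta, each = nrow(design)) *
    rep.int(lam, J)
  out$count <- with_seed_test(seed, stats::rpois(nrow(out), mu))
  out
}

# A synthetic ensemble "fit" assembled directly from curves and fixed draws,
# for projection oracles that need many curve realizations without MCMC.
fake_ensemble <- function(curves, design, beta_draws = NULL, theta = 1,
                          catch = NULL) {
  n_real <- length(curves)
  r <- ncol(design_matrix(design))
  beta_draws <- beta_draws %||%
    matrix(0, n_real, r, dimnames = list(NULL, colnames(design_matrix(design))))
  draws <- cbind(beta_draws,
                 matrix(theta, n_real, length(theta), byrow = TRUE))
  colnames(draws) <- c(colnames(design_matrix(design)),
                       paste0("theta[gear", seq_along(theta), "]"))
  catch <- catch %||% data.frame(
    lake_id = design$lake_id, gear = "gear1", year = design$year,
    count = 1L, effort_net_nights = 1
  )
  structure(
    list(call = NULL, model = "pga", draws = draws,
         realization = seq_len(n_real), curves = curves, prior = NULL,
         design = design, catch = catch, covariates = NULL,
         control = pga_control(n_realizations = n_real), seed = 1L,
         gear_levels = paste0("gear", seq_along(theta)),
         beta_cols = seq_len(r), theta_cols = r + seq_along(theta),
         diagnostics = data.frame()),
    class = "pga_fit"
  )
}

example_curve <- function() thermal_curve(ct_min = 4, t_opt = 22, ct_max = 30)
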