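# Poisson catch likelihood, priors, and pointwise contributions.
#
# Catch C_ijt in lake i with gear j in year t is modelled as
#   C_ijt ~ Poisson(E_ijt * theta_j * lambda_it),
# where E_ijt is sampling effort (net-nights), theta is the gear catchability
# vector constrained to sum to the number of gears J, and relative abundance
# lambda_it = P(T_it) * exp(X_it beta) (physiologically guided model) or
# exp(X_it beta) with quadratic temperature columns in X (naive model).

validate_catch <- function(catch) {
  need <- c("lake_id", "gear", "year", "count", "effort_net_nights")
  missing <- setdiff(need, names(catch))
  if (length(missing)) {
    stop_pga("catch table is missing columns: ", paste(missing, collapse = ", "))
  }
  cnt <- catch$count
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad)) {
    stop_pga("counts must be non-negative integers; offending rows: ",
             paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(is.na(catch$effort_net_nights) | catch$effort_net_nights <= 0)
  if (length(bad)) {
    stop_pga("effort_net_nights must be positive; offending rows: ",
             paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(catch)
}

# Map each catch record to its design row; error on unmatched lake-years.
align_catch <- function(catch, design) {
  key_d <- paste(design$lake_id, design$year, sep = "\r")
  key_c <- paste(catch$lake_id, catch$year, sep = "\r")
  idx <- match(key_c, key_d)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop_pga("data misalignment: catch rows without a covariate row: ",
             paste(utils::head(bad, 5), collapse = ", "))
  }
  idx
}

gear_index <- function(catch, gear_levels = NULL) {
  gear_levels <- gear_levels %||% sort(unique(as.character(catch$gear)))
  j <- match(as.character(catch$gear), gear_levels)
  if (anyNA(j)) stop_pga("catch contains gears absent from gear_levels")
  list(index = j, levels = gear_levels)
}

validate_theta <- function(theta, tol = 1e-8) {
  if (any(theta <= 0)) stop_pga("theta must be strictly positive")
  J <- length(theta)
  if (abs(sum(theta) - J) > tol) {
    stop_pga("theta is off the scaled simplex: sum(theta) must equal ", J)
  }
  invisible(theta)
}

#' Relative abundance for each lake-year
#'
#' Computes `lambda_it = P(T_it) * exp(X_it beta)` for the physiologically
#' guided model (supply `curve`), or `exp(X_it beta)` for the naive model
#' (leave `curve = NULL`; its design must carry the temperature columns).
#' Inside likelihood evaluation the performance scalar is floored at a small
#' positive value so that a curve realization placing an observed positive
#' catch above `ct_max` cannot make the log-likelihood minus infinity;
#' predictions use the unfloored scalar (`performance_floor = 0`).
#'
#' @param beta Coefficient vector, intercept first, aligned with
#'   `design_matrix(design)`.
#' @param design A [build_design()] result.
#' @param curve A [thermal_curve()] or `NULL`.
#' @param performance_floor Lower bound applied to the performance scalar.
#' @return Numeric vector of lambda values, one per design row.
#' @export
relative_abundance <- function(beta, design, curve = NULL,
                               performance_floor = 0) {
  X <- design_matrix(design)
  if (length(beta) != ncol(X)) {
    stop_pga("beta has length ", length(beta), " but the design (with ",
             "intercept) has ", ncol(X), " columns")
  }
  lam <- exp(drop(X %*% beta))
  if (!is.null(curve)) {
    p <- performance(attr(design, "temp_c"), curve)
    lam <- pmax(p, performance_floor) * lam
  }
  lam
}

#' Poisson log-likelihood of a catch table
#'
#' Sum over records of the Poisson log-pmf with intensity
#' `mu = effort * theta_gear * lambda_it`.
#'
#' @inheritParams relative_abundance
#' @param theta Catchability vector, one entry per gear (ordered as
#'   `gear_levels`, by default the sorted unique gears); must be positive and
#'   sum to the number of gears.
#' @param catch Catch table with columns `lake_id`, `gear`, `year`, `count`,
#'   `effort_net_nights`.
#' @param gear_levels Optional explicit gear ordering for `theta`.
#' @param validate Check the theta constraint (disable only for algebraic
#'   diagnostics).
#' @return The total log-likelihood (scalar).
#' @export
log_likelihood <- function(beta, theta, catch, design, curve = NULL,
                           performance_floor = 1e-10, gear_levels = NULL,
                           validate = TRUE) {
  validate_catch(catch)
  if (validate) validate_theta(theta)
  gi <- gear_index(catch, gear_levels)
  idx <- align_catch(catch, design)
  lam <- relative_abundance(beta, design, curve, performance_floor)
  mu <- catch$effort_net_nights * theta[gi$index] * lam[idx]
  sum(stats::dpois(catch$count, mu, log = TRUE))
}

#' Log prior density of the model parameters
#'
#' Independent normal priors `beta_l ~ N(0, beta_prior_sd^2)` plus the scaled
#' Dirichlet prior on the catchability vector: `theta = J * d` with
#' `d ~ Dirichlet(alpha)`; with the default `alpha = 1` the Dirichlet is
#' uniform on the simplex and contributes only a constant.
#'
#' @inheritParams log_likelihood
#' @param beta_prior_sd Prior SD of each coefficient.
#' @param alpha Dirichlet concentration vector (default all ones).
#' @return The log prior density (scalar).
#' @export
log_prior <- function(beta, theta, beta_prior_sd = 10, alpha = NULL) {
  validate_theta(theta)
  J <- length(theta)
  alpha <- alpha %||% rep(1, J)
  stopifnot(length(alpha) == J, all(alpha > 0))
  lp_beta <- sum(stats::dnorm(beta, 0, beta_prior_sd, log = TRUE))
  d <- theta / J
  lp_theta <- if (J > 1) {
    sum((alpha - 1) * log(d)) + lgamma(sum(alpha)) - sum(lgamma(alpha)) -
      (J - 1) * log(J)
  } else {
    0
  }
  lp_beta + lp_theta
}

#' Pointwise log-likelihood matrix of a fitted model
#'
#' Entry (s, n) is the Poisson log-pmf of catch record n under posterior draw
#' s; draws from the physiologically guided ensemble use their own curve
#' realization's performance scalar (floored as during fitting). Feeds the
#' PSIS-LOO machinery.
#'
#' @param fit A [pga()] fit.
#' @param catch,design Data to evaluate on; default the training data stored
#'   in the fit.
#' @return A draws-by-records numeric matrix.
#' @export
pointwise_loglik <- function(fit, catch = NULL, design = NULL) {
  stopifnot(inherits(fit, "pga_fit"))
  catch <- catch %||% fit$catch
  design <- design %||% fit$design
  validate_catch(catch)
  X <- design_matrix(design)
  idx <- align_catch(catch, design)
  gi <- gear_index(catch, fit$gear_levels)

  B <- fit$draws[, fit$beta_cols, drop = FALSE]
  TH <- fit$draws[, fit$theta_cols, drop = FALSE]
  S <- nrow(B)
  N <- nrow(catch)

  log_mu <- B %*% t(X[idx, , drop = FALSE])              # S x N
  log_mu <- log_mu + log(TH[, gi$index, drop = FALSE])
  log_mu <- sweep(log_mu, 2, log(catch$effort_net_nights), "+")
  if (fit$model == "pga") {
    temp <- attr(design, "temp_c")[idx]
    floor <- fit$control$performance_floor
    logP <- matrix(vapply(fit$curves, function(cv) {
      log(pmax(performance(temp, cv), floor))
    }, numeric(N)), nrow = N)                             # N x n_real
    log_mu <- log_mu + t(logP)[fit$realization, , drop = FALSE]
  }
  mu <- exp(log_mu)
  ll <- matrix(stats::dpois(rep(catch$count, each = S), as.vector(mu),
                            log = TRUE), S, N)
  dimnames(ll) <- NULL
  ll
}
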