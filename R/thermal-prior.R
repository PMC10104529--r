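#' Specify literature-derived priors on thermal tolerance traits
#'
#' Thermal tolerance traits measured in laboratory studies carry real
#' between-study uncertainty. The model represents it with independent normal
#' priors on the thermal optimum `t_opt` and the critical thermal maximum
#' `ct_max` (means and SDs compiled from the literature), while the critical
#' thermal minimum enters only through its mean, which fixes the Gaussian-limb
#' scale sigma via [derive_sigma()].
#'
#' `sigma_sd` is an optional hook for placing a (truncated-normal) prior on
#' sigma itself; it is 0 by default, i.e. sigma is fixed.
#'
#' @param t_opt_mean,t_opt_sd Prior mean and SD of the thermal optimum, deg C.
#' @param ct_max_mean,ct_max_sd Prior mean and SD of the critical thermal
#'   maximum, deg C.
#' @param ct_min_mean Mean critical thermal minimum, deg C (no prior; used to
#'   derive sigma and as the fixed lower trait of every curve realization).
#' @param species Optional species label.
#' @param sigma_sd Optional SD for a prior on sigma (0 = fixed, the default).
#' @return An object of class `thermal_prior`.
#' @examples
#' pr <- thermal_prior(t_opt_mean = 24, t_opt_sd = 1.5,
#'                     ct_max_mean = 31, ct_max_sd = 1.5,
#'                     ct_min_mean = 4, species = "cool-water archetype")
#' curves <- sample_curves(pr, n = 5, seed = 1)
#' @export
thermal_prior <- function(t_opt_mean, t_opt_sd, ct_max_mean, ct_max_sd,
                          ct_min_mean, species = "", sigma_sd = 0) {
  num <- c(t_opt_mean, t_opt_sd, ct_max_mean, ct_max_sd, ct_min_mean, sigma_sd)
  if (any(!is.finite(num))) stop_pga("prior parameters must be finite numbers")
  if (t_opt_sd < 0 || ct_max_sd < 0 || sigma_sd < 0) {
    stop_pga("prior SDs must be non-negative")
  }
  if (!(ct_min_mean < t_opt_mean && t_opt_mean < ct_max_mean)) {
    stop_pga("prior means must satisfy ct_min_mean < t_opt_mean < ct_max_mean")
  }
  structure(
    list(t_opt_mean = t_opt_mean, t_opt_sd = t_opt_sd,
         ct_max_mean = ct_max_mean, ct_max_sd = ct_max_sd,
         ct_min_mean = ct_min_mean, species = species, sigma_sd = sigma_sd),
    class = "thermal_prior"
  )
}

#' @export
print.thermal_prior <- function(x, ...) {
  cat(sprintf("Thermal trait priors%s:\n",
              if (nzchar(x$species)) paste0(" [", x$species, "]") else ""))
  cat(sprintf("  T_opt  ~ N(%.2f, sd %.2f) degC\n", x$t_opt_mean, x$t_opt_sd))
  cat(sprintf("  CT_max ~ N(%.2f, sd %.2f) degC, truncated to T_opt < CT_max\n",
              x$ct_max_mean, x$ct_max_sd))
  cat(sprintf("  CT_min fixed at %.2f degC; sigma %s at %.3f degC\n",
              x$ct_min_mean,
              if (x$sigma_sd > 0) sprintf("~ N(., sd %.3f)", x$sigma_sd) else "fixed",
              derive_sigma(x$t_opt_mean, x$ct_min_mean)))
  invisible(x)
}

#' Sample thermal-curve realizations from trait priors
#'
#' Draws `n` realizations of the thermal performance curve by sampling
#' `t_opt` and `ct_max` from their independent normal priors and jointly
#' rejecting (redrawing both) any pair with `t_opt >= ct_max`. Sigma is fixed
#' at `derive_sigma(t_opt_mean, ct_min_mean)` for every realization (unless
#' the prior carries `sigma_sd > 0`), and `ct_min` is fixed at its mean.
#'
#' @param prior A [thermal_prior()].
#' @param n Number of realizations (>= 1).
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @param max_tries Cap on total draws per requested realization; if the
#'   acceptance rate is so low that the cap is hit, the priors are considered
#'   incompatible and an error is signalled.
#' @return A list of `n` [thermal_curve()] objects.
#' @export
sample_curves <- function(prior, n, seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(prior, "thermal_prior"))
  if (n < 1) stop_pga("n must be >= 1")
  n <- as.integer(n)
  sigma0 <- derive_sigma(prior$t_opt_mean, prior$ct_min_mean)
  with_seed(seed, {
    t_opt <- ct_max <- sigma <- numeric(0)
    tries <- 0L
    while (length(t_opt) < n) {
      need <- n - length(t_opt)
      tries <- tries + need
      if (tries > max_tries * n) {
        stop_pga("incompatible priors: could not satisfy t_opt < ct_max ",
                 "within the rejection-sampling cap")
      }
      to <- stats::rnorm(need, prior$t_opt_mean, prior$t_opt_sd)
      cm <- stats::rnorm(need, prior$ct_max_mean, prior$ct_max_sd)
      ok <- to < cm
      # curves must also keep ct_min below t_opt for validity
      ok <- ok & (to > prior$ct_min_mean)
      t_opt <- c(t_opt, to[ok])
      ct_max <- c(ct_max, cm[ok])
    }
    t_opt <- t_opt[seq_len(n)]
    ct_max <- ct_max[seq_len(n)]
    sigma <- if (prior$sigma_sd > 0) {
      abs(stats::rnorm(n, sigma0, prior$sigma_sd))
    } else {
      rep(sigma0, n)
    }
    lapply(seq_len(n), function(i) {
      thermal_curve(ct_min = prior$ct_min_mean, t_opt = t_opt[i],
                    ct_max = ct_max[i], sigma = sigma[i])
    })
  })
}

#' Read a species thermal-trait prior from a YAML or JSON config
#'
#' Expected keys: `t_opt_mean`, `t_opt_sd`, `ct_max_mean`, `ct_max_sd`,
#' `ct_min_mean`, and optionally `species` and `sigma_sd`.
#'
#' @param path Path to a YAML (or JSON) file.
#' @return A [thermal_prior()].
#' @export
read_thermal_prior <- function(path) {
  if (!file.exists(path)) stop_pga("prior config not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- c("t_opt_mean", "t_opt_sd", "ct_max_mean", "ct_max_sd", "ct_min_mean")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop_pga("prior config is missing keys: ", paste(missing, collapse = ", "))
  }
  thermal_prior(
    t_opt_mean = cfg$t_opt_mean, t_opt_sd = cfg$t_opt_sd,
    ct_max_mean = cfg$ct_max_mean, ct_max_sd = cfg$ct_max_sd,
    ct_min_mean = cfg$ct_min_mean,
    species = cfg$species %||% "",
    sigma_sd = cfg$sigma_sd %||% 0
  )
}

curves_to_frame <- function(curves) {
  do.call(rbind, lapply(seq_along(curves), function(i) {
    cbind(realization = i, as.data.frame(curves[[i]]))
  }))
}
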