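# S3 methods for pga_fit objects.

#' @export
print.pga_fit <- function(x, ...) {
  rd <- retained_draws(x$control)
  cat(sprintf("%s Bayesian Poisson abundance model\n",
              if (x$model == "pga") "Physiologically guided" else "Naive (quadratic temperature)"))
  cat(sprintf("  %d catch records, %d lake-years, %d gear(s)\n",
              nrow(x$catch), nrow(x$design), length(x$gear_levels)))
  if (x$model == "pga") {
    cat(sprintf("  %d curve realizations x %d retained draws = %d aggregated draws\n",
                length(x$curves), rd$per_realization, nrow(x$draws)))
  } else {
    cat(sprintf("  %d retained draws (single chain)\n", nrow(x$draws)))
  }
  cat("\nPosterior means:\n")
  print(round(colMeans(x$draws), 3))
  invisible(x)
}

#' Summarize a fitted abundance model
#'
#' Posterior means, SDs, and central 95% credible intervals over the
#' aggregated draws, plus convergence flags.
#'
#' @param object A [pga()] fit.
#' @param ... Unused.
#' @return A data.frame of class `summary.pga_fit`.
#' @export
summary.pga_fit <- function(object, ...) {
  d <- object$draws
  qs <- t(apply(d, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  out <- data.frame(parameter = colnames(d), mean = colMeans(d),
                    sd = apply(d, 2, stats::sd),
                    `2.5%` = qs[, 1], `50%` = qs[, 2], `97.5%` = qs[, 3],
                    check.names = FALSE, row.names = NULL)
  n_flag <- sum(object$diagnostics$flagged, na.rm = TRUE)
  attr(out, "n_flagged") <- n_flag
  attr(out, "model") <- object$model
  class(out) <- c("summary.pga_fit", "data.frame")
  out
}

#' @export
print.summary.pga_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (%s model):\n", attr(x, "model")))
  df <- x
  class(df) <- "data.frame"
  df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  nf <- attr(x, "n_flagged")
  if (nf > 0) {
    cat(sprintf("Warning: %d realization-parameter chains flagged (split-Rhat > 1.05)\n", nf))
  }
  invisible(x)
}

#' @export
coef.pga_fit <- function(object, ...) {
  colMeans(object$draws[, object$beta_cols, drop = FALSE])
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws `nsim` replicate catch tables: for each replicate a posterior draw
#' is selected at random and counts are simulated from
#' Poisson(effort * theta_gear * lambda).
#'
#' @param object A [pga()] fit.
#' @param nsim Number of replicate catch tables.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` integer vectors of simulated counts (aligned with
#'   `object$catch` rows).
#' @export
simulate.pga_fit <- function(object, nsim = 1, seed = NULL, ...) {
  catch <- object$catch
  design <- object$design
  idx <- align_catch(catch, design)
  gi <- gear_index(catch, object$gear_levels)
  with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      s <- sample.int(nrow(object$draws), 1)
      beta <- object$draws[s, object$beta_cols]
      theta <- object$draws[s, object$theta_cols]
      curve <- if (object$model == "pga") object$curves[[object$realization[s]]]
      lam <- relative_abundance(beta, design, curve,
                                object$control$performance_floor)
      mu <- catch$effort_net_nights * theta[gi$index] * lam[idx]
      stats::rpois(length(mu), mu)
    })
  })
}

#' Pearson residuals of a fitted model
#'
#' `(count - mu_hat) / sqrt(mu_hat)` with `mu_hat` the posterior-mean Poisson
#' intensity of each record.
#'
#' @param object A [pga()] fit.
#' @param ... Unused.
#' @return Numeric vector, one residual per catch record.
#' @export
residuals.pga_fit <- function(object, ...) {
  mu <- fitted(object)
  (object$catch$count - mu) / sqrt(mu)
}

#' @export
fitted.pga_fit <- function(object, ...) {
  catch <- object$catch
  design <- object$design
  idx <- align_catch(catch, design)
  gi <- gear_index(catch, object$gear_levels)
  S <- nrow(object$draws)
  mu <- numeric(nrow(catch))
  for (r in unique(object$realization)) {
    rows <- which(object$realization == r)
    beta_m <- colMeans(object$draws[rows, object$beta_cols, drop = FALSE])
    theta_m <- colMeans(object$draws[rows, object$theta_cols, drop = FALSE])
    curve <- if (object$model == "pga") object$curves[[r]]
    lam <- relative_abundance(beta_m, design, curve,
                              object$control$performance_floor)
    mu <- mu + length(rows) / S *
      (catch$effort_net_nights * theta_m[gi$index] * lam[idx])
  }
  mu
}

#' Plot a fitted abundance model
#'
#' `type = "curves"` (physiologically guided fits) draws the ensemble of
#' thermal-curve realizations with the observed lake temperatures as a rug;
#' `type = "trace"` draws trace plots of the aggregated draws for each
#' parameter.
#'
#' @param x A [pga()] fit.
#' @param type `"curves"` or `"trace"`.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.pga_fit <- function(x, type = c("curves", "trace"), ...) {
  type <- match.arg(type)
  if (type == "curves") {
    if (x$model != "pga") stop_pga("curve plot requires a physiologically guided fit")
    temps <- attr(x$design, "temp_c")
    lo <- min(vapply(x$curves, `[[`, 0, "ct_min")) - 2
    hi <- max(vapply(x$curves, `[[`, 0, "ct_max")) + 2
    grid <- seq(lo, hi, length.out = 300)
    graphics::plot(NA, xlim = c(lo, hi), ylim = c(0, 1),
                   xlab = "Temperature (°C)", ylab = "Performance", ...)
    for (cv in x$curves) {
      graphics::lines(grid, performance(grid, cv),
                      col = grDevices::adjustcolor("steelblue", 0.25))
    }
    pbar <- rowMeans(vapply(x$curves, function(cv) performance(grid, cv),
                            numeric(length(grid))))
    graphics::lines(grid, pbar, lwd = 2)
    graphics::rug(temps)
  } else {
    d <- x$draws
    np <- ncol(d)
    old <- graphics::par(mfrow = c(min(np, 3), 1), mar = c(3, 4, 1, 1))
    on.exit(graphics::par(old))
    for (j in seq_len(min(np, 3))) {
      graphics::plot(d[, j], type = "l", ylab = colnames(d)[j], xlab = "draw")
    }
  }
  invisible(x)
}
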