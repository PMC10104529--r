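# PSIS-LOO cross-validation: Pareto-smoothed importance sampling estimates of
# the expected log pointwise predictive density (ELPD) and LOO-IC = -2*ELPD.

# Generalized Pareto fit to positive exceedances via the Zhang-Stephens
# weighted-profile-likelihood estimator, with the weak shape prior commonly
# used in the PSIS literature (pulls k toward 0.5 with prior weight 10).
gpd_fit <- function(x, prior_weight = 10, min_grid = 30L, weak_prior = TRUE) {
  x <- sort(x)
  n <- length(x)
  m <- min_grid + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  if (xstar <= 0) xstar <- mean(x[x > 0])
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_b <- vapply(b, function(bi) -mean(log1p(-bi * x)), 0)
  l_b <- n * (log(b / k_b) + k_b - 1)
  w <- exp(l_b - log_sum_exp(l_b))
  b_hat <- sum(b * w)
  k <- mean(log1p(-b_hat * x))
  sigma <- -k / b_hat
  if (weak_prior) k <- (n * k + prior_weight * 0.5) / (n + prior_weight)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smooth a vector of raw importance log-weights
#'
#' Fits a generalized Pareto distribution to the largest
#' `M = ceiling(min(0.2 S, 3 sqrt(S)))` importance ratios, replaces them with
#' the expected order statistics of the fitted distribution, truncates at the
#' raw maximum, and returns the smoothed log-weights together with the Pareto
#' shape diagnostic k-hat. A degenerate (all-equal) tail is returned
#' unchanged with `khat = -Inf`.
#'
#' @param lw Numeric vector of raw log-weights (one per posterior draw).
#' @param tail_frac Fraction of draws eligible for the tail fit.
#' @return A list with `log_weights` (same length/order as `lw`) and `khat`.
#' @export
psis_smooth <- function(lw, tail_frac = 0.2) {
  S <- length(lw)
  if (any(!is.finite(lw))) stop_pga("log-weights must be finite")
  M <- ceiling(min(tail_frac * S, 3 * sqrt(S)))
  if (S < 25 || M < 5) {
    stop_pga("insufficient sample for PSIS: need enough draws for a ",
             "tail of at least 5 (got S = ", S, ")")
  }
  shift <- max(lw)
  w <- exp(lw - shift)
  ord <- order(w)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- w[ord[S - M]]
  exc <- w[tail_ids] - cutoff
  if (stats::sd(exc) < 1e-30) {
    return(list(log_weights = lw, khat = -Inf))
  }
  fit <- gpd_fit(exc)
  p <- (seq_len(M) - 0.5) / M
  q <- cutoff + qgpd(p, fit$k, fit$sigma)
  q <- pmin(q, w[ord[S]])          # never exceed the raw maximum
  w_new <- w
  w_new[tail_ids] <- q             # tail_ids are in ascending weight order
  list(log_weights = log(w_new) + shift, khat = fit$k)
}

#' PSIS-LOO from a pointwise log-likelihood matrix
#'
#' For each record the raw leave-one-out importance log-ratios are the
#' negated pointwise log-likelihoods; they are Pareto-smoothed
#' ([psis_smooth()]), self-normalized, and combined into the pointwise ELPD.
#' `loo_ic = -2 * elpd`; lower is better.
#'
#' @param ll Draws-by-records matrix of pointwise log-likelihoods (e.g. from
#'   [pointwise_loglik()]).
#' @return An object of class `pga_loo`: `elpd`, `elpd_se`, `loo_ic`,
#'   `p_loo`, `n_bad_k` (records with k-hat > 0.7), and a `pointwise`
#'   data.frame (`elpd_n`, `lpd_n`, `khat`, `warn_k`).
#' @export
psis_loo <- function(ll) {
  if (!is.matrix(ll) || any(!is.finite(ll))) {
    stop_pga("pointwise log-likelihood must be a finite matrix; a -Inf here ",
             "usually means the performance floor was disabled upstream")
  }
  S <- nrow(ll)
  N <- ncol(ll)
  elpd_n <- lpd_n <- khat <- numeric(N)
  for (n in seq_len(N)) {
    sm <- psis_smooth(-ll[, n])
    lwn <- sm$log_weights - log_sum_exp(sm$log_weights)
    elpd_n[n] <- log_sum_exp(lwn + ll[, n])
    lpd_n[n] <- log_sum_exp(ll[, n]) - log(S)
    khat[n] <- sm$khat
  }
  elpd <- sum(elpd_n)
  structure(
    list(elpd = elpd,
         elpd_se = sqrt(N * stats::var(elpd_n)),
         loo_ic = -2 * elpd,
         p_loo = sum(lpd_n - elpd_n),
         n_bad_k = sum(khat > 0.7),
         n_records = N, n_draws = S,
         pointwise = data.frame(elpd_n = elpd_n, lpd_n = lpd_n, khat = khat,
                                warn_k = khat > 0.7)),
    class = "pga_loo"
  )
}

#' PSIS-LOO cross-validation of a fitted model
#'
#' Computes the pointwise log-likelihood of the fit's training records over
#' the aggregated posterior draws (ensemble draws use their own realization's
#' curve) and runs [psis_loo()] on it.
#'
#' @param fit A [pga()] fit.
#' @return A `pga_loo` object.
#' @export
pga_loo <- function(fit) {
  psis_loo(pointwise_loglik(fit))
}

#' @export
print.pga_loo <- function(x, ...) {
  cat("PSIS-LOO cross-validation\n")
  cat(sprintf("  elpd   %10.2f  (SE %.2f)\n", x$elpd, x$elpd_se))
  cat(sprintf("  p_loo  %10.2f\n", x$p_loo))
  cat(sprintf("  loo_ic %10.2f   (lower is better)\n", x$loo_ic))
  if (x$n_bad_k > 0) {
    cat(sprintf("  warning: %d of %d records with Pareto k-hat > 0.7\n",
                x$n_bad_k, x$n_records))
  }
  invisible(x)
}

#' Compare two fits by PSIS-LOO
#'
#' @param a,b `pga_loo` objects (or [pga()] fits, which are run through
#'   [pga_loo()]) computed on the same records.
#' @param labels Length-2 character labels for the report.
#' @return An object of class `pga_loo_compare` with per-model elpd / loo_ic,
#'   the elpd difference (a - b) and its SE, and the lower-loo-ic verdict.
#' @export
pga_compare <- function(a, b, labels = c("model_a", "model_b")) {
  if (inherits(a, "pga_fit")) a <- pga_loo(a)
  if (inherits(b, "pga_fit")) b <- pga_loo(b)
  stopifnot(inherits(a, "pga_loo"), inherits(b, "pga_loo"))
  if (a$n_records != b$n_records) {
    stop_pga("fits reference different record sets (",
             a$n_records, " vs ", b$n_records, ")")
  }
  dif <- a$pointwise$elpd_n - b$pointwise$elpd_n
  N <- a$n_records
  structure(
    list(labels = labels,
         elpd = c(a$elpd, b$elpd),
         loo_ic = c(a$loo_ic, b$loo_ic),
         elpd_diff = a$elpd - b$elpd,
         elpd_diff_se = sqrt(N * stats::var(dif)),
         better = labels[which.min(c(a$loo_ic, b$loo_ic))]),
    class = "pga_loo_compare"
  )
}

#' @export
print.pga_loo_compare <- function(x, ...) {
  cat("PSIS-LOO model comparison (lower loo_ic is better)\n")
  for (i in 1:2) {
    cat(sprintf("  %-10s elpd %10.2f   loo_ic %10.2f\n",
                x$labels[i], x$elpd[i], x$loo_ic[i]))
  }
  cat(sprintf("  elpd difference (%s - %s): %.2f (SE %.2f)\n",
              x$labels[1], x$labels[2], x$elpd_diff, x$elpd_diff_se))
  cat(sprintf("  preferred: %s\n", x$better))
  invisible(x)
}
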