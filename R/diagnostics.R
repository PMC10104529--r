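# Convergence diagnostics for the per-realization chains.

# Split-Rhat of a single chain: compare the two halves as if they were
# independent chains (rank-free classic formulation).
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  a <- x[seq_len(half)]
  b <- x[(n - half + 1):n]
  W <- (stats::var(a) + stats::var(b)) / 2
  B <- half * stats::var(c(mean(a), mean(b)))
  if (W < 1e-300) return(if (B < 1e-300) 1 else Inf)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

realization_diagnostics <- function(draws, realization) {
  params <- colnames(draws)
  ess <- tryCatch(as.numeric(coda::effectiveSize(coda::mcmc(draws))),
                  error = function(e) rep(NA_real_, ncol(draws)))
  rhat <- apply(draws, 2, split_rhat)
  data.frame(realization = realization, parameter = params,
             mean = colMeans(draws), sd = apply(draws, 2, stats::sd),
             ess = ess, split_rhat = rhat,
             flagged = !is.na(rhat) & rhat > 1.05,
             row.names = NULL)
}

#' Per-realization convergence summary of a fit
#'
#' Split-Rhat (the single chain split into halves) and effective sample size
#' for every parameter in every realization's chain; chains with
#' split-Rhat > 1.05 are flagged.
#'
#' @param fit A [pga()] fit.
#' @return A data.frame (realization, parameter, mean, sd, ess, split_rhat,
#'   flagged).
#' @export
convergence_summary <- function(fit) {
  stopifnot(inherits(fit, "pga_fit"))
  fit$diagnostics
}

#' Export posterior traces to CSV
#'
#' Writes one row per retained draw: realization index, draw index within
#' realization, and every parameter column. Intended for external trace-plot
#' inspection.
#'
#' @param fit A [pga()] fit.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_traces <- function(fit, path) {
  stopifnot(inherits(fit, "pga_fit"))
  per <- retained_draws(fit$control)$per_realization
  out <- data.frame(realization = fit$realization,
                    draw = rep(seq_len(per), length.out = nrow(fit$draws)),
                    fit$draws, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
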