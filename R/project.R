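# Climate-scenario projection: per-lake thermal performance scalars, percent
# change in relative abundance, and extinction probabilities under warming
# offsets applied to mean July surface water temperature.

# One design row per lake: the most recent sampled year.
lake_rows <- function(design) {
  ids <- sort(unique(design$lake_id))
  vapply(ids, function(lk) {
    i <- which(design$lake_id == lk)
    i[which.max(design$year[i])]
  }, 0L)
}

#' Project a fitted model under a warming scenario
#'
#' Applies a temperature offset `delta_t` (degrees C, added to mean July
#' surface temperature before any standardization; all other covariates held
#' at current values) and summarizes, per lake (its most recent sampled
#' year):
#'
#' * the thermal performance scalar under the scenario (posterior mean and
#'   central 95% credible interval) — physiologically guided fits only, using
#'   the unfloored curve so extirpation (performance exactly 0) is
#'   representable;
#' * percent change in relative abundance, computed per posterior draw as
#'   `100 * (lambda_scenario - lambda_current) / lambda_current` and then
#'   summarized (posterior mean, 2.5% and 97.5% quantiles). A draw that is
#'   extinct under the scenario contributes -100%; a draw already extinct
#'   under current conditions contributes -100% if still extinct, and is
#'   excluded (and counted in `n_excluded`) if the scenario would revive it;
#' * the posterior probability of extinction: the fraction of draws whose
#'   realization places the scenario temperature above `ct_max`. Lakes with
#'   extinction probability > 0.90 are flagged as extirpated. Both quantities
#'   are undefined for the naive model (reported as `NA`; see
#'   [extinction_probability()]).
#'
#' @param fit A [pga()] fit.
#' @param delta_t Warming offset in degrees C (e.g. 0-4).
#' @return A data.frame of class `pga_projection`, one row per lake, with
#'   attributes `delta_t`, `model` and `inhabited` (lakes with at least one
#'   positive observed catch).
#' @export
project <- function(fit, delta_t = 0) {
  stopifnot(inherits(fit, "pga_fit"), is.finite(delta_t))
  design <- fit$design
  rows <- lake_rows(design)
  lake_id <- design$lake_id[rows]
  year <- design$year[rows]
  temp <- attr(design, "temp_c")[rows]
  I <- length(rows)
  B <- fit$draws[, fit$beta_cols, drop = FALSE]
  S <- nrow(B)

  if (fit$model == "pga") {
    Xb <- exp(B %*% t(design_matrix(design)[rows, , drop = FALSE]))  # S x I
    n_real <- length(fit$curves)
    p_cur_r <- matrix(vapply(fit$curves, function(cv) performance(temp, cv),
                             numeric(I)), nrow = I)                  # I x R
    p_scn_r <- matrix(vapply(fit$curves,
                             function(cv) performance(temp + delta_t, cv),
                             numeric(I)), nrow = I)
    ext_r <- matrix(vapply(fit$curves,
                           function(cv) (temp + delta_t) > cv$ct_max,
                           logical(I)), nrow = I)
    P_cur <- t(p_cur_r)[fit$realization, , drop = FALSE]             # S x I
    P_scn <- t(p_scn_r)[fit$realization, , drop = FALSE]
    lam_cur <- P_cur * Xb
    lam_scn <- P_scn * Xb
    perf_mean <- colMeans(P_scn)
    perf_lo <- apply(P_scn, 2, stats::quantile, 0.025)
    perf_hi <- apply(P_scn, 2, stats::quantile, 0.975)
    real_w <- tabulate(fit$realization, n_real) / S
    p_ext <- as.numeric(real_w %*% t(ext_r))
  } else {
    cov_scn <- fit$covariates
    cov_scn$temp_july <- cov_scn$temp_july + delta_t
    design_scn <- build_design(cov_scn, model = "naive",
                               stats = design_stats(design))
    lam_cur <- exp(B %*% t(design_matrix(design)[rows, , drop = FALSE]))
    lam_scn <- exp(B %*% t(design_matrix(design_scn)[rows, , drop = FALSE]))
    perf_mean <- perf_lo <- perf_hi <- rep(NA_real_, I)
    p_ext <- rep(NA_real_, I)
  }

  pct <- 100 * (lam_scn - lam_cur) / lam_cur
  zero_cur <- lam_cur == 0
  if (any(zero_cur)) {
    pct[zero_cur & lam_scn == 0] <- -100   # extinct now and under scenario
    pct[zero_cur & lam_scn > 0] <- NA      # revived: undefined change, drop
  }
  n_excluded <- colSums(is.na(pct))
  pct_mean <- colMeans(pct, na.rm = TRUE)
  pct_lo <- apply(pct, 2, stats::quantile, 0.025, na.rm = TRUE)
  pct_hi <- apply(pct, 2, stats::quantile, 0.975, na.rm = TRUE)

  out <- data.frame(
    lake_id = lake_id, year = year, temp_c = temp,
    temp_scenario = temp + delta_t,
    perf_mean = perf_mean, perf_lo = perf_lo, perf_hi = perf_hi,
    pct_change_mean = pct_mean, pct_change_lo = pct_lo, pct_change_hi = pct_hi,
    p_extinct = p_ext,
    extirpated = if (fit$model == "pga") p_ext > 0.90 else NA,
    n_excluded = n_excluded,
    row.names = NULL
  )
  pos <- tapply(fit$catch$count, fit$catch$lake_id, function(x) any(x > 0))
  attr(out, "inhabited") <- names(pos)[pos]
  attr(out, "delta_t") <- delta_t
  attr(out, "model") <- fit$model
  class(out) <- c("pga_projection", "data.frame")
  out
}

#' @export
print.pga_projection <- function(x, ...) {
  dt <- attr(x, "delta_t")
  cat(sprintf("Scenario projection (%s model, +%g degC), %d lakes\n",
              attr(x, "model"), dt, nrow(x)))
  cat(sprintf("  percent change in relative abundance: mean of lake means %.1f%% (range %.1f%% to %.1f%%)\n",
              mean(x$pct_change_mean), min(x$pct_change_mean),
              max(x$pct_change_mean)))
  if (attr(x, "model") == "pga") {
    cat(sprintf("  lakes flagged extirpated (P(extinction) > 0.90): %d (%.0f%%)\n",
                sum(x$extirpated), 100 * mean(x$extirpated)))
  }
  invisible(x)
}

#' Per-lake thermal performance summary under a scenario
#'
#' Posterior mean and central 95% credible interval of the (unfloored)
#' thermal performance scalar evaluated at each lake's scenario temperature.
#'
#' @inheritParams project
#' @return A data.frame (lake_id, temp_scenario, perf_mean, perf_lo,
#'   perf_hi).
#' @export
performance_summary <- function(fit, delta_t = 0) {
  if (fit$model != "pga") {
    stop_pga("performance scalars are defined only for the physiologically ",
             "guided model")
  }
  pr <- project(fit, delta_t)
  pr[c("lake_id", "temp_scenario", "perf_mean", "perf_lo", "perf_hi")]
}

#' Posterior extinction probability per lake under a scenario
#'
#' The fraction of aggregated posterior draws whose curve realization places
#' the lake's scenario temperature above the critical thermal maximum.
#' Undefined for the naive model, which has no thermal limit and never
#' predicts extirpation: calling this on a naive fit is an error.
#'
#' @inheritParams project
#' @return Named numeric vector of probabilities (one per lake).
#' @export
extinction_probability <- function(fit, delta_t = 0) {
  if (fit$model != "pga") {
    stop_pga("the naive model cannot provide estimates of extinction ",
             "probability")
  }
  pr <- project(fit, delta_t)
  stats::setNames(pr$p_extinct, pr$lake_id)
}

#' Per-lake percent change in relative abundance under a scenario
#'
#' @inheritParams project
#' @return A data.frame (lake_id, pct_change_mean, pct_change_lo,
#'   pct_change_hi, n_excluded).
#' @export
percent_change <- function(fit, delta_t = 0) {
  pr <- project(fit, delta_t)
  pr[c("lake_id", "pct_change_mean", "pct_change_lo", "pct_change_hi",
       "n_excluded")]
}

#' Census of thermally unsuitable lakes under a scenario
#'
#' Counts and percentages of lakes flagged extirpated (posterior extinction
#' probability > 0.90), overall and within the currently inhabited subset
#' (by default, lakes with at least one positive observed catch in the
#' training data).
#'
#' @param projection A [project()] result from a physiologically guided fit.
#' @param inhabited Character vector of currently inhabited lake ids; must be
#'   a subset of the projected lakes.
#' @return A data.frame with rows `all_lakes` and `inhabited_lakes`
#'   (n_lakes, n_flagged, pct_flagged).
#' @export
extirpation_census <- function(projection, inhabited = NULL) {
  stopifnot(inherits(projection, "pga_projection"))
  if (attr(projection, "model") != "pga") {
    stop_pga("extirpation census requires a physiologically guided projection")
  }
  inhabited <- inhabited %||% attr(projection, "inhabited")
  ids <- as.character(projection$lake_id)
  if (!all(inhabited %in% ids)) {
    stop_pga("ID mismatch: inhabited lakes are not a subset of projected lakes")
  }
  flag <- stats::setNames(projection$extirpated, ids)
  census_row <- function(sel) {
    n <- length(sel)
    f <- sum(flag[sel])
    data.frame(n_lakes = n, n_flagged = f,
               pct_flagged = if (n > 0) 100 * f / n else 0)
  }
  out <- rbind(census_row(ids), census_row(as.character(inhabited)))
  out <- cbind(subset = c("all_lakes", "inhabited_lakes"), out)
  out
}

#' Predict from a fitted abundance model
#'
#' `type = "projection"` (default) returns the full [project()] scenario
#' summary for the warming offset `delta_t`. `type = "lambda"` returns the
#' posterior-mean relative abundance for every training lake-year row.
#'
#' @param object A [pga()] fit.
#' @param delta_t Warming offset in degrees C.
#' @param type `"projection"` or `"lambda"`.
#' @param ... Unused.
#' @export
predict.pga_fit <- function(object, delta_t = 0,
                            type = c("projection", "lambda"), ...) {
  type <- match.arg(type)
  if (type == "projection") return(project(object, delta_t))
  design <- object$design
  B <- object$draws[, object$beta_cols, drop = FALSE]
  lam <- exp(B %*% t(design_matrix(design)))    # S x rows
  if (object$model == "pga") {
    temp <- attr(design, "temp_c")
    pr <- matrix(vapply(object$curves,
                        function(cv) performance(temp + delta_t, cv),
                        numeric(nrow(design))), nrow = nrow(design))
    lam <- lam * t(pr)[object$realization, , drop = FALSE]
  }
  stats::setNames(colMeans(lam), paste(design$lake_id, design$year, sep = ":"))
}
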