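# Readers, writers, and run-level entry points. CSV is the tabular
# interchange (headered), YAML for configs, JSON for reports.

#' Read and validate a survey catch CSV
#'
#' Required columns: `lake_id`, `gear`, `year`, `count`,
#' `effort_net_nights`. Counts must be non-negative integers and efforts
#' positive; violations are reported with row numbers rather than silently
#' coerced.
#'
#' @param path CSV path.
#' @return A validated catch data.frame.
#' @export
read_catch_csv <- function(path) {
  if (!file.exists(path)) stop_pga("catch file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_catch(df)
  df
}

#' Read and validate a lake-year covariate CSV
#'
#' Required columns: `lake_id`, `year`, `temp_july`, `area`, `max_depth`,
#' `secchi`, `prop_developed`, `prop_agriculture`, `prop_wetland`.
#'
#' @param path CSV path.
#' @return A validated covariate data.frame.
#' @export
read_covariates_csv <- function(path) {
  if (!file.exists(path)) stop_pga("covariate file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_covariates(df)
  df
}

#' Persist a fitted model as a directory of plain-text artifacts
#'
#' Writes `draws.csv` (realization, draw, parameters), `realizations.csv`
#' (curve parameters per realization, physiologically guided fits),
#' `catch.csv`, `covariates.csv`, `diagnostics.csv`, `stats.json`
#' (standardization statistics), and `config.yml` (model, control, seed,
#' prior, package version) — a provenance block sufficient to reproduce the
#' fit bit-identically.
#'
#' @param fit A [pga()] fit.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(fit, dir) {
  stopifnot(inherits(fit, "pga_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_traces(fit, file.path(dir, "draws.csv"))
  if (fit$model == "pga") {
    utils::write.csv(curves_to_frame(fit$curves),
                     file.path(dir, "realizations.csv"), row.names = FALSE)
  }
  utils::write.csv(fit$catch, file.path(dir, "catch.csv"), row.names = FALSE)
  utils::write.csv(fit$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$diagnostics, file.path(dir, "diagnostics.csv"),
                   row.names = FALSE)
  write_design_stats(fit$design, file.path(dir, "stats.json"))
  cfg <- list(model = fit$model, seed = fit$seed,
              control = unclass(fit$control),
              prior = if (!is.null(fit$prior)) unclass(fit$prior),
              package_version = as.character(utils::packageVersion("pgabund")))
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Reload a persisted fit
#'
#' Reconstructs a `pga_fit` from a [write_ensemble()] directory. The design
#' matrix is rebuilt from the stored covariates and standardization
#' statistics, so downstream projections and LOO reproduce the original fit
#' exactly.
#'
#' @param dir Directory written by [write_ensemble()].
#' @return A `pga_fit`.
#' @export
read_ensemble <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yml"))
  control <- do.call(pga_control, cfg$control[setdiff(names(cfg$control), NULL)])
  covariates <- read_covariates_csv(file.path(dir, "covariates.csv"))
  catch <- read_catch_csv(file.path(dir, "catch.csv"))
  design <- build_design(covariates, model = cfg$model)
  tr <- utils::read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  realization <- tr$realization
  draws <- as.matrix(tr[setdiff(names(tr), c("realization", "draw"))])
  curves <- NULL
  if (cfg$model == "pga") {
    rc <- utils::read.csv(file.path(dir, "realizations.csv"))
    curves <- lapply(seq_len(nrow(rc)), function(i) {
      thermal_curve(rc$ct_min[i], rc$t_opt[i], rc$ct_max[i], rc$sigma[i])
    })
  }
  prior <- if (!is.null(cfg$prior)) do.call(thermal_prior, cfg$prior)
  gear_levels <- sort(unique(as.character(catch$gear)))
  n_beta <- ncol(design_matrix(design))
  diagnostics <- utils::read.csv(file.path(dir, "diagnostics.csv"))
  structure(
    list(call = NULL, model = cfg$model, draws = draws,
         realization = realization, curves = curves, prior = prior,
         design = design, catch = catch, covariates = covariates,
         control = control, seed = cfg$seed, gear_levels = gear_levels,
         beta_cols = seq_len(n_beta),
         theta_cols = n_beta + seq_along(gear_levels),
         diagnostics = diagnostics),
    class = "pga_fit"
  )
}

#' Write per-lake scenario results to CSV
#'
#' @param projection A [project()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_projection_csv <- function(projection, path) {
  utils::write.csv(as.data.frame(projection), path, row.names = FALSE)
  invisible(path)
}

#' Run a fit from file inputs (CLI backend)
#'
#' Reads the catch and covariate CSVs (and the species prior YAML for the
#' physiologically guided model), fits [pga()], and persists the result with
#' [write_ensemble()].
#'
#' @param catch_csv,covariates_csv,prior_yaml Input paths.
#' @param model `"pga"` or `"naive"`.
#' @param out_dir Output directory.
#' @param control A [pga_control()].
#' @param seed Integer seed.
#' @return The fit, invisibly.
#' @export
run_fit <- function(catch_csv, covariates_csv, prior_yaml = NULL,
                    model = c("pga", "naive"), out_dir,
                    control = pga_control(), seed = 1L) {
  model <- match.arg(model)
  catch <- read_catch_csv(catch_csv)
  covariates <- read_covariates_csv(covariates_csv)
  prior <- if (!is.null(prior_yaml)) read_thermal_prior(prior_yaml)
  fit <- pga(catch, covariates, prior = prior, model = model,
             control = control, seed = seed)
  write_ensemble(fit, out_dir)
  message("wrote ensemble (", nrow(fit$draws), " draws) to ", out_dir)
  invisible(fit)
}

#' Project a persisted fit under warming scenarios (CLI backend)
#'
#' @param fit_dir A [write_ensemble()] directory.
#' @param delta_t Numeric vector of warming offsets (degrees C).
#' @param out_dir Output directory; one CSV per offset plus a census CSV for
#'   physiologically guided fits.
#' @return Invisible list of projections.
#' @export
run_project <- function(fit_dir, delta_t = 0:4, out_dir) {
  fit <- read_ensemble(fit_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  projections <- lapply(delta_t, function(dt) {
    pr <- project(fit, dt)
    write_projection_csv(pr, file.path(out_dir,
                                       sprintf("scenario_plus%g.csv", dt)))
    pr
  })
  if (fit$model == "pga") {
    census <- do.call(rbind, Map(function(pr, dt) {
      cbind(delta_t = dt, extirpation_census(pr))
    }, projections, delta_t))
    utils::write.csv(census, file.path(out_dir, "extirpation_census.csv"),
                     row.names = FALSE)
  }
  invisible(projections)
}

#' Compare two persisted fits by PSIS-LOO (CLI backend)
#'
#' @param fit_dir_a,fit_dir_b [write_ensemble()] directories fitted to the
#'   same records.
#' @param out_json Optional path for a JSON report.
#' @return The [pga_compare()] result, invisibly.
#' @export
run_compare <- function(fit_dir_a, fit_dir_b, out_json = NULL) {
  a <- read_ensemble(fit_dir_a)
  b <- read_ensemble(fit_dir_b)
  if (nrow(a$catch) != nrow(b$catch) ||
      !all(a$catch$count == b$catch$count)) {
    stop_pga("fits reference different catch records")
  }
  cmp <- pga_compare(a, b, labels = c(basename(fit_dir_a),
                                      basename(fit_dir_b)))
  if (!is.null(out_json)) {
    rep <- list(
      models = list(
        list(label = cmp$labels[1], elpd = cmp$elpd[1], loo_ic = cmp$loo_ic[1]),
        list(label = cmp$labels[2], elpd = cmp$elpd[2], loo_ic = cmp$loo_ic[2])
      ),
      elpd_diff = cmp$elpd_diff, elpd_diff_se = cmp$elpd_diff_se,
      preferred = cmp$better
    )
    jsonlite::write_json(rep, out_json, auto_unbox = TRUE, digits = NA)
  }
  print(cmp)
  invisible(cmp)
}
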