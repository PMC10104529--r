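#' Trailing 5-year rolling mean of an annual series
#'
#' Time-varying lake conditions (July surface temperature, water clarity) are
#' summarized at each sampling year by the mean of the available annual values
#' in the trailing 5-year window (the sample year and the four preceding
#' years). A partial window uses whatever years are available; a window with
#' no observed year at all is an error.
#'
#' @param values Numeric vector of annual values.
#' @param years Integer vector of calendar years, same length as `values`.
#' @param target_year The sampling year.
#' @return The windowed mean.
#' @examples
#' rolling_mean_5yr(1:5, 2015:2019, 2019) # 3
#' @export
rolling_mean_5yr <- function(values, years, target_year) {
  stopifnot(length(values) == length(years))
  keep <- years >= target_year - 4 & years <= target_year & !is.na(values)
  if (!any(keep)) {
    stop_pga("missing covariate: no observed value in the 5-year window ",
             "ending ", target_year)
  }
  mean(values[keep])
}

logit <- function(p) log(p / (1 - p))

covariate_columns <- c("temp_july", "area", "max_depth", "secchi",
                       "prop_developed", "prop_agriculture", "prop_wetland")

validate_covariates <- function(covariates) {
  need <- c("lake_id", "year", covariate_columns)
  missing <- setdiff(need, names(covariates))
  if (length(missing)) {
    stop_pga("covariate table is missing columns: ",
             paste(missing, collapse = ", "))
  }
  props <- c("prop_developed", "prop_agriculture", "prop_wetland")
  for (p in props) {
    bad <- which(covariates[[p]] < 0 | covariates[[p]] > 1)
    if (length(bad)) {
      stop_pga("invalid input: ", p, " outside [0, 1] at rows ",
               paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  for (p in c("area", "max_depth", "secchi")) {
    bad <- which(covariates[[p]] <= 0)
    if (length(bad)) {
      stop_pga("invalid input: non-positive ", p, " at rows ",
               paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (anyDuplicated(covariates[c("lake_id", "year")])) {
    stop_pga("duplicated (lake_id, year) rows in covariate table")
  }
  invisible(covariates)
}

#' Standardize the columns of a numeric table
#'
#' Centers and scales each column to mean 0, SD 1. When `stats` (a list with
#' elements `mean` and `sd`, named vectors over columns) is supplied, those
#' training statistics are applied instead of recomputing — the prediction /
#' scenario mode. A constant column (zero SD) is a non-informative covariate
#' and is an error.
#'
#' @param table A data.frame of numeric columns.
#' @param stats Optional training statistics to reuse.
#' @return The standardized data.frame, with the statistics used attached as
#'   `attr(, "stats")`.
#' @export
standardize <- function(table, stats = NULL) {
  if (!is.null(stats)) {
    missing <- setdiff(names(table), names(stats$mean))
    if (length(missing)) {
      stop_pga("training stats lack columns: ", paste(missing, collapse = ", "))
    }
    mu <- stats$mean[names(table)]
    sd <- stats$sd[names(table)]
  } else {
    mu <- vapply(table, mean, 0)
    sd <- vapply(table, stats::sd, 0)
    zero <- names(table)[sd < 1e-12]
    if (length(zero)) {
      stop_pga("non-informative covariate (zero SD): ",
               paste(zero, collapse = ", "))
    }
    names(mu) <- names(sd) <- names(table)
  }
  out <- as.data.frame(Map(function(x, m, s) (x - m) / s, table, mu, sd))
  names(out) <- names(table)
  attr(out, "stats") <- list(mean = mu, sd = sd)
  out
}

#' Build the model design matrix from raw lake covariates
#'
#' Applies the covariate pipeline: trailing 5-year rolling means for July
#' temperature and Secchi depth; natural-log transforms for lake area and
#' maximum depth; logit transforms (with proportions clamped to
#' `[logit_eps, 1 - logit_eps]`) for the land use/cover proportions; then
#' standardization of every column to mean 0, SD 1.
#'
#' Temperature is handled differently by the two model variants. The
#' physiologically guided (`"pga"`) design excludes temperature — it acts only
#' through the thermal performance scalar. The `"naive"` design appends the
#' standardized temperature and its square (the squared column is itself
#' standardized, so every design column is on a common scale).
#'
#' Supplying `stats` (from a previous training design) puts the builder in
#' prediction mode: the stored means/SDs are reused so scenario matrices are
#' on the training scale. Temperature offsets for warming scenarios must be
#' applied to `temp_july` in degrees C *before* calling this function.
#'
#' @param covariates Data.frame with columns `lake_id`, `year`, `temp_july`,
#'   `area`, `max_depth`, `secchi`, `prop_developed`, `prop_agriculture`,
#'   `prop_wetland` (one row per lake-year).
#' @param model `"pga"` or `"naive"`.
#' @param stats Optional training statistics (see [design_stats()]).
#' @param logit_eps Boundary clamp for proportions before the logit.
#' @return A data.frame of class `pga_design` with key columns `lake_id`,
#'   `year` and the standardized covariate columns; the rolled temperature in
#'   degrees C is kept in `attr(, "temp_c")`, the training statistics in
#'   `attr(, "stats")`.
#' @export
build_design <- function(covariates, model = c("pga", "naive"), stats = NULL,
                         logit_eps = 1e-3) {
  model <- match.arg(model)
  covariates <- as.data.frame(covariates)
  validate_covariates(covariates)

  roll <- function(col) {
    vapply(seq_len(nrow(covariates)), function(i) {
      lk <- covariates$lake_id == covariates$lake_id[i]
      rolling_mean_5yr(covariates[[col]][lk], covariates$year[lk],
                       covariates$year[i])
    }, 0)
  }
  temp_c <- roll("temp_july")
  secchi5 <- roll("secchi")

  clamp <- function(p) pmin(pmax(p, logit_eps), 1 - logit_eps)
  raw <- data.frame(
    log_area = log(covariates$area),
    log_depth = log(covariates$max_depth),
    secchi = secchi5,
    logit_developed = logit(clamp(covariates$prop_developed)),
    logit_agriculture = logit(clamp(covariates$prop_agriculture)),
    logit_wetland = logit(clamp(covariates$prop_wetland))
  )
  if (model == "naive") raw$temp <- temp_c

  if (!is.null(stats)) {
    first <- standardize(raw, stats)
  } else {
    first <- standardize(raw)
  }
  st <- attr(first, "stats")

  if (model == "naive") {
    sq <- data.frame(temp_sq = first$temp^2)
    if (!is.null(stats)) {
      sq <- standardize(sq, stats)
    } else {
      sq <- standardize(sq)
    }
    st$mean <- c(st$mean, attr(sq, "stats")$mean)
    st$sd <- c(st$sd, attr(sq, "stats")$sd)
    first$temp_sq <- sq$temp_sq
  }

  out <- cbind(covariates[c("lake_id", "year")], first)
  attr(out, "stats") <- st
  attr(out, "model") <- model
  attr(out, "logit_eps") <- logit_eps
  attr(out, "temp_c") <- temp_c
  class(out) <- c("pga_design", "data.frame")
  out
}

#' Extract the numeric model matrix from a design
#'
#' @param design A [build_design()] result.
#' @param intercept Prepend a column of ones (the default; the coefficient
#'   vector includes an intercept).
#' @return A numeric matrix, one row per lake-year.
#' @export
design_matrix <- function(design, intercept = TRUE) {
  cols <- setdiff(names(design), c("lake_id", "year"))
  X <- as.matrix(design[cols])
  storage.mode(X) <- "double"
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

#' Training statistics of a design (for scenario reuse)
#'
#' @param design A [build_design()] result.
#' @return A list with named vectors `mean` and `sd`.
#' @export
design_stats <- function(design) attr(design, "stats")

#' Write / read design standardization statistics as JSON
#'
#' @param design A [build_design()] result (or a stats list for `write`).
#' @param path File path.
#' @return `read_design_stats` returns the stats list.
#' @export
write_design_stats <- function(design, path) {
  st <- if (inherits(design, "pga_design")) design_stats(design) else design
  jsonlite::write_json(lapply(st, as.list), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_design_stats
#' @export
read_design_stats <- function(path) {
  raw <- jsonlite::read_json(path)
  list(mean = unlist(raw$mean), sd = unlist(raw$sd))
}
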