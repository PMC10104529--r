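make_cov <- function(n_lakes = 8, n_years = 1, seed = 5) {
  simulate_lakes(n_lakes, n_years, seed = seed)
}

test_that("the trailing 5-year rolling mean uses available years only", {
  expect_equal(rolling_mean_5yr(rep(7, 5), 2015:2019, 2019), 7)
  expect_equal(rolling_mean_5yr(1:5, 2015:2019, 2019), 3)
  # single observed year in the window
  expect_equal(rolling_mean_5yr(4, 2019, 2019), 4)
  # exactly five consecutive years: equals the plain mean
  v <- rnorm(5)
  expect_equal(rolling_mean_5yr(v, 2010:2014, 2014), mean(v))
  # years outside the trailing window are ignored
  expect_equal(rolling_mean_5yr(c(100, 1, 2), c(2012, 2018, 2019), 2019), 1.5)
  expect_error(rolling_mean_5yr(1, 2010, 2019), "missing covariate")
})

test_that("transforms follow the log/logit conventions with boundary clamping", {
  cov <- make_cov()
  cov$prop_developed[1] <- 0.5
  cov$prop_agriculture[1] <- 0
  cov$area[1] <- exp(2)
  d <- build_design(cov, model = "pga")
  st <- design_stats(d)
  # invert standardization to recover the transformed values
  raw_dev <- d$logit_developed * st$sd["logit_developed"] +
    st$mean["logit_developed"]
  expect_equal(unname(raw_dev[1]), 0)                  # logit(0.5)
  raw_agr <- d$logit_agriculture * st$sd["logit_agriculture"] +
    st$mean["logit_agriculture"]
  expect_equal(unname(raw_agr[1]), log(1e-3 / (1 - 1e-3)))  # clamped, ~ -6.9068
  raw_area <- d$log_area * st$sd["log_area"] + st$mean["log_area"]
  expect_equal(unname(raw_area[1]), 2)                 # ln(e^2)
})

test_that("invalid covariate values are rejected loudly", {
  cov <- make_cov()
  cov$prop_wetland[2] <- 1.4
  expect_error(build_design(cov, "pga"), "prop_wetland")
  cov <- make_cov()
  cov$max_depth[3] <- 0
  expect_error(build_design(cov, "pga"), "max_depth")
  cov <- make_cov()
  cov$area <- NULL
  expect_error(build_design(cov, "pga"), "area")
})

test_that("training columns are standardized and the round trip is exact", {
  cov <- make_cov(12)
  d <- build_design(cov, model = "pga")
  num <- d[setdiff(names(d), c("lake_id", "year"))]
  for (col in names(num)) {
    expect_lt(abs(mean(num[[col]])), 1e-8)
    expect_lt(abs(stats::sd(num[[col]]) - 1), 1e-8)
  }
  # de-standardizing recovers the transformed inputs to 1e-12
  st <- design_stats(d)
  back <- Map(function(x, m, s) x * s + m, num,
              st$mean[names(num)], st$sd[names(num)])
  redo <- standardize(as.data.frame(back), st)
  for (col in names(num)) {
    expect_equal(redo[[col]], num[[col]], tolerance = 1e-12)
  }
})

test_that("a constant column is a standardization error", {
  tab <- data.frame(a = rnorm(10), b = rep(2, 10))
  expect_error(standardize(tab), "zero SD.*b|b.*zero SD")
})

test_that("stored training stats reproduce prediction-mode standardization", {
  cov <- make_cov(10)
  d <- build_design(cov, model = "naive")
  st <- design_stats(d)
  shifted <- cov
  shifted$temp_july <- shifted$temp_july + 4
  d2 <- build_design(shifted, model = "naive", stats = st)
  # temperature column shifts by 4 / sd_train on the standardized scale
  expect_equal(d2$temp, d$temp + 4 / unname(st$sd["temp"]), tolerance = 1e-10)
  # squared term follows standardize-then-square with training stats
  z2 <- (d2$temp^2 * 1 - 0)  # raw squared standardized temp
  expect_equal(d2$temp_sq,
               (d2$temp^2 - unname(st$mean["temp_sq"])) / unname(st$sd["temp_sq"]),
               tolerance = 1e-10)
  # untouched covariates are unchanged
  expect_equal(d2$log_area, d$log_area, tolerance = 1e-12)
})

test_that("the two model variants carry the right temperature columns", {
  cov <- make_cov()
  dp <- build_design(cov, "pga")
  dn <- build_design(cov, "naive")
  expect_false(any(c("temp", "temp_sq") %in% names(dp)))
  expect_true(all(c("temp", "temp_sq") %in% names(dn)))
  # temperature in degrees C rides along as metadata for the curve
  expect_length(attr(dp, "temp_c"), nrow(cov))
  # rebuilding from the same records is bit-identical
  expect_identical(build_design(cov, "pga"), dp)
})

test_that("design stats survive a JSON round trip", {
  d <- build_design(make_cov(), "pga")
  path <- tempfile(fileext = ".json")
  write_design_stats(d, path)
  st <- read_design_stats(path)
  expect_equal(st$mean, design_stats(d)$mean)
  expect_equal(st$sd, design_stats(d)$sd)
})
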