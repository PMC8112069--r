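make_cov <- function(n = 30, seed = 1, start = 1985) {
  set.seed(seed)
  yrs <- start + 0:(n - 1)
  climate_covariates(
    yrs,
    temperature = rnorm(n, 0, 0.5),
    precipitation = rnorm(n, 0, 80),
    co2 = 350 + 2 * (0:(n - 1)),
    enso_index = rnorm(n), pdo_index = rnorm(n)
  )
}

test_that("climate regression recovers a noise-free linear model exactly", {
  cov <- make_cov()
  b_true <- 0.1 * cov$temperature + 0.002 * cov$precipitation +
    0.01 * cov$co2 - 2.5
  b <- flux_series(b_true, cov$year, "B", region = "tropics")
  reg <- fit_climate_regression(b, cov)
  expect_equal(unname(reg$coefficients),
               c(-2.5, 0.1, 0.002, 0.01), tolerance = 1e-9)
  expect_equal(reg$r2, 1, tolerance = 1e-9)
  expect_equal(reg$predicted_b$values, b_true, tolerance = 1e-9)
  # residuals orthogonal to the design columns (OLS normal equations)
  res <- stats::residuals(reg$model)
  expect_lt(abs(sum(res * cov$temperature)), 1e-10)
  expect_lt(abs(sum(res * cov$precipitation)), 1e-10)
  expect_lt(abs(sum(res * cov$co2)), 1e-8)
  expect_error(fit_climate_regression(
    flux_series(1:5, 2000:2004, "B"), cov), ">= 8 overlapping")
})

test_that("coefficient CIs achieve near-nominal coverage", {
  cov <- make_cov(n = 40, seed = 3)
  truth <- c(`(Intercept)` = -2, temperature = 0.1,
             precipitation = 0.002, co2 = 0.01)
  hits <- matrix(FALSE, 60, 4)
  for (s in 1:60) {
    set.seed(1000 + s)
    bv <- truth[1] + truth[2] * cov$temperature +
      truth[3] * cov$precipitation + truth[4] * cov$co2 + rnorm(40, 0, 0.2)
    reg <- fit_climate_regression(flux_series(bv, cov$year, "B"), cov)
    hits[s, ] <- reg$ci95[, 1] <= truth & truth <= reg$ci95[, 2]
  }
  # nominal 95%; with 60 replicates allow a generous binomial band
  expect_gt(mean(hits), 0.87)
})

test_that("null model r2 stays small when B is independent of climate", {
  cov <- make_cov(n = 30, seed = 9)
  r2s <- vapply(1:40, function(s) {
    set.seed(2000 + s)
    fit_climate_regression(flux_series(rnorm(30), cov$year, "B"), cov)$r2
  }, 0)
  # r2 of 3 null covariates on n=30: mean ~ 3/29
  expect_lt(mean(r2s), 0.25)
})

test_that("index correlation matches the closed-form Pearson r", {
  cov <- make_cov(n = 25, seed = 7)
  # identity and sign-flip extremes
  cov2 <- cov; cov2$enso_index <- cov2$temperature
  expect_equal(correlate_index(cov2, "temperature", "enso")$r, 1,
               tolerance = 1e-12)
  cov2$enso_index <- -cov2$temperature
  expect_equal(correlate_index(cov2, "temperature", "enso")$r, -1,
               tolerance = 1e-12)
  # closed-form covariance oracle
  r <- correlate_index(cov, "precipitation", "pdo")$r
  x <- cov$precipitation; y <- cov$pdo_index
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, manual, tolerance = 1e-12)
  # constant input errors
  cov3 <- cov; cov3$temperature <- rep(1, 25)
  expect_error(correlate_index(cov3, "temperature", "enso"), "constant")
})

test_that("replace_years applies the stated masking rule and is idempotent", {
  s <- flux_series(c(1, 2.0, 5, 6, 4.0, 3), 2013:2018, "B")
  out <- replace_years(s, c(2015, 2016), c(2014, 2017))
  expect_equal(out$values, c(1, 2, 3, 3, 4, 3))
  # untouched years retain their values
  expect_identical(out$values[c(1, 2, 5, 6)], s$values[c(1, 2, 5, 6)])
  # idempotent
  expect_identical(replace_years(out, c(2015, 2016), c(2014, 2017))$values,
                   out$values)
  # empty target set is the identity
  expect_identical(replace_years(s, integer(), c(2014))$values, s$values)
  expect_error(replace_years(s, 2015, c(2015, 2017)), "disjoint")
  expect_error(replace_years(s, 2015, 2030), "not in series")
})

test_that("El Nino masking keeps the built-in breakpoint detectable", {
  sim <- generate_panel(synthetic_config(), seed = 77)
  p <- sim$panels[[1]]
  b <- panel_global(p, "B"); f <- panel_global(p, "F")
  l <- panel_global(p, "L")
  b_masked <- replace_years(b, c(2015, 2016), c(2014, 2017))
  e <- sink_efficiency(b_masked, f, l, window = 5)
  ft <- fit_segmented(e, window = c(1996, 2016))
  expect_lt(abs(ft$psi - sim$truth$psi_true), 2.5)
  p_mask <- breakpoint_significance(ft, n_boot = 199, seed = 5)
  expect_lt(as.numeric(p_mask), 0.1)
})

test_that("covariate-predicted efficiency reproduces an efficiency breakpoint", {
  # B driven entirely by covariates whose joint effect reverses at 2009
  yrs <- 1990:2018
  n <- length(yrs)
  i <- yrs - yrs[1]
  co2 <- 355 + 1.9 * i
  set.seed(21)
  temperature <- 0.01 * i + rnorm(n, 0, 0.05)
  # precipitation declines after 2009, dragging B down
  precipitation <- -60 * pmax(yrs - 2009, 0) + rnorm(n, 0, 10)
  b_true <- -4 + 0.012 * co2 + 0.004 * precipitation / 10 +
    0.05 * temperature
  cov <- climate_covariates(yrs, temperature, precipitation, co2)
  b <- flux_series(b_true + rnorm(n, 0, 0.01), yrs, "B")
  f <- flux_series(7 + 0.1 * i, yrs, "F")
  l <- flux_series(rep(1.2, n), yrs, "L")
  reg <- fit_climate_regression(b, cov)
  ft <- predicted_efficiency_breakpoint(reg, f, l, window = 5)
  expect_lt(abs(ft$psi - 2009), 1.5)
  # predicted_B == observed B reproduces the observed-E fit
  reg_exact <- reg
  reg_exact$predicted_b <- b
  ft_obs <- fit_segmented(sink_efficiency(b, f, l, window = 5))
  ft_same <- predicted_efficiency_breakpoint(reg_exact, f, l, window = 5)
  expect_equal(ft_same$psi, ft_obs$psi)
  expect_equal(ft_same$sse, ft_obs$sse, tolerance = 1e-12)
})

test_that("covariates CSV round trip", {
  cov <- make_cov(n = 12, seed = 5)
  tmp <- tempfile(fileext = ".csv")
  write_covariates(cov, tmp)
  back <- read_covariates(tmp)
  expect_equal(back$temperature, cov$temperature, tolerance = 1e-12)
  expect_equal(back$enso_index, cov$enso_index, tolerance = 1e-12)
  unlink(tmp)
})
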