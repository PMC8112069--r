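test_that("same seed gives bit-identical panels", {
  a <- generate_panel(synthetic_config(), seed = 123)
  b <- generate_panel(synthetic_config(), seed = 123)
  for (d in names(a$panels)) {
    for (k in names(a$panels[[d]]$flux)) {
      expect_identical(a$panels[[d]]$flux[[k]], b$panels[[d]]$flux[[k]])
    }
  }
  expect_identical(a$covariates$enso_index, b$covariates$enso_index)
  c <- generate_panel(synthetic_config(), seed = 124)
  expect_false(identical(a$panels[[2]]$flux$BL, c$panels[[2]]$flux$BL))
})

test_that("panel conservation holds by construction", {
  sim <- generate_panel(synthetic_config(), seed = 3)
  p <- sim$panels[[3]]
  for (k in c("F", "L", "B", "BL")) {
    expect_equal(panel_global(p, k)$values, unname(colSums(p$flux[[k]])),
                 tolerance = 1e-12)
  }
  # BL = B - L within each region
  expect_equal(p$flux$BL, p$flux$B - p$flux$L, tolerance = 1e-12)
  # global budget closes up to the configured imbalance noise
  res <- panel_global(p, "F")$values + panel_global(p, "L")$values -
    panel_global(p, "B")$values - panel_global(p, "O")$values -
    panel_global(p, "G_atm")$values
  expect_lt(max(abs(res)), 1.5)  # |imbalance| stays at budget scale
})

test_that("noise-free generator is piecewise linear with the designed break", {
  sim <- generate_panel(quiet_config(), seed = 1)
  p <- sim$panels[[1]]
  yrs <- p$years
  # second differences of global F vanish away from the knot
  fg <- panel_global(p, "F")$values
  d2 <- diff(diff(fg))
  knot <- which(yrs[-c(1, length(yrs))] %in%
                  c(sim$config$psi_true, sim$config$b_accel_year))
  expect_equal(max(abs(d2[-knot])), 0, tolerance = 1e-12)
  # derived global efficiency recovers the designed breakpoint closely
  e <- panel_efficiency(p, window = 5)
  ft <- fit_segmented(e, window = c(1996, 2016))
  expect_lt(abs(ft$psi - sim$truth$psi_true), 1)
  expect_gt(ft$s1, 0); expect_lt(ft$s2, 0)
  # both datasets identical when inter-dataset noise is off
  expect_identical(sim$panels[[1]]$flux$BL, sim$panels[[2]]$flux$BL)
})

test_that("generator magnitudes sit at global-carbon-budget scale", {
  sim <- generate_panel(quiet_config(), seed = 1)
  p <- sim$panels[[1]]
  yrs <- p$years
  fg <- panel_global(p, "F")$values
  bg <- panel_global(p, "B")$values
  lg <- panel_global(p, "L")$values
  expect_equal(mean(fg[yrs %in% 1960:1969]), 3.04, tolerance = 0.1)
  expect_equal(mean(fg[yrs %in% 2009:2018]), 9.5, tolerance = 0.25)
  expect_true(all(lg >= 0.9 & lg <= 1.9))
  expect_equal(mean(bg[yrs %in% 1980:1984]), 1.86, tolerance = 0.4)
  # absorbed fraction over the final decade near one third
  expect_equal(mean(bg[yrs %in% 2009:2018]) /
                 mean(fg[yrs %in% 2009:2018] + lg[yrs %in% 2009:2018]),
               1 / 3, tolerance = 0.06)
})

test_that("Pinatubo pulse lifts the sink only in the pulse years", {
  base <- generate_panel(quiet_config(), seed = 1)
  cfgp <- quiet_config()
  cfgp$pinatubo_amplitude <- 2
  pulsed <- generate_panel(cfgp, seed = 1)
  dif <- panel_global(pulsed$panels[[1]], "B")$values -
    panel_global(base$panels[[1]], "B")$values
  yrs <- base$panels[[1]]$years
  expect_equal(dif[yrs %in% 1991:1993], rep(2, 3), tolerance = 1e-12)
  expect_equal(max(abs(dif[!yrs %in% 1991:1993])), 0, tolerance = 1e-12)
})

test_that("tropical sink decouples from ENSO at zero amplitude", {
  cfg0 <- synthetic_config()
  cfg0$enso$amplitude <- 0
  rs <- vapply(1:8, function(s) {
    sim <- generate_panel(cfg0, seed = 400 + s)
    p <- sim$panels[[1]]
    trop <- colSums(p$flux$B[cfg0$tropics, ])
    # correlate detrended tropical B with the ENSO index
    resid <- stats::residuals(stats::lm(trop ~ poly(seq_along(trop), 3)))
    abs(stats::cor(resid, sim$covariates$enso_index))
  }, 0)
  expect_lt(stats::median(rs), 0.2)
  # with coupling on, the correlation strengthens (negative forcing)
  rs1 <- vapply(1:8, function(s) {
    sim <- generate_panel(synthetic_config(), seed = 400 + s)
    p <- sim$panels[[1]]
    trop <- colSums(p$flux$B[synthetic_config()$tropics, ])
    resid <- stats::residuals(stats::lm(trop ~ poly(seq_along(trop), 3)))
    stats::cor(resid, sim$covariates$enso_index)
  }, 0)
  expect_lt(stats::median(rs1), -0.2)
})

test_that("two-segment fixture obeys its own truth", {
  g0 <- generate_two_segment_series(noise_sd = 0)
  expect_equal(g0$values, g0$truth$mu, tolerance = 1e-14)
  # s1 == s2 is a single line
  gl <- generate_two_segment_series(s1 = 0.004, s2 = 0.004, noise_sd = 0)
  expect_equal(diff(gl$values), rep(0.004, 20), tolerance = 1e-12)
  # determinism and interior-psi validation
  expect_identical(generate_two_segment_series(seed = 5)$values,
                   generate_two_segment_series(seed = 5)$values)
  expect_error(generate_two_segment_series(psi = 1997), "interior")
})

test_that("generator output feeds the CSV readers unchanged", {
  sim <- generate_panel(synthetic_config(n_datasets = 1), seed = 6)
  tmp <- tempfile(fileext = ".csv")
  write_flux_table(sim$panels[[1]], tmp)
  p2 <- read_flux_table(tmp)
  expect_identical(p2$flux$B, sim$panels[[1]]$flux$B)
  unlink(tmp)
})
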