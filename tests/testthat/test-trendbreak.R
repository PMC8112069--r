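test_that("linear trend matches the closed-form OLS slope", {
  # noise-free line is recovered exactly
  t <- 1990:2009
  ft <- fit_linear(2 * t + 1, years = t)
  expect_equal(ft$slope, 2, tolerance = 1e-12)
  expect_equal(ft$intercept, 1, tolerance = 1e-9)
  expect_equal(ft$r2, 1)
  # constant series has zero slope
  expect_equal(fit_linear(rep(5, 10), years = 2000:2009)$slope, 0)
  # closed-form oracle on random series
  for (seed in 1:10) {
    set.seed(seed)
    y <- rnorm(15)
    tt <- 2001:2015
    ft <- fit_linear(y, years = tt)
    expect_equal(ft$slope,
                 sum((tt - mean(tt)) * (y - mean(y))) / sum((tt - mean(tt))^2),
                 tolerance = 1e-12)
  }
  expect_error(fit_linear(c(1, 2), years = 2000:2001), "at least 3")
})

test_that("segmented fit recovers noise-free two-segment data exactly", {
  g <- generate_two_segment_series(n = 21, psi = 2009, s1 = 0.004,
                                   s2 = -0.006, noise_sd = 0)
  ft <- fit_segmented(g$values, years = g$years)
  expect_equal(ft$psi, 2009, tolerance = 0.01)
  expect_equal(ft$s1, 0.004, tolerance = 1e-10)
  expect_equal(ft$s2, -0.006, tolerance = 1e-10)
  expect_false(ft$no_breakpoint)
  # exactly linear data: slope change ~ 0 and flagged
  lin <- generate_two_segment_series(n = 21, psi = 2009, s1 = 0.004,
                                     s2 = 0.004, noise_sd = 0)
  fl <- fit_segmented(lin$values, years = lin$years)
  expect_true(fl$no_breakpoint)
  expect_equal(fl$s2 - fl$s1, 0, tolerance = 1e-8)
  # too-short windows error
  expect_error(fit_segmented(rnorm(6), years = 2000:2005), "too short")
})

test_that("segmented SSE never exceeds the straight-line SSE", {
  for (seed in 1:20) {
    set.seed(seed)
    y <- rnorm(21)
    ft <- fit_segmented(y, years = 1996:2016)
    expect_lte(ft$sse, ft$sse_linear + 1e-12)
  }
})

test_that("breakpoint estimate is equivariant under year-axis shifts", {
  set.seed(5)
  y <- cumsum(rnorm(21, 0, 0.1))
  f1 <- fit_segmented(y, years = 1996:2016)
  f2 <- fit_segmented(y, years = 1996:2016 + 100)
  expect_equal(f2$psi, f1$psi + 100, tolerance = 1e-9)
  expect_equal(f2$s1, f1$s1, tolerance = 1e-9)
  expect_equal(f2$s2, f1$s2, tolerance = 1e-9)
})

test_that("significance test is deterministic given a seed and detects a strong break", {
  g <- generate_two_segment_series(n = 21, psi = 2009, s1 = 0.02,
                                   s2 = -0.02, noise_sd = 0.003,
                                   ar1 = 0, seed = 1)
  ft <- fit_segmented(g$values, years = g$years)
  p1 <- breakpoint_significance(ft, n_boot = 199, seed = 42)
  p2 <- breakpoint_significance(ft, n_boot = 199, seed = 42)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_lt(as.numeric(p1), 0.01)
  # Davies bound agrees on the strong break
  expect_lt(as.numeric(breakpoint_significance(ft, method = "davies")), 0.01)
  expect_warning(breakpoint_significance(ft, n_boot = 50, seed = 1),
                 "n_boot < 100")
})

test_that("bootstrap CI contains the estimate and collapses without noise", {
  g0 <- generate_two_segment_series(n = 21, psi = 2009, s1 = 0.004,
                                    s2 = -0.006, noise_sd = 0)
  f0 <- fit_segmented(g0$values, years = g0$years)
  ci0 <- breakpoint_ci(f0, n_boot = 99, seed = 3)
  expect_lte(ci0[2] - ci0[1], 2 * f0$grid_step + 1e-9)
  g <- generate_two_segment_series(n = 21, psi = 2009, s1 = 0.01,
                                   s2 = -0.01, noise_sd = 0.004, seed = 2)
  ft <- fit_segmented(g$values, years = g$years)
  ci <- breakpoint_ci(ft, n_boot = 99, seed = 4)
  expect_lte(ci[1], ft$psi); expect_gte(ci[2], ft$psi)
  # profile (curvature) variant also brackets the estimate
  cip <- breakpoint_ci(ft, method = "profile")
  expect_lte(cip[1], ft$psi); expect_gte(cip[2], ft$psi)
  # exactly linear series: psi unidentified
  lin <- fit_segmented(seq(0, 2, length.out = 21), years = 1996:2016)
  expect_error(breakpoint_ci(lin, n_boot = 99, seed = 1), "degenerate")
})

test_that("CI width shrinks with the noise level on average", {
  width_at <- function(sd, seeds = 1:15) {
    mean(vapply(seeds, function(s) {
      g <- generate_two_segment_series(n = 21, psi = 2009, s1 = 0.01,
                                       s2 = -0.01, noise_sd = sd, seed = s)
      ft <- fit_segmented(g$values, years = g$years)
      ci <- breakpoint_ci(ft, n_boot = 99, seed = 1000 + s)
      ci[2] - ci[1]
    }, 0))
  }
  expect_lt(width_at(0.002), width_at(0.008))
})

test_that("fixed-psi fits and local refinement behave", {
  set.seed(9)
  y <- cumsum(rnorm(21, 0, 0.05))
  ff <- fit_segmented(y, years = 1996:2016, psi = 2007)
  expect_equal(ff$psi, 2007)
  expect_true(ff$psi_fixed)
  fr <- fit_segmented(y, years = 1996:2016, refine = TRUE)
  f0 <- fit_segmented(y, years = 1996:2016)
  expect_lte(fr$sse, f0$sse + 1e-15)
})
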