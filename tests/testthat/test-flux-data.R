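test_that("flux_series enforces contiguity, sign conventions and kinds", {
  expect_s3_class(flux_series(c(1, 2, 3), 2000:2002, "F"), "flux_series")
  expect_error(flux_series(c(1, 2), c(2000, 2002), "F"), "gap after year 2000")
  expect_error(flux_series(1:3, 2000:2002, "nope"), "arg")
  expect_error(flux_series(c(1, -1, 2), 2000:2002, "F"), "non-negative")
  # other kinds may be negative (source years of the land sink)
  expect_silent(flux_series(c(-0.5, 0.5, 0), 2000:2002, "B"))
  s <- flux_series(1:3, 2000:2002, "G_atm")
  expect_identical(s$sign_convention, "emission-positive")
  expect_identical(flux_series(1:3, 2000:2002, "O")$sign_convention,
                   "uptake-positive")
})

test_that("B = BL + L identity and its round trip", {
  bl <- flux_series(c(1.5, 2.0), 2000:2001, "BL")
  l <- flux_series(c(1.3, 0.5), 2000:2001, "L")
  b <- b_from_bl(bl, l)
  expect_equal(b$values, c(2.8, 2.5))
  expect_identical(b$kind, "B")
  # L == 0 leaves BL unchanged
  l0 <- flux_series(c(0, 0), 2000:2001, "L")
  expect_equal(b_from_bl(bl, l0)$values, bl$values)
  # inverse check: bit-exact on dyadic inputs, tight tolerance otherwise
  for (seed in 1:5) {
    set.seed(seed)
    dyadic <- function(n) round(rnorm(n) * 64) / 64
    blr <- flux_series(dyadic(10), 1991:2000, "BL")
    lr <- flux_series(dyadic(10), 1991:2000, "L")
    expect_identical(bl_from_b(b_from_bl(blr, lr), lr)$values, blr$values)
    blr2 <- flux_series(rnorm(10), 1991:2000, "BL")
    lr2 <- flux_series(rnorm(10), 1991:2000, "L")
    expect_equal(bl_from_b(b_from_bl(blr2, lr2), lr2)$values, blr2$values,
                 tolerance = 1e-14)
  }
  # misaligned years error
  l2 <- flux_series(c(1, 1), 2001:2002, "L")
  expect_error(b_from_bl(bl, l2), "misaligned")
})

test_that("fossil-prior adjustment conserves the atmospheric constraint", {
  yrs <- 2000:2002
  bl <- flux_series(c(2, 2, 2), yrs, "BL")
  fp <- flux_series(c(9, 9, 9), yrs, "F")
  fc <- flux_series(c(9.5, 9.5, 9.5), yrs, "F")
  adj <- adjust_fossil_prior(bl, fp, fc)
  expect_equal(adj$values, c(2.5, 2.5, 2.5))
  # identity when priors agree
  expect_identical(adjust_fossil_prior(bl, fp, fp)$values, bl$values)
  # exact conservation of F - BL: random inputs on a dyadic grid (exactly
  # representable, so the identity must hold at the bit level)
  for (seed in 1:10) {
    set.seed(seed)
    dyadic <- function(n, lo, hi) round(runif(n, lo, hi) * 64) / 64
    blr <- flux_series(dyadic(8, -2, 3), 1995:2002, "BL")
    fpr <- flux_series(dyadic(8, 5, 10), 1995:2002, "F")
    fcr <- flux_series(dyadic(8, 5, 10), 1995:2002, "F")
    adj <- adjust_fossil_prior(blr, fpr, fcr)
    expect_identical(fcr$values - adj$values, fpr$values - blr$values)
  }
})

test_that("panel GLOBAL is the regional sum; removals conserve it", {
  p <- tiny_panel(nreg = 2, f = 1.0)
  expect_equal(panel_global(p, "F")$values, rep(2, 5))
  # single-region panel: GLOBAL equals the region
  p1 <- tiny_panel(nreg = 1)
  expect_equal(panel_global(p1, "B")$values,
               panel_series(p1, "B", "R1")$values)
  # conservation under removal, elementwise, for every kind
  pr <- random_panel(42, nreg = 4)
  for (k in names(pr$flux)) {
    g <- panel_global(pr, k)$values
    for (r in pr$regions) {
      red <- remove_regions(pr, r)
      expect_equal(panel_global(red, k)$values +
                     panel_series(pr, k, r)$values, g, tolerance = 1e-12)
    }
  }
  # dropping nothing is the identity; dropping everything errors
  expect_identical(remove_regions(pr, character()), pr)
  expect_error(remove_regions(pr, pr$regions), "all regions")
  expect_error(remove_regions(pr, "nope"), "unknown region")
})

test_that("panel construction validates a supplied GLOBAL series", {
  yrs <- 2000:2002
  mk <- function(gvals) {
    flux_panel(list(
      flux_series(c(1, 1, 1), yrs, "F", region = "A", dataset = "d"),
      flux_series(c(2, 2, 2), yrs, "F", region = "B", dataset = "d"),
      flux_series(gvals, yrs, "F", region = "GLOBAL", dataset = "d")
    ))
  }
  expect_s3_class(mk(c(3, 3, 3)), "flux_panel")
  expect_error(mk(c(3, 3, 3.1)), "does not equal the sum")
})

test_that("flux table round trip preserves values bit-exactly", {
  for (seed in c(1, 2, 3)) {
    p <- random_panel(seed)
    tmp <- tempfile(fileext = ".csv")
    write_flux_table(p, tmp)
    p2 <- read_flux_table(tmp)
    expect_identical(p2$regions, p$regions)
    for (k in names(p$flux)) {
      expect_identical(p2$flux[[k]], p$flux[[k]])
    }
    unlink(tmp)
  }
})

test_that("reader errors name gaps and unknown kinds", {
  df <- data.frame(dataset = "d", region = "A", year = c(2000, 2001, 2003),
                   kind = "F", value = 1)
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE)
  expect_error(read_flux_table(tmp), "gap after year 2001")
  df$year <- 2000:2002; df$kind <- "X"
  utils::write.csv(df, tmp, row.names = FALSE)
  expect_error(read_flux_table(tmp), "unknown flux kind")
  unlink(tmp)
})

test_that("grid aggregation matches brute force and is linear", {
  set.seed(7)
  ncell <- 60; yrs <- 2001:2003
  areas <- runif(ncell, 1e10, 5e10)
  mask <- sample(0:3, ncell, replace = TRUE)
  vals <- matrix(rnorm(ncell * 3, 0, 1e-3), ncell, 3)
  vals[mask == 0, ] <- 0  # keep unmasked cells silent here
  g <- gridded_flux(vals, yrs, areas, mask, c("A", "B", "C"))
  p <- aggregate_grid(g, kind = "B", dataset = "grid")
  # brute-force per-cell accumulation
  for (i in 1:3) {
    manual <- rep(0, 3)
    for (c in seq_len(ncell)) {
      if (mask[c] > 0) manual[mask[c]] <- manual[mask[c]] +
          vals[c, i] * areas[c] * 1e-12
    }
    expect_equal(unname(p$flux$B[, i]), manual, tolerance = 1e-12)
  }
  # linearity: aggregating the sum of two grids = sum of aggregates
  vals2 <- matrix(rnorm(ncell * 3, 0, 1e-3), ncell, 3)
  vals2[mask == 0, ] <- 0
  g2 <- gridded_flux(vals2, yrs, areas, mask, c("A", "B", "C"))
  gsum <- gridded_flux(vals + vals2, yrs, areas, mask, c("A", "B", "C"))
  expect_equal(aggregate_grid(gsum, kind = "B")$flux$B,
               aggregate_grid(g, kind = "B")$flux$B +
                 aggregate_grid(g2, kind = "B")$flux$B, tolerance = 1e-12)
  # uniform density over one region integrates to d * A (unit-converted)
  d <- 2e-3
  vals3 <- matrix(0, ncell, 3); vals3[mask == 1, ] <- d
  g3 <- gridded_flux(vals3, yrs, areas, mask, c("A", "B", "C"))
  expect_equal(unname(aggregate_grid(g3, kind = "B")$flux$B["A", ]),
               rep(d * sum(areas[mask == 1]) * 1e-12, 3))
  # all-zero grid -> all-zero panel
  g0 <- gridded_flux(matrix(0, ncell, 3), yrs, areas, mask, c("A", "B", "C"))
  expect_true(all(aggregate_grid(g0)$flux$BL == 0))
  # unmasked nonzero cells -> warning + remainder assignment
  vals4 <- matrix(0, ncell, 3); vals4[mask == 0, ] <- 1e-3
  g4 <- gridded_flux(vals4, yrs, areas, mask, c("A", "B", "C"))
  expect_warning(p4 <- aggregate_grid(g4, kind = "B"), "remainder region 'C'")
  expect_equal(sum(p4$flux$B[c("A", "B"), ]), 0)
  expect_true(all(p4$flux$B["C", ] > 0))
})
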