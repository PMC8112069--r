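# small builders used across test files

# tiny panel: `nreg` regions x kinds F, L, B (and BL) over `years`,
# with constant or supplied values
tiny_panel <- function(nreg = 2, years = 2000:2004, f = 1.0, l = 0.2,
                       b = 0.5, dataset = "toy") {
  regions <- paste0("R", seq_len(nreg))
  series <- list()
  for (r in regions) {
    fv <- rep(f, length(years))[seq_along(years)]
    lv <- rep(l, length(years))[seq_along(years)]
    bv <- rep(b, length(years))[seq_along(years)]
    series <- c(series, list(
      flux_series(fv, years, "F", region = r, dataset = dataset),
      flux_series(lv, years, "L", region = r, dataset = dataset),
      flux_series(bv, years, "B", region = r, dataset = dataset),
      flux_series(bv - lv, years, "BL", region = r, dataset = dataset)
    ))
  }
  flux_panel(series, regions = regions)
}

# random panel for round-trip property tests
random_panel <- function(seed, nreg = 3, years = 1990:1999) {
  set.seed(seed)
  regions <- paste0("R", seq_len(nreg))
  series <- list()
  for (r in regions) {
    series <- c(series, list(
      flux_series(runif(length(years), 0, 10), years, "F", region = r,
                  dataset = "rand"),
      flux_series(rnorm(length(years)), years, "L", region = r,
                  dataset = "rand"),
      flux_series(rnorm(length(years)), years, "B", region = r,
                  dataset = "rand")
    ))
  }
  flux_panel(series, regions = regions)
}

# quiet synthetic configuration: deterministic backbones only
quiet_config <- function(n_datasets = 2, ...) {
  synthetic_config(
    n_datasets = n_datasets,
    sigma_b = 0, sigma_l = 0, sigma_f_rel = 0, pinatubo_amplitude = 0,
    enso = list(phi = 0.5, sd = 0, post_trend = 0,
                spike_years = c(2015, 2016), spike_values = c(0, 0),
                amplitude = 0),
    covariates = list(alpha_t = 0.4, t_trend = 0.012, t_noise = 0,
                      alpha_p = -80, p_noise = 0, co2_base = 314,
                      co2_lin = 0.8, co2_quad = 0.0135,
                      pdo_phi = 0.6, pdo_sd = 0, pdo_post_trend = 0),
    ocean = list(start = 1.0, slope = 0.025, sd = 0, imbalance_sd = 0,
                 imbalance_ar1 = 0.3),
    dataset_sd_bl = 0, dataset_sd_l = 0, ...
  )
}

# independent brute-force oracle for the segmented fit: exhaustive
# grid search with a plain lm.fit per candidate (deliberately naive)
brute_force_segmented <- function(t, y, min_seg = 3, step = 0.01) {
  lo <- t[min_seg]; hi <- t[length(t) - min_seg + 1]
  cand <- seq(lo, hi, by = step)
  best_sse <- Inf; best_psi <- NA_real_
  for (psi in cand) {
    fit <- stats::lm.fit(cbind(1, t, pmax(t - psi, 0)), y)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse - 0 && sse < best_sse) {
      best_sse <- sse; best_psi <- psi
    }
  }
  list(psi = best_psi, sse = best_sse)
}
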