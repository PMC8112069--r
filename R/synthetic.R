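# Synthetic multi-dataset regional flux panels with known truth.
#
# The generator emulates the statistical structure of the multi-product
# global-carbon-budget panel the efficiency analysis consumes: 11 regions
# over 1957-2018, deterministic piecewise-linear flux backbones whose
# regional pieces sum exactly to the global design, a post-2009 natural-
# sink reversal concentrated in the tropics (strongest in Latin America),
# a fossil-growth slowdown concentrated in East Asia, accelerating
# land-use emissions in Africa and East Asia, a Pinatubo-like 1991-1993
# sink pulse, AR(1) interannual noise, ENSO-coupled tropical sink
# anomalies with 2015-2016 El Nino spikes, climate covariates tied to the
# ENSO index, and an ensemble of datasets differing by mean-zero
# perturbations of BL and L (the fossil series is shared, as it is across
# real inversions).

# default piecewise backbones (Pg C yr^-1 at 1957 and slopes per year);
# regional rows sum exactly to the global design values
synth_backbone_defaults <- function() {
  regions <- default_regions()
  fossil <- data.frame(
    region = regions,
    start     = c(0.07, 0.15, 0.55, 0.55, 0.04, 0.30, 0.02, 0.03, 0.04, 0.05, 0.20),
    slope_pre = c(0.009, 0.034, 0.021, 0.012, 0.007, 0.015, 0.011, 0.003, 0.009, 0.012, 0.006),
    slope_post= c(0.008, -0.004, -0.002, 0.000, 0.008, 0.005, 0.009, 0.002, 0.010, 0.018, 0.011),
    stringsAsFactors = FALSE
  )
  sink <- data.frame(
    region = regions,
    start      = c(0.22, 0.10, 0.15, 0.12, 0.15, 0.12, 0.01, 0.03, 0.10, 0.06, 0.04),
    slope_early= c(0.006, 0.002, 0.004, 0.002, 0.004, 0.003, 0.000, 0.001, 0.002, 0.002, 0.001),
    slope_mid  = c(0.044, 0.002, 0.006, 0.004, 0.025, 0.004, 0.000, 0.001, 0.010, 0.004, 0.000),
    slope_post = c(-0.040, 0.005, 0.007, 0.005, -0.017, 0.000, 0.000, -0.001, 0.006, 0.002, -0.002),
    stringsAsFactors = FALSE
  )
  luc <- data.frame(
    region = regions,
    start     = c(0.40, 0.05, 0.03, 0.02, 0.25, 0.02, 0.00, 0.01, 0.15, 0.05, 0.02),
    slope_pre = c(0.004, 0.000, -0.001, 0.000, 0.000, 0.000, 0.000, 0.000, 0.002, 0.000, 0.000),
    slope_post= c(-0.002, 0.010, 0.002, 0.000, 0.013, 0.001, 0.000, 0.001, 0.003, 0.002, 0.000),
    stringsAsFactors = FALSE
  )
  list(fossil = fossil, sink = sink, luc = luc)
}

#' Configuration of the synthetic flux-panel generator
#'
#' Defaults encode the study conditions the pipeline is designed for:
#' years 1957-2018, a breakpoint at 2009, a natural-sink growth
#' acceleration from 1994, flux magnitudes at global-carbon-budget scale
#' (fossil emissions rising from ~3 Pg C yr^-1 in the 1960s to
#' ~9.5 Pg C yr^-1 in 2009-2018, land-use emissions 1-1.8 Pg C yr^-1,
#' natural sink ~1.1 to ~3.6 Pg C yr^-1 peaking at the breakpoint), a
#' 2 Pg C yr^-1 Pinatubo pulse over 1991-1993, AR(1) interannual noise
#' and an ENSO-forced tropical sink.
#'
#' @param regions region labels (default [default_regions()]).
#' @param years year axis (default 1957:2018).
#' @param psi_true breakpoint year of the backbones (default 2009).
#' @param b_accel_year knot where natural-sink growth accelerates (1994).
#' @param backbones list of data.frames `fossil`, `sink`, `luc` with
#'   per-region start values and segment slopes (see
#'   `synth_backbone_defaults`).
#' @param pinatubo_years,pinatubo_amplitude volcanic sink-pulse years and
#'   global amplitude (Pg C yr^-1), split across regions by sink share.
#' @param ar1 AR(1) coefficient of all flux noise (default 0.3).
#' @param sigma_b,sigma_l global-equivalent marginal noise SD of the
#'   natural-sink and land-use fluxes (Pg C yr^-1); regional SDs are
#'   `sqrt(share)`-allocated so independent regional noise sums back to
#'   the global SD.
#' @param sigma_f_rel relative noise SD of fossil emissions (multiplicative,
#'   keeps F non-negative).
#' @param tropics regions coupled to the ENSO index.
#' @param enso list: `phi`, `sd` (AR(1) shape of the index),
#'   `post_trend` (index trend per year after `psi_true`), `spike_years`,
#'   `spike_values` (El Nino spikes), `amplitude` (Pg C yr^-1 of tropical
#'   sink reduction per index unit, split across tropics by sink share).
#' @param covariates list: `alpha_t`, `t_trend`, `t_noise` (temperature on
#'   index), `alpha_p`, `p_noise` (precipitation on index), `co2_base`,
#'   `co2_lin`, `co2_quad` (CO2 path), `pdo_phi`, `pdo_sd`,
#'   `pdo_post_trend`.
#' @param ocean list: `start`, `slope`, `sd` of the global ocean sink and
#'   `imbalance_sd`, `imbalance_ar1` of the budget-imbalance noise used to
#'   construct atmospheric growth.
#' @param n_datasets number of dataset variants (default 7, as for the net
#'   land sink products).
#' @param n_l_sources number of land-use flux variants (default 4).
#' @param dataset_sd_bl,dataset_sd_l marginal SD of the mean-zero
#'   inter-dataset perturbations of BL (regional, share-allocated) and of
#'   the global alternative L estimates.
#' @param seed default seed used by [generate_panel()].
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(regions = default_regions(),
                             years = 1957:2018,
                             psi_true = 2009,
                             b_accel_year = 1994,
                             backbones = synth_backbone_defaults(),
                             pinatubo_years = 1991:1993,
                             pinatubo_amplitude = 2.0,
                             ar1 = 0.3,
                             sigma_b = 0.05,
                             sigma_l = 0.04,
                             sigma_f_rel = 0.01,
                             tropics = c("Latin America", "Africa",
                                         "Southeast Asia", "South Asia"),
                             enso = list(phi = 0.5, sd = 0.5,
                                         post_trend = 0.10,
                                         spike_years = c(2015, 2016),
                                         spike_values = c(2.0, 1.2),
                                         amplitude = 0.10),
                             covariates = list(alpha_t = 0.4, t_trend = 0.012,
                                               t_noise = 0.10,
                                               alpha_p = -80, p_noise = 50,
                                               co2_base = 314, co2_lin = 0.8,
                                               co2_quad = 0.0135,
                                               pdo_phi = 0.6, pdo_sd = 1.0,
                                               pdo_post_trend = 0.10),
                             ocean = list(start = 1.0, slope = 0.025,
                                          sd = 0.08, imbalance_sd = 0.25,
                                          imbalance_ar1 = 0.3),
                             n_datasets = 7,
                             n_l_sources = 4,
                             dataset_sd_bl = 0.06,
                             dataset_sd_l = 0.06,
                             seed = 1L) {
  stopifnot(abs(ar1) < 1, psi_true > min(years), psi_true < max(years),
            b_accel_year > min(years), b_accel_year < psi_true,
            n_datasets >= 1, n_l_sources >= 2)
  for (nm in c("fossil", "sink", "luc")) {
    bad <- setdiff(backbones[[nm]]$region, regions)
    if (length(bad)) {
      stop(sprintf("backbone '%s' names unknown region(s): %s", nm,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  bad <- setdiff(tropics, regions)
  if (length(bad)) {
    stop("tropics names unknown region(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(regions = regions, years = as.integer(years), psi_true = psi_true,
         b_accel_year = b_accel_year, backbones = backbones,
         pinatubo_years = pinatubo_years,
         pinatubo_amplitude = pinatubo_amplitude,
         ar1 = ar1, sigma_b = sigma_b, sigma_l = sigma_l,
         sigma_f_rel = sigma_f_rel, tropics = tropics, enso = enso,
         covariates = covariates, ocean = ocean, n_datasets = n_datasets,
         n_l_sources = n_l_sources, dataset_sd_bl = dataset_sd_bl,
         dataset_sd_l = dataset_sd_l, seed = seed),
    class = "synthetic_config"
  )
}

# deterministic per-region backbone matrices (region x year)
synth_backbones_eval <- function(cfg) {
  yrs <- cfg$years
  i <- yrs - yrs[1]
  post <- pmax(yrs - cfg$psi_true, 0)
  mid <- pmax(pmin(yrs, cfg$psi_true) - cfg$b_accel_year, 0)
  pre_b <- pmin(yrs, cfg$b_accel_year) - yrs[1]
  mk <- function(df, f) {
    m <- t(vapply(seq_len(nrow(df)), function(r) f(df[r, ]),
                  numeric(length(yrs))))
    rownames(m) <- df$region
    colnames(m) <- yrs
    m
  }
  two_seg <- function(row) {
    row$start + row$slope_pre * pmin(i, cfg$psi_true - yrs[1]) +
      row$slope_post * post
  }
  f <- mk(cfg$backbones$fossil, two_seg)
  l <- mk(cfg$backbones$luc, two_seg)
  b <- mk(cfg$backbones$sink, function(row) {
    row$start + row$slope_early * pre_b + row$slope_mid * mid +
      row$slope_post * post
  })
  list(F = f, L = l, B = b)
}

#' Generate a synthetic multi-dataset flux panel with known truth
#'
#' See [synthetic_config()] for the generated structure. The same seed
#' yields bit-identical output.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed (default `cfg$seed`).
#' @return a list of class `synthetic_ensemble`:
#'   \describe{
#'     \item{panels}{named list of [flux_panel()] (one per dataset) with
#'       regional F, L, BL, B and global-only O and G_atm;}
#'     \item{covariates}{a [climate_covariates()] table;}
#'     \item{l_ensemble}{global land-use series variants (the first is the
#'       primary source used in the panels);}
#'     \item{truth}{true breakpoint, per-region slope-change contributions,
#'       region ranking, ENSO/covariate coefficients;}
#'     \item{config, seed}{provenance.}
#'   }
#' @export
generate_panel <- function(cfg = synthetic_config(), seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seed <- seed %||% cfg$seed
  yrs <- cfg$years
  ny <- length(yrs)
  nr <- length(cfg$regions)
  bb <- synth_backbones_eval(cfg)

  with_seed(seed, {
    # ENSO-like index: AR(1) + post-breakpoint trend + El Nino spikes
    enso <- ar1_noise(ny, cfg$enso$phi, cfg$enso$sd) +
      cfg$enso$post_trend * pmax(yrs - cfg$psi_true, 0)
    sp <- match(cfg$enso$spike_years, yrs)
    enso[sp[!is.na(sp)]] <- enso[sp[!is.na(sp)]] +
      cfg$enso$spike_values[!is.na(sp)]
    pdo <- ar1_noise(ny, cfg$covariates$pdo_phi, cfg$covariates$pdo_sd) +
      cfg$covariates$pdo_post_trend * pmax(yrs - cfg$psi_true, 0)

    i <- yrs - yrs[1]
    temperature <- cfg$covariates$alpha_t * enso +
      cfg$covariates$t_trend * i +
      stats::rnorm(ny, 0, cfg$covariates$t_noise)
    precipitation <- cfg$covariates$alpha_p * enso +
      stats::rnorm(ny, 0, cfg$covariates$p_noise)
    co2 <- cfg$covariates$co2_base + cfg$covariates$co2_lin * i +
      cfg$covariates$co2_quad * i^2
    cov <- climate_covariates(yrs, temperature, precipitation, co2,
                              enso_index = enso, pdo_index = pdo)

    # noise shares: sqrt of each region's share of the global backbone at
    # the breakpoint, so independent regional noise sums to the global SD
    share_of <- function(m) {
      at <- m[, as.character(cfg$psi_true)]
      s <- abs(at) / max(sum(abs(at)), .Machine$double.eps)
      sqrt(s)
    }
    sh_b <- share_of(bb$B); sh_l <- share_of(bb$L)

    # Pinatubo pulse split by sink share at 1992
    pulse <- numeric(ny)
    pulse[yrs %in% cfg$pinatubo_years] <- cfg$pinatubo_amplitude
    mid_pulse <- cfg$pinatubo_years[ceiling(length(cfg$pinatubo_years) / 2)]
    b_share_92 <- bb$B[, as.character(mid_pulse)]
    b_share_92 <- b_share_92 / sum(b_share_92)

    # ENSO coupling: tropical sink reduced in warm phases, split by share
    trop_share <- bb$B[, as.character(cfg$psi_true)]
    trop_share[!cfg$regions %in% cfg$tropics] <- 0
    trop_share <- if (sum(trop_share) > 0) trop_share / sum(trop_share) else trop_share

    Bm <- bb$B; Lm <- bb$L; Fm <- bb$F
    for (r in seq_len(nr)) {
      Bm[r, ] <- Bm[r, ] + ar1_noise(ny, cfg$ar1, cfg$sigma_b * sh_b[r]) +
        b_share_92[r] * pulse -
        cfg$enso$amplitude * trop_share[r] * enso
      Lm[r, ] <- Lm[r, ] + ar1_noise(ny, cfg$ar1, cfg$sigma_l * sh_l[r])
      Fm[r, ] <- Fm[r, ] *
        pmax(1 + ar1_noise(ny, cfg$ar1, cfg$sigma_f_rel), 0)
    }

    # global budget terms shared by all datasets
    o <- pmax(cfg$ocean$start + cfg$ocean$slope * i +
                ar1_noise(ny, cfg$ar1, cfg$ocean$sd), 0.1)
    imb <- ar1_noise(ny, cfg$ocean$imbalance_ar1, cfg$ocean$imbalance_sd)
    g_atm <- colSums(Fm) + colSums(Lm) - colSums(Bm) - o + imb

    # dataset ensemble: shared F and L, BL perturbed per dataset
    panels <- vector("list", cfg$n_datasets)
    names(panels) <- sprintf("inv%02d", seq_len(cfg$n_datasets))
    for (d in seq_len(cfg$n_datasets)) {
      pert <- if (d == 1) {
        matrix(0, nr, ny)  # first dataset is the reference product
      } else {
        t(vapply(seq_len(nr), function(r) {
          ar1_noise(ny, cfg$ar1, cfg$dataset_sd_bl * sh_b[r])
        }, numeric(ny)))
      }
      series <- list()
      for (r in seq_len(nr)) {
        reg <- cfg$regions[r]
        ds <- names(panels)[d]
        bl_v <- (Bm[r, ] - Lm[r, ]) + pert[r, ]
        series <- c(series, list(
          flux_series(Fm[r, ], yrs, "F", region = reg, dataset = ds),
          flux_series(Lm[r, ], yrs, "L", region = reg, dataset = ds),
          flux_series(bl_v, yrs, "BL", region = reg, dataset = ds),
          flux_series(bl_v + Lm[r, ], yrs, "B", region = reg, dataset = ds)
        ))
      }
      series <- c(series, list(
        flux_series(o, yrs, "O", region = "GLOBAL", dataset = names(panels)[d]),
        flux_series(g_atm, yrs, "G_atm", region = "GLOBAL",
                    dataset = names(panels)[d])
      ))
      panels[[d]] <- flux_panel(series, regions = cfg$regions)
    }

    # alternative global land-use estimates (first = primary source)
    l_glob <- colSums(Lm)
    l_ens <- vector("list", cfg$n_l_sources)
    names(l_ens) <- sprintf("luc%02d", seq_len(cfg$n_l_sources))
    l_ens[[1]] <- flux_series(l_glob, yrs, "L", dataset = names(l_ens)[1])
    for (k in seq_len(cfg$n_l_sources)[-1]) {
      l_ens[[k]] <- flux_series(
        l_glob + ar1_noise(ny, cfg$ar1, cfg$dataset_sd_l), yrs, "L",
        dataset = names(l_ens)[k])
    }

    contrib <- cfg$backbones$sink$slope_post - cfg$backbones$sink$slope_mid
    names(contrib) <- cfg$backbones$sink$region
    truth <- list(
      psi_true = cfg$psi_true,
      b_slope_change = contrib,
      reversal_region = names(contrib)[which.min(contrib)],
      region_ranking = names(sort(contrib)),
      enso_amplitude = cfg$enso$amplitude,
      covariate_coefficients = cfg$covariates,
      seed = seed
    )
    structure(list(panels = panels, covariates = cov, l_ensemble = l_ens,
                   truth = truth, config = cfg, seed = seed),
              class = "synthetic_ensemble")
  })
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf(
    "<synthetic_ensemble> %d datasets x %d regions, years %d-%d (seed %s)\n  true breakpoint %s; reversal region: %s\n",
    length(x$panels), length(x$config$regions), min(x$config$years),
    max(x$config$years), format(x$seed), format(x$truth$psi_true),
    x$truth$reversal_region))
  invisible(x)
}

#' Two-segment annual test series with known truth
#'
#' Minimal fixture for the trend-break estimators: a continuous two-
#' segment line with optional AR(1) noise. Defaults mirror the smoothed
#' global efficiency over 1996-2016: breakpoint 2009, slopes +0.004 and
#' -0.006 per year, marginal noise SD 0.004.
#'
#' @param n series length (>= 7).
#' @param psi breakpoint year, strictly inside the year span with at least
#'   3 points on each side.
#' @param s1,s2 pre- and post-break slopes (per year).
#' @param noise_sd marginal noise standard deviation.
#' @param seed integer seed.
#' @param start_year first year.
#' @param intercept value at `start_year`.
#' @param ar1 AR(1) coefficient of the noise (0 = white).
#' @return a list with `years`, `values` and `truth`
#'   (psi, s1, s2, intercept).
#' @export
generate_two_segment_series <- function(n = 21, psi = 2009, s1 = 0.004,
                                        s2 = -0.006, noise_sd = 0.004,
                                        seed = NULL, start_year = 1996,
                                        intercept = 0.30, ar1 = 0.3) {
  stopifnot(n >= 7)
  years <- seq.int(start_year, length.out = n)
  if (psi <= years[3] || psi >= years[n - 2]) {
    stop("psi must lie in the interior of the year span", call. = FALSE)
  }
  mu <- intercept + s1 * (years - start_year) +
    (s2 - s1) * pmax(years - psi, 0)
  noise <- with_seed(seed, ar1_noise(n, ar1, noise_sd))
  list(years = years, values = mu + noise,
       truth = list(psi = psi, s1 = s1, s2 = s2, intercept = intercept,
                    mu = mu))
}
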