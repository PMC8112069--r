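# End-to-end orchestration: from a run configuration (synthetic or CSV
# inputs) to the full report bundle — efficiency series, pre-Pinatubo
# linear trends, post-Pinatubo segmented fits with significance and CI,
# leave-one-out / leave-two-out attribution, per-region per-flux slopes
# around the breakpoint, and the Monte Carlo envelope.

#' Build a run configuration
#'
#' All analysis choices live here; the defaults are the study conditions
#' (5-yr window, pre-Pinatubo linear window 1959-1988, post-Pinatubo fit
#' window 1996-2016, alpha 0.01 for the global breakpoint and 0.1 for
#' removal experiments).
#'
#' @param flux_csv path(s) to tidy flux CSVs (one panel per dataset), or
#'   `NULL` to simulate.
#' @param covariates_csv optional covariates CSV (with `flux_csv` input).
#' @param synthetic a [synthetic_config()] used when `flux_csv` is NULL.
#' @param window odd smoothing window in years.
#' @param smooth `"fluxes"` (smooth fluxes then ratio) or `"efficiency"`.
#' @param pre_window linear-trend window, smoothed years.
#' @param fit_window segmented-fit window, smoothed years.
#' @param min_seg minimum points per breakpoint segment.
#' @param grid_step breakpoint candidate spacing (years).
#' @param alpha_global significance level for the global breakpoint.
#' @param alpha_removal detectability level for removal experiments.
#' @param psi_mode `"free"` or `"fixed"` attribution mode.
#' @param n_boot bootstrap replicates for p-values and CIs.
#' @param run_pairs evaluate all two-region removals (on `pairs_datasets`).
#' @param pairs_datasets dataset names (or indices) for the pair scan;
#'   `NULL` = all datasets.
#' @param mc_n Monte Carlo draws.
#' @param mc_f_rel_sd relative fossil 1-sigma for the Monte Carlo.
#' @param guard denominator guard (Pg C yr^-1).
#' @param seed base seed; every stochastic stage derives a sub-seed.
#' @param out_dir optional directory for CSV/JSON reports.
#' @return a list of class `run_config`.
#' @export
run_config <- function(flux_csv = NULL, covariates_csv = NULL,
                       synthetic = synthetic_config(),
                       window = 5L, smooth = "fluxes",
                       pre_window = c(1959, 1988),
                       fit_window = c(1996, 2016),
                       min_seg = 3, grid_step = 0.01,
                       alpha_global = 0.01, alpha_removal = 0.1,
                       psi_mode = "free", n_boot = 199,
                       run_pairs = TRUE, pairs_datasets = NULL,
                       mc_n = 10000, mc_f_rel_sd = 0.05,
                       guard = 0.1, seed = 1L, out_dir = NULL) {
  stopifnot(alpha_global > 0, alpha_global < 1,
            alpha_removal > 0, alpha_removal < 1,
            window >= 1, window %% 2 == 1)
  structure(
    list(flux_csv = flux_csv, covariates_csv = covariates_csv,
         synthetic = synthetic, window = as.integer(window),
         smooth = smooth, pre_window = pre_window, fit_window = fit_window,
         min_seg = min_seg, grid_step = grid_step,
         alpha_global = alpha_global, alpha_removal = alpha_removal,
         psi_mode = psi_mode, n_boot = n_boot, run_pairs = run_pairs,
         pairs_datasets = pairs_datasets, mc_n = mc_n,
         mc_f_rel_sd = mc_f_rel_sd, guard = guard, seed = seed,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys map onto [run_config()] arguments; unknown keys error.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(lst), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, lst)
}

# load or simulate the input panels for a run
pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$flux_csv)) {
    panels <- list()
    for (p in cfg$flux_csv) {
      got <- read_flux_table(p)
      if (inherits(got, "flux_panel")) got <- stats::setNames(list(got), got$dataset_id)
      panels <- c(panels, got)
    }
    cov <- if (!is.null(cfg$covariates_csv)) read_covariates(cfg$covariates_csv)
    list(panels = panels, covariates = cov, l_ensemble = NULL, truth = NULL)
  } else {
    sim <- generate_panel(cfg$synthetic, seed = derive_seed(cfg$seed, 0))
    list(panels = sim$panels, covariates = sim$covariates,
         l_ensemble = sim$l_ensemble, truth = sim$truth)
  }
}

#' Run the full land-sink-efficiency analysis
#'
#' Executes the complete pipeline on the configured inputs and returns a
#' report bundle; when `cfg$out_dir` is set the tables are also written as
#' CSV and the fits as JSON. Re-running with an identical configuration
#' and seed reproduces the bundle exactly.
#'
#' @param cfg a [run_config()].
#' @return a list of class `sink_report`:
#'   \describe{
#'     \item{efficiency}{named list of [efficiency_series()] per dataset;}
#'     \item{pre_trends}{pre-Pinatubo linear trends per dataset;}
#'     \item{breakpoints}{segmented fits per dataset (psi, slopes, p, CI);}
#'     \item{attribution}{`loo` rows per dataset and region, `mean_rsc`
#'       per region across datasets, `pairs` rows and `killing` pairs;}
#'     \item{flux_trends}{per dataset, region and flux kind: slopes before
#'       and after the (rounded mean) breakpoint within the fit window;}
#'     \item{mc}{Monte Carlo envelope for the first dataset plus the
#'       IAV comparison;}
#'     \item{log}{the choices used (windows, alphas, seeds, mode).}
#'   }
#' @export
run_full_analysis <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  inp <- pipeline_inputs(cfg)
  panels <- inp$panels
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # (a) efficiency series per dataset
  eff <- stage("efficiency", lapply(panels, panel_efficiency,
                                    window = cfg$window, guard = cfg$guard,
                                    smooth = cfg$smooth))

  # (b) pre-Pinatubo linear trends
  pre <- stage("pre_trends", do.call(rbind, lapply(names(eff), function(d) {
    ft <- fit_linear(eff[[d]], window = cfg$pre_window)
    data.frame(dataset = d, slope = ft$slope, p_value = ft$p_value,
               r2 = ft$r2, start = ft$window[1], end = ft$window[2],
               stringsAsFactors = FALSE)
  })))

  # (c) post-Pinatubo segmented fits with significance and CI
  fits <- list()
  bres <- stage("breakpoints", do.call(rbind, lapply(seq_along(eff), function(k) {
    d <- names(eff)[k]
    ft <- fit_segmented(eff[[d]], window = cfg$fit_window,
                        min_seg = cfg$min_seg, grid_step = cfg$grid_step)
    ft$p_value <- as.numeric(breakpoint_significance(
      ft, n_boot = cfg$n_boot, seed = derive_seed(cfg$seed, 100 + k)))
    ft$ci95 <- breakpoint_ci(ft, n_boot = cfg$n_boot,
                             seed = derive_seed(cfg$seed, 200 + k))
    fits[[d]] <<- ft
    data.frame(dataset = d, psi = ft$psi, s1 = ft$s1, s2 = ft$s2,
               p_value = ft$p_value, ci_lo = ft$ci95[1], ci_hi = ft$ci95[2],
               sse = ft$sse, no_breakpoint = ft$no_breakpoint,
               significant = !ft$no_breakpoint && ft$p_value <= cfg$alpha_global,
               stringsAsFactors = FALSE)
  })))

  # (d) leave-one-out and leave-two-out attribution
  loo <- stage("leave_one_out", do.call(rbind, lapply(seq_along(panels), function(k) {
    d <- names(panels)[k]
    res <- leave_one_out(panels[[d]], window = cfg$window,
                         fit_window = cfg$fit_window, min_seg = cfg$min_seg,
                         grid_step = cfg$grid_step, alpha = cfg$alpha_removal,
                         psi_mode = cfg$psi_mode, n_boot = cfg$n_boot,
                         seed = derive_seed(cfg$seed, 300 + 100 * k),
                         guard = cfg$guard, global_fit = fits[[d]])
    cbind(dataset = d, res, stringsAsFactors = FALSE)
  })))
  mean_rsc <- stage("mean_rsc", {
    ag <- stats::aggregate(r_sc_percent ~ removed, data = loo, FUN = mean)
    ag[order(-ag$r_sc_percent), ]
  })

  pairs <- NULL; killing <- character()
  if (isTRUE(cfg$run_pairs)) {
    pd <- cfg$pairs_datasets %||% names(panels)
    if (is.numeric(pd)) pd <- names(panels)[pd]
    pairs <- stage("leave_pairs_out", do.call(rbind, lapply(seq_along(pd), function(k) {
      d <- pd[k]
      res <- leave_pairs_out(panels[[d]], window = cfg$window,
                             fit_window = cfg$fit_window,
                             min_seg = cfg$min_seg,
                             grid_step = cfg$grid_step,
                             alpha = cfg$alpha_removal,
                             psi_mode = cfg$psi_mode, n_boot = cfg$n_boot,
                             seed = derive_seed(cfg$seed, 10000 + 100 * k),
                             guard = cfg$guard, global_fit = fits[[d]])
      killing <<- union(killing, attr(res, "killing"))
      cbind(dataset = d, res, stringsAsFactors = FALSE)
    })))
  }

  # (e) per-region per-kind slopes before/after the breakpoint
  psi_ref <- round(mean(bres$psi))
  flux_trends <- stage("flux_trends", do.call(rbind, lapply(names(panels), function(d) {
    p <- panels[[d]]
    do.call(rbind, lapply(c("F", "L", "B"), function(k) {
      do.call(rbind, lapply(c(p$regions, "GLOBAL"), function(r) {
        s <- moving_average(panel_series(p, k, r), cfg$window)
        pre_f <- fit_linear(s, window = c(cfg$fit_window[1], psi_ref))
        post_f <- fit_linear(s, window = c(psi_ref, cfg$fit_window[2]))
        data.frame(dataset = d, region = r, kind = k,
                   slope_pre = pre_f$slope, slope_post = post_f$slope,
                   stringsAsFactors = FALSE)
      }))
    }))
  })))

  # (f) Monte Carlo envelope on the first dataset's global smoothed fluxes
  mc <- stage("monte_carlo", {
    p1 <- panels[[1]]
    f_s <- moving_average(panel_global(p1, "F"), cfg$window)
    l_s <- moving_average(panel_global(p1, "L"), cfg$window)
    bl_s <- moving_average(panel_global(p1, "BL"), cfg$window)
    sd_bl <- if (length(panels) >= 2) {
      flux_spread(lapply(panels, function(p) {
        moving_average(panel_global(p, "BL"), cfg$window)
      }))
    } else 0
    sd_l <- if (!is.null(inp$l_ensemble) && length(inp$l_ensemble) >= 2) {
      flux_spread(lapply(inp$l_ensemble, moving_average, cfg$window))
    } else 0
    env <- mc_efficiency(f_s, bl_s, l_s, sd_l = sd_l, sd_bl = sd_bl,
                         f_rel_sd = cfg$mc_f_rel_sd, n = cfg$mc_n,
                         seed = derive_seed(cfg$seed, 900))
    # interannual variability is judged on the annual (unsmoothed)
    # efficiency anomalies within the fit window
    e_ann <- panel_efficiency(p1, window = 1L, guard = cfg$guard)
    keep <- e_ann$years >= cfg$fit_window[1] & e_ann$years <= cfg$fit_window[2]
    e_ann <- efficiency_series(e_ann$E[keep], e_ann$years[keep], window = 1L,
                               dataset = e_ann$source_panel,
                               l_source = e_ann$L_source)
    list(envelope = env,
         iav = compare_uncertainty_to_iav(env, e_ann))
  })

  report <- structure(
    list(efficiency = eff, pre_trends = pre, breakpoints = bres,
         attribution = list(loo = loo, mean_rsc = mean_rsc, pairs = pairs,
                            killing = killing),
         flux_trends = flux_trends, mc = mc, truth = inp$truth,
         log = list(window = cfg$window, smooth = cfg$smooth,
                    pre_window = cfg$pre_window, fit_window = cfg$fit_window,
                    alpha_global = cfg$alpha_global,
                    alpha_removal = cfg$alpha_removal,
                    psi_mode = cfg$psi_mode, n_boot = cfg$n_boot,
                    psi_reference = psi_ref, seed = cfg$seed)),
    class = "sink_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.sink_report <- function(x, ...) {
  cat("<sink_report>\n")
  cat(sprintf("  datasets: %s\n", paste(names(x$efficiency), collapse = ", ")))
  cat(sprintf("  breakpoints: %s (mean %.1f)\n",
              paste(sprintf("%.1f", x$breakpoints$psi), collapse = ", "),
              mean(x$breakpoints$psi)))
  cat(sprintf("  top region by mean R_sc: %s (%.1f%%)\n",
              x$attribution$mean_rsc$removed[1],
              x$attribution$mean_rsc$r_sc_percent[1]))
  if (length(x$attribution$killing)) {
    cat(sprintf("  breakpoint-killing pairs: %s\n",
                paste(x$attribution$killing, collapse = "; ")))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `efficiency_<dataset>.csv`, `pre_trends.csv`, `breakpoints.csv`
#' (+`breakpoints.json`), `attribution_loo.csv`, `attribution_pairs.csv`,
#' `flux_trends.csv`, `mc_envelope.csv` and `run_log.json` under `dir`.
#'
#' @param report a `sink_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sink_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in names(report$efficiency)) {
    write_efficiency(report$efficiency[[d]],
                     file.path(dir, paste0("efficiency_", d, ".csv")))
  }
  utils::write.csv(report$pre_trends, file.path(dir, "pre_trends.csv"),
                   row.names = FALSE)
  utils::write.csv(report$breakpoints, file.path(dir, "breakpoints.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$breakpoints,
                       file.path(dir, "breakpoints.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(report$attribution$loo,
                   file.path(dir, "attribution_loo.csv"), row.names = FALSE)
  if (!is.null(report$attribution$pairs)) {
    utils::write.csv(report$attribution$pairs,
                     file.path(dir, "attribution_pairs.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$flux_trends, file.path(dir, "flux_trends.csv"),
                   row.names = FALSE)
  write_mc_envelope(report$mc$envelope, file.path(dir, "mc_envelope.csv"),
                    file.path(dir, "mc_envelope.json"))
  jsonlite::write_json(report$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
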