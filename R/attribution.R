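# Regional attribution of the global efficiency breakpoint via the
# slope-change ratio R_sc, with one-region and two-region removals.

#' Slope-change ratio of a region removal
#'
#' For a global segmented fit with slopes `s1`, `s2` and the re-fit after
#' removing one or two regions with slopes `s1'`, `s2'`, the contribution
#' of the removal is
#' `R_sc = (1 - (s2' - s1') / (s2 - s1)) * 100` (percent).
#' Positive values mean the removal weakens the slope reversal in the
#' remainder, i.e. the removed region strengthens the global reversal;
#' negative values mean it weakens the reversal. A degenerate global
#' slope change (|s2 - s1| below `tol`) yields `NA` with a `degenerate`
#' attribute rather than an error.
#'
#' @param global_fit [fit_segmented()] result on the full global series.
#' @param reduced_fit fit on the series with region(s) removed.
#' @param tol degeneracy tolerance for |s2 - s1|.
#' @return R_sc in percent (possibly `NA` if degenerate).
#' @export
slope_change_ratio <- function(global_fit, reduced_fit, tol = 1e-12) {
  stopifnot(inherits(global_fit, "breakpoint_fit"),
            inherits(reduced_fit, "breakpoint_fit"))
  d <- global_fit$s2 - global_fit$s1
  if (abs(d) <= tol) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  dp <- reduced_fit$s2 - reduced_fit$s1
  (1 - dp / d) * 100
}

# shared worker for one- and two-region removals
removal_fits <- function(panel, removals, window, fit_window, min_seg,
                         grid_step, alpha, psi_mode, n_boot, seed, guard,
                         global_fit, inference) {
  rows <- vector("list", length(removals))
  for (i in seq_along(removals)) {
    drop <- removals[[i]]
    row <- data.frame(
      removed = paste(drop, collapse = " + "),
      psi_prime = NA_real_, s1p = NA_real_, s2p = NA_real_,
      p_prime = NA_real_, r_sc_percent = NA_real_,
      detectable = NA, no_breakpoint = NA, degenerate = FALSE,
      valid = FALSE, stringsAsFactors = FALSE
    )
    e_red <- tryCatch(
      panel_efficiency(panel, drop = drop, window = window, guard = guard),
      error = function(e) e
    )
    if (inherits(e_red, "error")) {
      row$removed <- paste(drop, collapse = " + ")
      rows[[i]] <- row  # guard violated after removal: flagged invalid
      next
    }
    fit_r <- fit_segmented(
      e_red, window = fit_window, min_seg = min_seg, grid_step = grid_step,
      psi = if (psi_mode == "fixed") global_fit$psi else NULL
    )
    rsc <- slope_change_ratio(global_fit, fit_r)
    row$psi_prime <- fit_r$psi
    row$s1p <- fit_r$s1; row$s2p <- fit_r$s2
    row$r_sc_percent <- as.numeric(rsc)
    row$degenerate <- isTRUE(attr(rsc, "degenerate"))
    row$no_breakpoint <- fit_r$no_breakpoint
    row$valid <- TRUE
    if (inference) {
      p <- breakpoint_significance(fit_r, n_boot = n_boot,
                                   seed = derive_seed(seed, i))
      row$p_prime <- as.numeric(p)
      row$detectable <- !fit_r$no_breakpoint && row$p_prime <= alpha
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Leave-one-region-out attribution of the global breakpoint
#'
#' For every region, rebuilds the global efficiency from the remaining
#' regions, re-fits the segmented regression on the same fit window,
#' and reports the reduced slopes, the slope-change ratio R_sc, the
#' significance of the reduced breakpoint and a detectability flag at
#' `alpha`. The breakpoint is re-estimated on each reduced series by
#' default (`psi_mode = "free"`); `psi_mode = "fixed"` keeps the global
#' breakpoint year.
#'
#' @param panel a [flux_panel()] with per-region F, L and B (or BL).
#' @param window flux smoothing window in years (odd; default 5).
#' @param fit_window `c(start, end)` smoothed years for the segmented fit
#'   (default 1996-2016).
#' @param min_seg minimum points per segment.
#' @param grid_step breakpoint candidate spacing in years.
#' @param alpha detectability threshold on the reduced-series p-value
#'   (default 0.1, the removal-experiment level).
#' @param psi_mode `"free"` (re-estimate psi) or `"fixed"` (global psi).
#' @param n_boot bootstrap replicates for the reduced-series p-values.
#' @param seed integer seed (sub-seeded per removal).
#' @param guard denominator guard passed to [sink_efficiency()].
#' @param global_fit optional precomputed global fit (recomputed if NULL).
#' @param inference compute p-values and detectability flags (set FALSE to
#'   skip the bootstrap when only R_sc is needed).
#' @return a data.frame with one row per region: `removed`, `psi_prime`,
#'   `s1p`, `s2p`, `p_prime`, `r_sc_percent`, `detectable`,
#'   `no_breakpoint`, `degenerate`, `valid`; the global fit is attached as
#'   attribute `global_fit`.
#' @export
leave_one_out <- function(panel, window = 5L, fit_window = c(1996, 2016),
                          min_seg = 3, grid_step = 0.01, alpha = 0.1,
                          psi_mode = c("free", "fixed"), n_boot = 199,
                          seed = NULL, guard = 0.1, global_fit = NULL,
                          inference = TRUE) {
  psi_mode <- match.arg(psi_mode)
  stopifnot(inherits(panel, "flux_panel"), length(panel$regions) >= 2)
  if (is.null(global_fit)) {
    e_glob <- panel_efficiency(panel, window = window, guard = guard)
    global_fit <- fit_segmented(e_glob, window = fit_window,
                                min_seg = min_seg, grid_step = grid_step)
  }
  out <- removal_fits(panel, as.list(panel$regions), window, fit_window,
                      min_seg, grid_step, alpha, psi_mode, n_boot, seed,
                      guard, global_fit, inference)
  attr(out, "global_fit") <- global_fit
  out
}

#' Leave-two-regions-out attribution
#'
#' Evaluates all unordered region pairs; pairs whose removal makes the
#' reduced breakpoint insignificant (`p > alpha`) or makes the SSE profile
#' flat ("no distinct breakpoint") are the breakpoint-killing pairs,
#' returned in the `killing` attribute.
#'
#' @inheritParams leave_one_out
#' @return a data.frame with one row per pair (same columns as
#'   [leave_one_out()]); attributes `global_fit` and `killing`.
#' @export
leave_pairs_out <- function(panel, window = 5L, fit_window = c(1996, 2016),
                            min_seg = 3, grid_step = 0.01, alpha = 0.1,
                            psi_mode = c("free", "fixed"), n_boot = 199,
                            seed = NULL, guard = 0.1, global_fit = NULL,
                            inference = TRUE) {
  psi_mode <- match.arg(psi_mode)
  stopifnot(inherits(panel, "flux_panel"), length(panel$regions) >= 3)
  if (is.null(global_fit)) {
    e_glob <- panel_efficiency(panel, window = window, guard = guard)
    global_fit <- fit_segmented(e_glob, window = fit_window,
                                min_seg = min_seg, grid_step = grid_step)
  }
  prs <- utils::combn(panel$regions, 2, simplify = FALSE)
  out <- removal_fits(panel, prs, window, fit_window, min_seg, grid_step,
                      alpha, psi_mode, n_boot, seed, guard, global_fit,
                      inference)
  out$region1 <- vapply(prs, `[`, "", 1)
  out$region2 <- vapply(prs, `[`, "", 2)
  attr(out, "global_fit") <- global_fit
  if (inference) {
    kill <- out$valid & (out$no_breakpoint | out$p_prime > alpha)
    attr(out, "killing") <- out$removed[kill]
  }
  out
}
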