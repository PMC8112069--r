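# Land carbon sink efficiency E = B / (F + L): residual sink, moving-
# window smoothing and the efficiency ratio itself.

#' Construct an efficiency series
#'
#' @param E dimensionless efficiency values.
#' @param years integer years.
#' @param window smoothing window (years) used to produce `E`; 1 = none.
#' @param dataset source dataset id.
#' @param l_source label of the land-use-change flux source.
#' @return an object of class `efficiency_series`.
#' @export
efficiency_series <- function(E, years, window = 1L, dataset = "unnamed",
                              l_source = "unnamed") {
  years <- as.integer(years)
  stopifnot(length(E) == length(years), length(E) >= 1)
  if (any(!is.finite(E))) stop("E must be finite", call. = FALSE)
  structure(
    list(years = years, E = as.numeric(E), window = as.integer(window),
         source_panel = dataset, L_source = l_source),
    class = "efficiency_series"
  )
}

#' @export
print.efficiency_series <- function(x, ...) {
  cat(sprintf(
    "<efficiency_series> %s (L: %s), window %d yr, years %d-%d, mean E %.3f\n",
    x$source_panel, x$L_source, x$window, min(x$years), max(x$years),
    mean(x$E)))
  invisible(x)
}

#' @export
as.data.frame.efficiency_series <- function(x, ...) {
  data.frame(year = x$years, E = x$E)
}

#' Natural land sink as the residual of the global carbon budget
#'
#' Closes the budget F + L = B + O + G_atm for B:
#' `B = F + L - G_atm - O`.
#'
#' @param f fossil emissions (kind `"F"`).
#' @param l land-use change emissions (kind `"L"`).
#' @param g_atm atmospheric growth (kind `"G_atm"`).
#' @param o ocean sink (kind `"O"`).
#' @return a `flux_series` of kind `"B"`.
#' @export
residual_land_sink <- function(f, l, g_atm, o) {
  check_kind(f, "F"); check_kind(l, "L")
  check_kind(g_atm, "G_atm"); check_kind(o, "O")
  check_aligned(f, l, "F"); check_aligned(f, g_atm, "F")
  check_aligned(f, o, "F")
  flux_series(f$values + l$values - g_atm$values - o$values, f$years, "B",
              region = f$region, dataset = f$dataset_id)
}

#' Centered moving average with edge trimming
#'
#' Means over full windows only: the output year axis loses
#' `(window - 1) / 2` years at each end (1957-2018 with a 5-yr window
#' becomes 1959-2016).
#'
#' @param x a [flux_series()], [efficiency_series()] or numeric vector.
#' @param window odd positive integer window width in years.
#' @param ... unused.
#' @return same type as `x`, on the trimmed year axis.
#' @export
moving_average <- function(x, window = 5L, ...) UseMethod("moving_average")

ma_values <- function(v, window) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  if (window > length(v)) {
    stop("`window` exceeds series length", call. = FALSE)
  }
  if (window == 1L) return(v)
  h <- (window - 1L) %/% 2L
  sm <- stats::filter(v, rep(1 / window, window), sides = 2)
  as.numeric(sm[(h + 1L):(length(v) - h)])
}

#' @export
moving_average.numeric <- function(x, window = 5L, ...) ma_values(x, window)

#' @export
moving_average.flux_series <- function(x, window = 5L, ...) {
  h <- (as.integer(window) - 1L) %/% 2L
  v <- ma_values(x$values, window)
  yrs <- if (h > 0) x$years[(h + 1L):(length(x$years) - h)] else x$years
  flux_series(v, yrs, x$kind, region = x$region, dataset = x$dataset_id)
}

#' @export
moving_average.efficiency_series <- function(x, window = 5L, ...) {
  h <- (as.integer(window) - 1L) %/% 2L
  v <- ma_values(x$E, window)
  yrs <- if (h > 0) x$years[(h + 1L):(length(x$years) - h)] else x$years
  efficiency_series(v, yrs, window = window, dataset = x$source_panel,
                    l_source = x$L_source)
}

#' Land carbon sink efficiency E = B / (F + L)
#'
#' With `window > 1` the fluxes are smoothed with a centered moving
#' average before forming the ratio (`smooth = "fluxes"`, the default);
#' `smooth = "efficiency"` instead smooths the annual ratio, provided as a
#' sensitivity variant. E = 1 marks carbon neutrality (natural uptake
#' offsets all fossil and land-use emissions).
#'
#' @param b natural land sink (kind `"B"`).
#' @param f fossil emissions (kind `"F"`).
#' @param l land-use change emissions (kind `"L"`).
#' @param window odd smoothing window in years (1 = annual values).
#' @param guard minimum allowed denominator F + L in Pg C yr^-1; a smaller
#'   denominator is an error naming the offending year (regional series
#'   can have near-zero emissions; a silently infinite E must not leak
#'   into trend fits).
#' @param smooth smoothing order, see above.
#' @param l_source label recorded as the L provenance.
#' @return an [efficiency_series()].
#' @export
sink_efficiency <- function(b, f, l, window = 1L, guard = 0.1,
                            smooth = c("fluxes", "efficiency"),
                            l_source = NULL) {
  smooth <- match.arg(smooth)
  check_kind(b, "B"); check_kind(f, "F"); check_kind(l, "L")
  check_aligned(b, f, "B"); check_aligned(b, l, "B")
  l_source <- l_source %||% l$dataset_id
  ratio <- function(bv, fv, lv, yrs) {
    den <- fv + lv
    if (any(den <= guard)) {
      bad <- yrs[which(den <= guard)[1]]
      stop(sprintf(
        "denominator F + L (%.3g) at or below guard %.3g in year %d",
        den[which(den <= guard)[1]], guard, bad), call. = FALSE)
    }
    bv / den
  }
  if (window > 1L && smooth == "fluxes") {
    bs <- moving_average(b, window); fs <- moving_average(f, window)
    ls <- moving_average(l, window)
    E <- ratio(bs$values, fs$values, ls$values, bs$years)
    yrs <- bs$years
  } else {
    E <- ratio(b$values, f$values, l$values, b$years)
    yrs <- b$years
    if (window > 1L) {
      E <- ma_values(E, window)
      h <- (as.integer(window) - 1L) %/% 2L
      yrs <- yrs[(h + 1L):(length(yrs) - h)]
    }
  }
  efficiency_series(E, yrs, window = window, dataset = b$dataset_id,
                    l_source = l_source)
}

#' Global efficiency of a panel, optionally after removing regions
#'
#' Sums B, F and L over the retained regions (GLOBAL is re-derived, never
#' cached) and forms the smoothed efficiency. If the panel lacks B it is
#' reconstructed as BL + L.
#'
#' @param panel a [flux_panel()].
#' @param drop regions to remove before aggregating (default none).
#' @inheritParams sink_efficiency
#' @return an [efficiency_series()].
#' @export
panel_efficiency <- function(panel, drop = character(), window = 5L,
                             guard = 0.1, smooth = c("fluxes", "efficiency")) {
  stopifnot(inherits(panel, "flux_panel"))
  p <- remove_regions(panel, drop)
  f <- panel_global(p, "F")
  l <- panel_global(p, "L")
  b <- if ("B" %in% names(p$flux)) {
    panel_global(p, "B")
  } else {
    b_from_bl(panel_global(p, "BL"), l)
  }
  sink_efficiency(b, f, l, window = window, guard = guard, smooth = smooth)
}

#' Write an efficiency series to CSV (+ JSON provenance)
#'
#' @param e an [efficiency_series()].
#' @param csv_path output CSV path (`year,E`).
#' @param json_path optional path for provenance metadata (dataset,
#'   L source, window).
#' @return `csv_path`, invisibly.
#' @export
write_efficiency <- function(e, csv_path, json_path = NULL) {
  stopifnot(inherits(e, "efficiency_series"))
  utils::write.csv(as.data.frame(e), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(dataset = e$source_panel, l_source = e$L_source,
           window = e$window, years = range(e$years)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
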