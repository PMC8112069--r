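# Per-year flux uncertainty from dataset spread, and Monte Carlo
# propagation of flux uncertainties to the efficiency E.

#' Per-year spread of an ensemble of flux series
#'
#' Sample standard deviation (denominator n - 1) across ensemble members
#' for each year, e.g. across the available land-use-change or net-land-
#' sink products.
#'
#' @param ensemble list of [flux_series()] of one kind on one year axis.
#' @return named numeric vector of per-year standard deviations.
#' @export
flux_spread <- function(ensemble) {
  if (length(ensemble) < 2) {
    stop("need at least 2 ensemble members for a spread", call. = FALSE)
  }
  stopifnot(all(vapply(ensemble, inherits, TRUE, "flux_series")))
  kinds <- unique(vapply(ensemble, `[[`, "", "kind"))
  if (length(kinds) != 1) {
    stop("ensemble members must share one flux kind", call. = FALSE)
  }
  for (s in ensemble[-1]) check_aligned(ensemble[[1]], s, "ensemble")
  m <- do.call(rbind, lapply(ensemble, `[[`, "values"))
  sds <- apply(m, 2, stats::sd)
  names(sds) <- ensemble[[1]]$years
  sds
}

#' Monte Carlo uncertainty envelope of the sink efficiency
#'
#' Per draw and per year, samples `F* ~ N(F, (f_rel_sd * F)^2)`,
#' `L* ~ N(L, sd_l^2)`, `BL* ~ N(BL, sd_bl^2)` (all independent across
#' years and components), forms `B* = BL* + L*` and
#' `E* = B* / (F* + L*)`, and returns the mean and standard deviation of
#' E over draws. Draws whose denominator `F* + L*` falls at or below
#' `guard` are resampled (the count is recorded). Fossil uncertainty is a
#' relative 1-sigma (default 5%).
#'
#' @param f,bl,l aligned [flux_series()] (kinds F, BL, L); typically the
#'   smoothed fluxes the efficiency pipeline uses.
#' @param sd_l,sd_bl per-year standard deviations (scalar or one per
#'   year), e.g. from [flux_spread()].
#' @param f_rel_sd relative 1-sigma uncertainty of F (default 0.05).
#' @param n number of draws (default 10000).
#' @param seed integer seed.
#' @param guard lowest admissible denominator in a draw.
#' @param max_resample resampling rounds before giving up.
#' @return an object of class `mc_envelope`: `years`, `E_mean`, `E_sd`,
#'   `n_draws`, `seed`, `resampled`, `component_sds`.
#' @export
mc_efficiency <- function(f, bl, l, sd_l = 0, sd_bl = 0, f_rel_sd = 0.05,
                          n = 10000, seed = NULL, guard = 1e-6,
                          max_resample = 100) {
  check_kind(f, "F"); check_kind(bl, "BL"); check_kind(l, "L")
  check_aligned(f, bl, "F"); check_aligned(f, l, "F")
  ny <- length(f$years)
  expand <- function(s, nm) {
    if (length(s) == 1) s <- rep(s, ny)
    if (length(s) != ny) stop(sprintf("%s must be scalar or per-year", nm),
                              call. = FALSE)
    if (any(s < 0)) stop(sprintf("%s must be >= 0", nm), call. = FALSE)
    s
  }
  sd_l <- expand(sd_l, "sd_l"); sd_bl <- expand(sd_bl, "sd_bl")
  sd_f <- f_rel_sd * f$values
  res <- with_seed(seed, {
    draw <- function(nn) {
      list(
        f = matrix(stats::rnorm(nn * ny, rep(f$values, each = nn),
                                rep(sd_f, each = nn)), nn, ny),
        l = matrix(stats::rnorm(nn * ny, rep(l$values, each = nn),
                                rep(sd_l, each = nn)), nn, ny),
        bl = matrix(stats::rnorm(nn * ny, rep(bl$values, each = nn),
                                 rep(sd_bl, each = nn)), nn, ny)
      )
    }
    d <- draw(n)
    resampled <- 0L
    for (k in seq_len(max_resample)) {
      bad <- which(d$f + d$l <= guard)
      if (!length(bad)) break
      resampled <- resampled + length(bad)
      cols <- ((bad - 1L) %/% n) + 1L  # year index of each offending cell
      d$f[bad] <- stats::rnorm(length(bad), f$values[cols], sd_f[cols])
      d$l[bad] <- stats::rnorm(length(bad), l$values[cols], sd_l[cols])
      d$bl[bad] <- stats::rnorm(length(bad), bl$values[cols], sd_bl[cols])
    }
    if (length(which(d$f + d$l <= guard))) {
      stop("Monte Carlo denominator guard could not be satisfied",
           call. = FALSE)
    }
    e <- (d$bl + d$l) / (d$f + d$l)
    list(mean = colMeans(e),
         sd = apply(e, 2, stats::sd),
         resampled = resampled)
  })
  structure(
    list(years = f$years, E_mean = res$mean, E_sd = res$sd,
         n_draws = as.integer(n), seed = seed, resampled = res$resampled,
         component_sds = list(F = sd_f, L = sd_l, BL = sd_bl)),
    class = "mc_envelope"
  )
}

#' @export
print.mc_envelope <- function(x, ...) {
  cat(sprintf(
    "<mc_envelope> %d draws, years %d-%d: mean E_sd %.4g (%d resampled draws)\n",
    x$n_draws, min(x$years), max(x$years), mean(x$E_sd), x$resampled))
  invisible(x)
}

#' Write a Monte Carlo envelope to CSV (+ JSON metadata)
#'
#' @param env an [mc_efficiency()] envelope.
#' @param csv_path output CSV (`year,E_mean,E_sd`).
#' @param json_path optional metadata path (n, seed, component sigmas).
#' @return `csv_path`, invisibly.
#' @export
write_mc_envelope <- function(env, csv_path, json_path = NULL) {
  stopifnot(inherits(env, "mc_envelope"))
  utils::write.csv(
    data.frame(year = env$years, E_mean = env$E_mean, E_sd = env$E_sd),
    csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_draws = env$n_draws, seed = env$seed,
           resampled = env$resampled,
           component_sds = lapply(env$component_sds, unname)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Compare the Monte Carlo uncertainty of E to its interannual variability
#'
#' The interannual variability is the standard deviation of the efficiency
#' anomalies after removing the fitted segmented trend; the comparison
#' reports whether the mean Monte Carlo uncertainty is smaller (a
#' prerequisite for calling the trend reversal robust).
#'
#' @param env an [mc_efficiency()] envelope.
#' @param e the matching [efficiency_series()].
#' @param fit optional [fit_segmented()] on `e` used for detrending; fitted
#'   on the overlap if `NULL`.
#' @return a list: `mean_uncertainty`, `iav_sd`, `ratio`
#'   (uncertainty / IAV) and `uncertainty_smaller`.
#' @export
compare_uncertainty_to_iav <- function(env, e, fit = NULL) {
  stopifnot(inherits(env, "mc_envelope"), inherits(e, "efficiency_series"))
  common <- intersect(env$years, e$years)
  if (length(common) < 7) stop("too little overlap between envelope and E",
                               call. = FALSE)
  if (is.null(fit)) {
    fit <- fit_segmented(e, window = range(common))
  }
  resid <- fit$values - fit$fitted
  # noise scale of the anomalies: divide by the residual degrees of
  # freedom of the 4-parameter segmented model, not n - 1
  iav <- sqrt(sum((resid - mean(resid))^2) / max(fit$n - 4, 1))
  mu <- mean(env$E_sd[env$years %in% common])
  list(mean_uncertainty = mu, iav_sd = iav,
       ratio = if (iav > 0) mu / iav else Inf,
       uncertainty_smaller = mu < iav)
}
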