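# Linear trends and continuous one-breakpoint segmented regression.
#
# The segmented model is y = b0 + b1*t + b2*(t - psi)_+ , continuous at
# the breakpoint psi. psi is estimated by profiling the residual sum of
# squares over a fine grid of candidate breakpoints between the admissible
# years (>= min_seg points on each side), with the smallest psi winning
# ties. Significance of the slope change and the confidence interval for
# psi are bootstrap-based by default, with analytic alternatives.

# extract (years, values) from the objects trend functions accept
series_xy <- function(x, years = NULL) {
  if (inherits(x, "flux_series")) {
    list(years = as.numeric(x$years), values = x$values)
  } else if (inherits(x, "efficiency_series")) {
    list(years = as.numeric(x$years), values = x$E)
  } else if (is.list(x) && !is.null(x$years) && !is.null(x$values)) {
    list(years = as.numeric(x$years), values = as.numeric(x$values))
  } else if (is.numeric(x)) {
    if (is.null(years)) stop("`years` required for a bare numeric vector",
                             call. = FALSE)
    stopifnot(length(years) == length(x))
    list(years = as.numeric(years), values = as.numeric(x))
  } else {
    stop("cannot extract an annual series from this object", call. = FALSE)
  }
}

subset_window <- function(xy, window) {
  if (is.null(window)) return(xy)
  stopifnot(length(window) == 2)
  keep <- xy$years >= window[1] & xy$years <= window[2]
  if (!any(keep)) stop("window outside the data years", call. = FALSE)
  list(years = xy$years[keep], values = xy$values[keep])
}

#' Ordinary linear trend of an annual series
#'
#' OLS slope and intercept with a two-sided t-test on the slope
#' (n - 2 degrees of freedom).
#'
#' @param x a [flux_series()], [efficiency_series()], a `list(years,
#'   values)`, or a numeric vector (then supply `years`).
#' @param years year axis when `x` is a bare numeric vector.
#' @param window optional `c(start, end)` year window to fit within.
#' @return an object of class `linear_trend`: slope (units per year),
#'   intercept (at year 0), `p_value`, `r2`, `se`, `n`, `window`.
#' @export
fit_linear <- function(x, years = NULL, window = NULL) {
  xy <- subset_window(series_xy(x, years), window)
  t <- xy$years; y <- xy$values; n <- length(y)
  if (n < 3) stop("need at least 3 points for a linear trend", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[2]; intercept <- fit$coefficients[1]
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  sxx <- sum((t - mean(t))^2)
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- if (se > 0) slope / se else Inf * sign(slope)
  p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), n - 2) else 0
  if (sse == 0 && slope == 0) p <- 1  # constant series: no trend to test
  structure(
    list(slope = unname(slope), intercept = unname(intercept),
         p_value = p, r2 = if (sst > 0) 1 - sse / sst else NA_real_,
         se = unname(se), sse = sse, n = n,
         window = c(min(t), max(t))),
    class = "linear_trend"
  )
}

#' @export
print.linear_trend <- function(x, ...) {
  cat(sprintf(
    "<linear_trend> %d-%d (n=%d): slope %.4g per yr (p = %.3g, r2 = %.3f)\n",
    x$window[1], x$window[2], x$n, x$slope, x$p_value, x$r2))
  invisible(x)
}

# admissible breakpoint candidates: fine grid spanning the closed interval
# [t_(min_seg), t_(n - min_seg + 1)], so both segments keep >= min_seg points
seg_candidates <- function(t, min_seg, grid_step) {
  lo <- t[min_seg]; hi <- t[length(t) - min_seg + 1]
  if (hi <= lo) stop("window too short for the requested min_seg",
                     call. = FALSE)
  cand <- seq(lo, hi, by = grid_step)
  if (cand[length(cand)] < hi) cand <- c(cand, hi)
  cand
}

# SSE profile of the segmented model over candidate breakpoints, for one
# series (y vector) or many (y matrix, columns = series). Returns, per
# series, the minimizing candidate (first index on ties -> smallest psi),
# its SSE, and the straight-line SSE.
seg_profile <- function(t, y, cand) {
  y <- as.matrix(y)
  qx <- qr(cbind(1, t))
  ry <- qr.resid(qx, y)                      # n x B
  U <- outer(t, cand, function(a, b) pmax(a - b, 0))
  ru <- qr.resid(qx, U)                      # n x K
  den <- colSums(ru^2)                       # K
  num <- crossprod(ru, ry)                   # K x B
  sse_lin <- colSums(ry^2)                   # B
  gain <- num^2 / ifelse(den > 1e-12, den, Inf)
  idx <- max.col(t(gain), ties.method = "first")
  sse <- pmax(sse_lin - gain[cbind(idx, seq_along(idx))], 0)
  list(psi = cand[idx], sse = sse, sse_lin = sse_lin, idx = idx)
}

# coefficients of the segmented model at a fixed breakpoint
seg_refit <- function(t, y, psi) {
  X <- cbind(1, t, pmax(t - psi, 0))
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  sse <- sum(fit$residuals^2)
  list(beta = unname(beta), sse = sse, fitted = as.numeric(X %*% beta))
}

#' One-breakpoint segmented regression on an annual series
#'
#' Fits `y = b0 + b1*t + b2*(t - psi)_+` (continuous at `psi`), choosing
#' `psi` to minimize the residual sum of squares over a fine grid of
#' candidates that keep at least `min_seg` points in each segment. Ties
#' are broken toward the smallest `psi`. With `refine = TRUE` the grid
#' optimum is polished by continuous optimization within one grid step.
#'
#' If the best segmented fit does not improve on the straight line beyond
#' `flat_tol` (relative), the fit is flagged `no_breakpoint`.
#'
#' @inheritParams fit_linear
#' @param min_seg minimum points per segment (default 3).
#' @param grid_step candidate spacing in years (default 0.01).
#' @param refine polish the grid optimum by continuous search.
#' @param flat_tol relative SSE-gain threshold below which the profile is
#'   considered flat (no distinct breakpoint).
#' @param psi fix the breakpoint at this value instead of estimating it
#'   (used by the psi-fixed attribution mode).
#' @return an object of class `breakpoint_fit`: `psi`, slopes `s1`
#'   (pre-break) and `s2` (post-break), `intercept`, `sse`, `sse_linear`,
#'   `n`, `window`, `no_breakpoint`, and `p_value` / `ci95` slots filled
#'   by [breakpoint_significance()] / [breakpoint_ci()].
#' @export
fit_segmented <- function(x, years = NULL, window = NULL, min_seg = 3,
                          grid_step = 0.01, refine = FALSE,
                          flat_tol = 1e-10, psi = NULL) {
  xy <- subset_window(series_xy(x, years), window)
  t <- xy$years; y <- xy$values; n <- length(y)
  if (n < 2 * min_seg + 1) {
    stop(sprintf("window too short: need >= %d points, have %d",
                 2 * min_seg + 1, n), call. = FALSE)
  }
  if (is.null(psi)) {
    cand <- seg_candidates(t, min_seg, grid_step)
    prof <- seg_profile(t, y, cand)
    psi_hat <- prof$psi[1]
    if (refine) {
      lo <- max(cand[1], psi_hat - grid_step)
      hi <- min(cand[length(cand)], psi_hat + grid_step)
      opt <- stats::optimize(function(p) seg_refit(t, y, p)$sse, c(lo, hi))
      if (opt$objective < prof$sse[1]) psi_hat <- opt$minimum
    }
  } else {
    psi_hat <- psi
    if (psi_hat <= t[1] || psi_hat >= t[n]) {
      stop("fixed psi must lie strictly inside the window", call. = FALSE)
    }
  }
  fit <- seg_refit(t, y, psi_hat)
  lin <- stats::lm.fit(cbind(1, t), y)
  sse_lin <- sum(lin$residuals^2)
  gain <- sse_lin - fit$sse
  flat <- gain <= flat_tol * max(sse_lin, .Machine$double.eps)
  structure(
    list(psi = psi_hat,
         s1 = fit$beta[2], s2 = fit$beta[2] + fit$beta[3],
         beta2 = fit$beta[3], intercept = fit$beta[1],
         sse = fit$sse, sse_linear = sse_lin, n = n,
         window = c(min(t), max(t)), min_seg = min_seg,
         grid_step = grid_step, psi_fixed = !is.null(psi),
         no_breakpoint = flat,
         p_value = NA_real_, ci95 = c(NA_real_, NA_real_),
         fitted = fit$fitted, years = t, values = y),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<breakpoint_fit> %d-%d (n=%d): psi = %.2f, s1 = %.4g,",
           " s2 = %.4g per yr%s\n  p = %s, 95%% CI [%s, %s]\n"),
    x$window[1], x$window[2], x$n, x$psi, x$s1, x$s2,
    if (x$no_breakpoint) " [no distinct breakpoint]" else "",
    format(x$p_value, digits = 3), format(x$ci95[1], digits = 6),
    format(x$ci95[2], digits = 6)))
  invisible(x)
}

#' Significance of the slope change at the breakpoint
#'
#' Tests H0 "single straight line" against H1 "one continuous breakpoint".
#' The default is a seeded parametric bootstrap of the SSE-ratio statistic
#' `(SSE_linear - SSE_segmented) / SSE_segmented`: null series are drawn
#' as the H0 line plus Gaussian noise at the H0 residual scale, and the
#' statistic is recomputed with the same breakpoint search on each draw.
#' `method = "davies"` instead gives a Davies-type upper bound from the
#' maximum of the pointwise slope-change t-statistics over the candidate
#' grid (conservative, no randomness).
#'
#' @param fit a [fit_segmented()] result (it retains its data).
#' @param method `"bootstrap"` (default) or `"davies"`.
#' @param n_boot bootstrap replicates; fewer than 100 triggers a warning.
#' @param seed integer seed for the bootstrap.
#' @param grid_step candidate spacing used inside the test (may be coarser
#'   than the fit's; the observed statistic and the null draws always use
#'   the same grid).
#' @param ar1_correct draw the bootstrap null with AR(1) noise at the
#'   lag-1 autocorrelation of the H0 residuals instead of white noise.
#'   Smoothed series are autocorrelated by construction, which makes the
#'   white-noise null anti-conservative; the uncorrected test is kept as
#'   the default because the reference analysis works on the smoothed
#'   series directly.
#' @return the p-value, with attributes `method` and `stat`.
#' @export
breakpoint_significance <- function(fit, method = c("bootstrap", "davies"),
                                    n_boot = 199, seed = NULL,
                                    grid_step = 0.25, ar1_correct = FALSE) {
  stopifnot(inherits(fit, "breakpoint_fit"))
  method <- match.arg(method)
  t <- fit$years; y <- fit$values; n <- fit$n
  cand <- seg_candidates(t, fit$min_seg, grid_step)
  obs <- seg_profile(t, y, cand)
  if (method == "davies") {
    qx <- qr(cbind(1, t))
    ry <- qr.resid(qx, y)
    U <- outer(t, cand, function(a, b) pmax(a - b, 0))
    ru <- qr.resid(qx, U)
    den <- colSums(ru^2)
    num <- as.vector(crossprod(ru, ry))
    sse_k <- sum(ry^2) - num^2 / ifelse(den > 1e-12, den, Inf)
    s2_k <- sse_k / (n - 3)
    tk <- num / sqrt(pmax(den, 1e-12)) / sqrt(pmax(s2_k, 1e-300))
    m <- max(abs(tk))
    v <- sum(abs(diff(tk)))
    p <- 2 * stats::pnorm(-m) + v * exp(-m^2 / 2) / sqrt(2 * pi)
    p <- min(1, max(p, 0))
    return(structure(p, method = "davies", stat = m))
  }
  if (n_boot < 100) warning("n_boot < 100: bootstrap p-value is coarse")
  stat <- function(prof) {
    (prof$sse_lin - prof$sse) / pmax(prof$sse, .Machine$double.eps)
  }
  t_obs <- stat(obs)
  lin <- stats::lm.fit(cbind(1, t), y)
  mu0 <- as.numeric(cbind(1, t) %*% lin$coefficients)
  sigma0 <- sqrt(sum(lin$residuals^2) / (n - 2))
  phi0 <- 0
  if (ar1_correct && n > 3) {
    r <- lin$residuals
    phi0 <- sum(r[-1] * r[-n]) / sum(r^2)
    phi0 <- max(min(phi0, 0.95), -0.95)
  }
  p <- with_seed(seed, {
    noise <- if (phi0 != 0) {
      vapply(seq_len(n_boot), function(b) ar1_noise(n, phi0, sigma0),
             numeric(n))
    } else {
      matrix(stats::rnorm(n * n_boot, 0, sigma0), n, n_boot)
    }
    tstar <- stat(seg_profile(t, mu0 + noise, cand))
    (1 + sum(tstar >= t_obs)) / (n_boot + 1)
  })
  structure(p, method = "bootstrap", stat = t_obs, n_boot = n_boot)
}

#' Confidence interval for the breakpoint year
#'
#' Default is a seeded parametric bootstrap: series are redrawn from the
#' fitted segmented model plus Gaussian noise at its residual scale, the
#' breakpoint is re-estimated on each draw with the fit's own grid, and
#' percentile bounds are taken. `method = "profile"` instead uses the
#' curvature of the SSE profile at the optimum (a delta-method style
#' approximation). The returned interval always contains the estimate.
#'
#' @param fit a [fit_segmented()] result.
#' @param level confidence level (default 0.95).
#' @param method `"bootstrap"` (default) or `"profile"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return `c(lo, hi)` in years.
#' @export
breakpoint_ci <- function(fit, level = 0.95,
                          method = c("bootstrap", "profile"),
                          n_boot = 199, seed = NULL) {
  stopifnot(inherits(fit, "breakpoint_fit"))
  method <- match.arg(method)
  if (fit$no_breakpoint && fit$sse_linear <= .Machine$double.eps) {
    stop("degenerate fit: series is exactly linear, psi is unidentified",
         call. = FALSE)
  }
  t <- fit$years; n <- fit$n
  alpha <- 1 - level
  if (method == "profile") {
    sigma2 <- fit$sse / max(n - 4, 1)
    h <- max(fit$grid_step, 0.5)
    ps <- c(fit$psi - h, fit$psi, fit$psi + h)
    ss <- vapply(ps, function(p) seg_refit(t, fit$values, p)$sse, 0)
    curv <- (ss[1] - 2 * ss[2] + ss[3]) / h^2
    se <- if (curv > 0) sqrt(2 * sigma2 / curv) else Inf
    z <- stats::qnorm(1 - alpha / 2)
    ci <- c(fit$psi - z * se, fit$psi + z * se)
  } else {
    sigma <- sqrt(fit$sse / max(n - 4, 1))
    cand <- seg_candidates(t, fit$min_seg, fit$grid_step)
    psis <- with_seed(seed, {
      ystar <- fit$fitted + matrix(stats::rnorm(n * n_boot, 0, sigma), n,
                                   n_boot)
      seg_profile(t, ystar, cand)$psi
    })
    ci <- unname(stats::quantile(psis, c(alpha / 2, 1 - alpha / 2)))
  }
  c(min(ci[1], fit$psi), max(ci[2], fit$psi))
}
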