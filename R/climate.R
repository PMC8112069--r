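# Climate covariates, the tropical climate-driver regression, index
# correlations and the El Nino masking transform.

#' Construct an annual climate covariate table
#'
#' @param years integer years (contiguous).
#' @param temperature air temperature (deg C, anomaly or absolute as
#'   declared by `temperature_is_anomaly`).
#' @param precipitation precipitation (mm yr^-1, anomaly or absolute).
#' @param co2 atmospheric CO2 concentration (ppm).
#' @param enso_index ENSO index (MEI-like), optional.
#' @param pdo_index Pacific Decadal Oscillation index, optional.
#' @param temperature_is_anomaly flag recorded with the object.
#' @return a data.frame of class `climate_covariates`.
#' @export
climate_covariates <- function(years, temperature, precipitation, co2,
                               enso_index = NULL, pdo_index = NULL,
                               temperature_is_anomaly = TRUE) {
  years <- as.integer(years)
  n <- length(years)
  stopifnot(length(temperature) == n, length(precipitation) == n,
            length(co2) == n)
  if (n > 1 && any(diff(years) != 1L)) {
    stop("covariate years must be contiguous", call. = FALSE)
  }
  df <- data.frame(
    year = years, temperature = as.numeric(temperature),
    precipitation = as.numeric(precipitation), co2 = as.numeric(co2),
    enso_index = if (is.null(enso_index)) NA_real_ else as.numeric(enso_index),
    pdo_index = if (is.null(pdo_index)) NA_real_ else as.numeric(pdo_index)
  )
  if (anyNA(df[c("year", "temperature", "precipitation", "co2")])) {
    stop("covariates must have no gaps", call. = FALSE)
  }
  structure(df, class = c("climate_covariates", "data.frame"),
            temperature_is_anomaly = temperature_is_anomaly)
}

#' Read / write covariates CSV
#'
#' Columns: `year,temperature,precipitation,co2,enso_index,pdo_index`.
#'
#' @param path CSV path.
#' @return a [climate_covariates()] table.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "temperature", "precipitation", "co2")
  if (!all(need %in% names(df))) {
    stop("covariates CSV must have columns: ",
         paste(need, collapse = ","), call. = FALSE)
  }
  climate_covariates(df$year, df$temperature, df$precipitation, df$co2,
                     enso_index = df$enso_index, pdo_index = df$pdo_index)
}

#' @rdname read_covariates
#' @param cov a [climate_covariates()] table.
#' @export
write_covariates <- function(cov, path) {
  utils::write.csv(as.data.frame(cov), path, row.names = FALSE)
  invisible(path)
}

#' Regress the tropical land sink on climate drivers
#'
#' Ordinary least squares of the annual (unsmoothed) tropical natural sink
#' B on temperature, precipitation and CO2 concentration. A high design
#' condition number triggers a collinearity warning.
#'
#' @param b_tropics tropical B series (kind `"B"`).
#' @param cov a [climate_covariates()] table; at least 8 overlapping years.
#' @param kappa_warn condition-number threshold for the warning.
#' @return an object of class `climate_regression`: `coefficients`
#'   (intercept, beta_T, beta_P, beta_CO2), `r2`, `residual_sd`,
#'   `predicted_b` (a `flux_series` on the covariate years), `model` (the
#'   underlying `lm`), `ci95` (coefficient intervals).
#' @export
fit_climate_regression <- function(b_tropics, cov, kappa_warn = 1e8) {
  check_kind(b_tropics, "B")
  stopifnot(inherits(cov, "climate_covariates"))
  common <- intersect(b_tropics$years, cov$year)
  if (length(common) < 8) {
    stop("need >= 8 overlapping years between B and covariates",
         call. = FALSE)
  }
  d <- data.frame(
    b = b_tropics$values[match(common, b_tropics$years)],
    temperature = cov$temperature[match(common, cov$year)],
    precipitation = cov$precipitation[match(common, cov$year)],
    co2 = cov$co2[match(common, cov$year)]
  )
  X <- cbind(1, d$temperature, d$precipitation, d$co2)
  if (kappa(X, exact = TRUE) > kappa_warn) {
    warning("covariates are nearly collinear; coefficients are unstable")
  }
  model <- stats::lm(b ~ temperature + precipitation + co2, data = d)
  sm <- summary(model)
  pred_all <- stats::predict(
    model, newdata = data.frame(temperature = cov$temperature,
                                precipitation = cov$precipitation,
                                co2 = cov$co2))
  structure(
    list(coefficients = stats::coef(model), r2 = sm$r.squared,
         residual_sd = sm$sigma,
         ci95 = stats::confint(model),
         predicted_b = flux_series(pred_all, cov$year, "B",
                                   region = b_tropics$region,
                                   dataset = paste0(b_tropics$dataset_id,
                                                    "_climate_pred")),
         years = common, model = model),
    class = "climate_regression"
  )
}

#' @export
print.climate_regression <- function(x, ...) {
  cat(sprintf(
    "<climate_regression> B ~ T + P + CO2 on %d years: r2 = %.3f, residual sd = %.3g\n",
    length(x$years), x$r2, x$residual_sd))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Breakpoint of the climate-predicted efficiency
#'
#' Forms `E_pred = predicted_B / (F + L)` with the pipeline's smoothing and
#' fits the segmented regression — the check that climate drivers alone
#' reproduce the efficiency reversal.
#'
#' @param reg a [fit_climate_regression()] result.
#' @param f,l fossil and land-use series aligned with the prediction years.
#' @param window smoothing window (default 5).
#' @param fit_window segmented-fit year window (`NULL` = all smoothed years).
#' @param ... passed to [fit_segmented()].
#' @return a [fit_segmented()] object on the predicted efficiency.
#' @export
predicted_efficiency_breakpoint <- function(reg, f, l, window = 5L,
                                            fit_window = NULL, ...) {
  stopifnot(inherits(reg, "climate_regression"))
  e_pred <- sink_efficiency(reg$predicted_b, f, l, window = window,
                            l_source = l$dataset_id)
  fit_segmented(e_pred, window = fit_window, ...)
}

#' Pearson correlation between a climate variable and an ocean index
#'
#' @param cov a [climate_covariates()] table.
#' @param var `"temperature"` or `"precipitation"`.
#' @param index `"enso"` or `"pdo"`.
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_index <- function(cov, var = c("temperature", "precipitation"),
                            index = c("enso", "pdo")) {
  stopifnot(inherits(cov, "climate_covariates"))
  var <- match.arg(var); index <- match.arg(index)
  x <- cov[[var]]
  y <- cov[[paste0(index, "_index")]]
  if (anyNA(y)) stop(sprintf("%s index not available", index), call. = FALSE)
  if (length(x) < 8) stop("need >= 8 years", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Replace selected years by the mean of donor years
#'
#' The El Nino masking sensitivity transform: e.g. replace the natural
#' sink in 2015 and 2016 by the mean of its 2014 and 2017 values. Target
#' and donor years must not overlap, so the transform is idempotent.
#'
#' @param s a [flux_series()].
#' @param target_years years whose values are replaced.
#' @param donor_years years whose mean value is substituted.
#' @return the modified `flux_series`.
#' @export
replace_years <- function(s, target_years, donor_years) {
  stopifnot(inherits(s, "flux_series"))
  target_years <- as.integer(target_years)
  donor_years <- as.integer(donor_years)
  if (length(target_years) == 0) return(s)
  if (length(intersect(target_years, donor_years))) {
    stop("target and donor years must be disjoint", call. = FALSE)
  }
  miss <- setdiff(c(target_years, donor_years), s$years)
  if (length(miss)) {
    stop("year(s) not in series: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v <- s$values
  v[match(target_years, s$years)] <- mean(v[match(donor_years, s$years)])
  flux_series(v, s$years, s$kind, region = s$region, dataset = s$dataset_id)
}
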