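# Annual carbon-flux series: the atomic data object of the package.
#
# Sign conventions are fixed per flux kind and enforced at construction:
# emissions to the atmosphere are positive for F (fossil), L (land-use
# change) and G_atm (atmospheric growth); uptake from the atmosphere is
# positive for B (natural land sink), BL (net land sink, B - L) and O
# (ocean sink).

#' Flux kinds and their sign conventions
#'
#' @format a named character vector mapping kind to sign convention.
#' @export
flux_kinds <- c(
  F     = "emission-positive",
  L     = "emission-positive",
  G_atm = "emission-positive",
  B     = "uptake-positive",
  BL    = "uptake-positive",
  O     = "uptake-positive"
)

#' Construct an annual carbon-flux series
#'
#' @param values numeric flux values in Pg C yr^-1, one per year.
#' @param years integer years, strictly increasing and contiguous.
#' @param kind one of `"F"`, `"L"`, `"B"`, `"BL"`, `"O"`, `"G_atm"`.
#' @param region region label; `"GLOBAL"` for global series.
#' @param dataset dataset identifier (e.g. an inversion or budget product).
#' @return an object of class `flux_series`.
#' @examples
#' f <- flux_series(c(9.0, 9.2, 9.4), 2009:2011, kind = "F")
#' @export
flux_series <- function(values, years, kind, region = "GLOBAL",
                        dataset = "unnamed") {
  kind <- match.arg(kind, names(flux_kinds))
  years <- unname(as.integer(years))
  values <- unname(as.numeric(values))
  if (length(years) != length(values)) {
    stop("`years` and `values` must have the same length", call. = FALSE)
  }
  if (length(years) == 0) stop("empty series", call. = FALSE)
  if (anyNA(years) || anyNA(values) || any(!is.finite(values))) {
    stop("years and values must be finite and non-missing", call. = FALSE)
  }
  if (length(years) > 1) {
    d <- diff(years)
    if (any(d != 1L)) {
      gap <- years[which(d != 1L)[1]]
      stop(sprintf(
        "years must be contiguous annual steps; gap after year %d in %s/%s/%s",
        gap, dataset, region, kind
      ), call. = FALSE)
    }
  }
  if (kind == "F" && any(values < 0)) {
    stop("fossil emissions (kind F) must be non-negative", call. = FALSE)
  }
  structure(
    list(
      dataset_id = as.character(dataset),
      region = as.character(region),
      kind = kind,
      years = years,
      values = values,
      sign_convention = unname(flux_kinds[kind])
    ),
    class = "flux_series"
  )
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf(
    "<flux_series> %s | %s | kind %s (%s)\n  %d years: %d-%d, mean %.3f Pg C yr-1\n",
    x$dataset_id, x$region, x$kind, x$sign_convention,
    length(x$years), min(x$years), max(x$years), mean(x$values)
  ))
  invisible(x)
}

#' @export
as.data.frame.flux_series <- function(x, ...) {
  data.frame(
    dataset = x$dataset_id, region = x$region, year = x$years,
    kind = x$kind, value = x$values, stringsAsFactors = FALSE
  )
}

#' @export
length.flux_series <- function(x) length(x$years)

# error unless two series share an identical year axis
check_aligned <- function(a, b, what = "series") {
  if (!identical(a$years, b$years)) {
    stop(sprintf(
      "misaligned year axes between %s (%d-%d) and %s (%d-%d); pre-trim to a common span",
      what, min(a$years), max(a$years), b$kind, min(b$years), max(b$years)
    ), call. = FALSE)
  }
  invisible(TRUE)
}

check_kind <- function(s, kind) {
  if (!inherits(s, "flux_series")) {
    stop("expected a flux_series", call. = FALSE)
  }
  if (s$kind != kind) {
    stop(sprintf("expected a series of kind %s, got %s", kind, s$kind),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Natural land sink from net land sink and land-use emissions
#'
#' The net land sink constrained by atmospheric inversions is BL = B - L,
#' so the natural sink is recovered as B = BL + L.
#'
#' @param bl net land sink series (kind `"BL"`, uptake-positive).
#' @param l land-use change emission series (kind `"L"`, emission-positive).
#' @return a `flux_series` of kind `"B"`.
#' @export
b_from_bl <- function(bl, l) {
  check_kind(bl, "BL"); check_kind(l, "L")
  check_aligned(bl, l, "BL")
  flux_series(bl$values + l$values, bl$years, "B",
              region = bl$region, dataset = bl$dataset_id)
}

#' Net land sink from natural sink and land-use emissions
#'
#' Inverse of [b_from_bl()]: BL = B - L.
#'
#' @param b natural land sink series (kind `"B"`).
#' @param l land-use change emission series (kind `"L"`).
#' @return a `flux_series` of kind `"BL"`.
#' @export
bl_from_b <- function(b, l) {
  check_kind(b, "B"); check_kind(l, "L")
  check_aligned(b, l, "B")
  flux_series(b$values - l$values, b$years, "BL",
              region = b$region, dataset = b$dataset_id)
}

#' Adjust an inversion's net land sink to a common fossil prior
#'
#' Atmospheric inversions fix a fossil-fuel prior F and adjust land fluxes,
#' so the atmosphere effectively constrains F - BL. Replacing the product's
#' prior with a common F therefore shifts BL by the prior difference:
#' `BL_adj = BL + (F_common - F_prior)`. The constraint is conserved
#' exactly: `F_common - BL_adj == F_prior - BL`.
#'
#' @param bl net land sink series (kind `"BL"`) from the inversion.
#' @param f_prior the inversion's own fossil prior (kind `"F"`).
#' @param f_common the common fossil series to harmonize to (kind `"F"`).
#' @return adjusted `flux_series` of kind `"BL"`.
#' @export
adjust_fossil_prior <- function(bl, f_prior, f_common) {
  check_kind(bl, "BL"); check_kind(f_prior, "F"); check_kind(f_common, "F")
  check_aligned(bl, f_prior, "BL")
  check_aligned(bl, f_common, "BL")
  flux_series(bl$values + (f_common$values - f_prior$values), bl$years, "BL",
              region = bl$region, dataset = bl$dataset_id)
}
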