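# Gridded annual fluxes and their aggregation onto panel regions.
# The container is built from plain arrays (cells x years); any gridded
# product can be flattened into it.

#' Construct a gridded annual flux field
#'
#' @param values matrix of cell values, `n_cells x n_years`. Units per
#'   `units`: flux density in kg C m^-2 yr^-1, or a per-cell total in
#'   Pg C yr^-1.
#' @param years integer years (columns of `values`).
#' @param areas cell areas in m^2, length `n_cells`, all positive.
#' @param mask integer region id per cell; `0` marks unassigned cells.
#' @param region_labels character labels for region ids `1..max(mask)`.
#' @param units `"kgC_m2_yr"` (density) or `"PgC_cell"` (per-cell total).
#' @return an object of class `gridded_flux`.
#' @export
gridded_flux <- function(values, years, areas, mask, region_labels,
                         units = c("kgC_m2_yr", "PgC_cell")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  years <- as.integer(years)
  stopifnot(ncol(values) == length(years),
            nrow(values) == length(areas),
            nrow(values) == length(mask))
  if (any(areas <= 0)) stop("cell areas must be positive", call. = FALSE)
  mask <- as.integer(mask)
  if (any(mask < 0) || any(mask > length(region_labels))) {
    stop("mask ids must be 0 (unassigned) or map onto region_labels",
         call. = FALSE)
  }
  structure(
    list(values = values, years = years, areas = as.numeric(areas),
         mask = mask, region_labels = as.character(region_labels),
         units = units),
    class = "gridded_flux"
  )
}

#' Aggregate a gridded flux to a regional panel
#'
#' Converts each cell to Pg C yr^-1 (density times area, 1 kg = 1e-12 Pg)
#' and sums cells by region. Unmasked cells carrying nonzero flux raise a
#' warning and are assigned to the remainder region, so the regional sum
#' always equals the global grid integral.
#'
#' @param g a [gridded_flux()].
#' @param kind flux kind for the resulting series.
#' @param dataset dataset id for the resulting panel.
#' @param remainder region receiving unmasked nonzero cells (default: the
#'   last region label).
#' @return a [flux_panel()] with one series per region.
#' @export
aggregate_grid <- function(g, kind = "BL", dataset = "gridded",
                           remainder = NULL) {
  stopifnot(inherits(g, "gridded_flux"))
  remainder <- remainder %||% g$region_labels[length(g$region_labels)]
  if (!remainder %in% g$region_labels) {
    stop("remainder region not in region_labels", call. = FALSE)
  }
  pg <- if (g$units == "kgC_m2_yr") g$values * g$areas * 1e-12 else g$values
  mask <- g$mask
  orphan <- mask == 0L & rowSums(abs(pg)) > 0
  if (any(orphan)) {
    warning(sprintf(
      "%d unmasked nonzero cell(s) assigned to remainder region '%s'",
      sum(orphan), remainder))
    mask[orphan] <- match(remainder, g$region_labels)
  }
  series <- lapply(seq_along(g$region_labels), function(i) {
    sel <- mask == i
    tot <- if (any(sel)) colSums(pg[sel, , drop = FALSE]) else numeric(ncol(pg))
    flux_series(tot, g$years, kind, region = g$region_labels[i],
                dataset = dataset)
  })
  flux_panel(series, regions = g$region_labels)
}
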