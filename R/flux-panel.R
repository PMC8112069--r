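# Regional flux panel: aligned collection of flux series over a common
# year axis and region set, with GLOBAL always derived as the sum of
# regions (never stored, so aggregates cannot go stale).

#' Default region set
#'
#' Ten named continental-scale regions plus a configurable remainder
#' region (default label `"Rest"`).
#'
#' @param rest label for the remainder region.
#' @return character vector of 11 region labels.
#' @export
default_regions <- function(rest = "Rest") {
  c("Latin America", "East Asia", "North America", "Europe", "Africa",
    "Former Soviet Union", "Middle East", "Oceania", "Southeast Asia",
    "South Asia", rest)
}

#' Construct a regional flux panel from flux series
#'
#' Kinds supplied per region are stored as region x year matrices; kinds
#' supplied only as `"GLOBAL"` (e.g. ocean sink, atmospheric growth) are
#' kept as global series. If a kind is supplied both per region and as
#' GLOBAL, the GLOBAL series must equal the regional sum within `tol` and
#' is then discarded (it is always re-derived on demand).
#'
#' @param series list of [flux_series()] objects with a common dataset id
#'   and identical year axes.
#' @param regions optional region ordering; defaults to the regions present.
#' @param tol tolerance (Pg C yr^-1) for the GLOBAL-equals-sum check.
#' @return an object of class `flux_panel`.
#' @export
flux_panel <- function(series, regions = NULL, tol = 1e-9) {
  stopifnot(length(series) >= 1)
  if (!all(vapply(series, inherits, TRUE, "flux_series"))) {
    stop("`series` must be a list of flux_series objects", call. = FALSE)
  }
  ds <- unique(vapply(series, `[[`, "", "dataset_id"))
  if (length(ds) != 1) {
    stop("all series in a panel must share one dataset id; got: ",
         paste(ds, collapse = ", "), call. = FALSE)
  }
  years <- series[[1]]$years
  for (s in series) {
    if (!identical(s$years, years)) {
      stop(sprintf("series %s/%s is not on the panel year axis %d-%d",
                   s$region, s$kind, min(years), max(years)), call. = FALSE)
    }
  }
  reg_present <- unique(vapply(series, `[[`, "", "region"))
  reg_present <- setdiff(reg_present, "GLOBAL")
  if (is.null(regions)) regions <- reg_present
  if (length(setdiff(reg_present, regions))) {
    stop("series regions not in `regions`: ",
         paste(setdiff(reg_present, regions), collapse = ", "), call. = FALSE)
  }
  regions <- as.character(regions)

  kinds <- unique(vapply(series, `[[`, "", "kind"))
  flux <- list()
  global_only <- list()
  for (k in kinds) {
    sk <- Filter(function(s) s$kind == k, series)
    reg_k <- vapply(sk, `[[`, "", "region")
    if (anyDuplicated(reg_k)) {
      stop(sprintf("duplicate series for kind %s, region %s", k,
                   reg_k[duplicated(reg_k)][1]), call. = FALSE)
    }
    has_regional <- any(reg_k != "GLOBAL")
    if (has_regional) {
      m <- matrix(NA_real_, length(regions), length(years),
                  dimnames = list(regions, years))
      for (s in sk) if (s$region != "GLOBAL") m[s$region, ] <- s$values
      if (anyNA(m)) {
        miss <- regions[apply(is.na(m), 1, any)]
        stop(sprintf("kind %s missing for region(s): %s", k,
                     paste(miss, collapse = ", ")), call. = FALSE)
      }
      g <- Filter(function(s) s$region == "GLOBAL", sk)
      if (length(g)) {
        if (max(abs(colSums(m) - g[[1]]$values)) > tol) {
          stop(sprintf(
            "GLOBAL %s series does not equal the sum over regions (tol %g)",
            k, tol), call. = FALSE)
        }
      }
      flux[[k]] <- m
    } else {
      global_only[[k]] <- sk[[1]]$values
    }
  }
  structure(
    list(dataset_id = ds, regions = regions, years = years,
         flux = flux, global_only = global_only),
    class = "flux_panel"
  )
}

#' @export
print.flux_panel <- function(x, ...) {
  cat(sprintf(
    "<flux_panel> %s: %d regions, years %d-%d\n  regional kinds: %s\n  global-only kinds: %s\n",
    x$dataset_id, length(x$regions), min(x$years), max(x$years),
    paste(names(x$flux), collapse = ", "),
    if (length(x$global_only)) paste(names(x$global_only), collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Extract one series from a panel
#'
#' @param panel a `flux_panel`.
#' @param kind flux kind.
#' @param region region label, or `"GLOBAL"` for the regional sum.
#' @return a [flux_series()].
#' @export
panel_series <- function(panel, kind, region = "GLOBAL") {
  stopifnot(inherits(panel, "flux_panel"))
  if (region == "GLOBAL") return(panel_global(panel, kind))
  if (!kind %in% names(panel$flux)) {
    stop(sprintf("kind %s not present per-region in panel", kind), call. = FALSE)
  }
  if (!region %in% panel$regions) {
    stop(sprintf("unknown region: %s", region), call. = FALSE)
  }
  flux_series(panel$flux[[kind]][region, ], panel$years, kind,
              region = region, dataset = panel$dataset_id)
}

#' Global series of a panel (sum over regions)
#'
#' For kinds stored per region the GLOBAL series is always recomputed as
#' the column sum over the panel's current regions.
#'
#' @inheritParams panel_series
#' @export
panel_global <- function(panel, kind) {
  stopifnot(inherits(panel, "flux_panel"))
  if (kind %in% names(panel$flux)) {
    v <- colSums(panel$flux[[kind]])
  } else if (kind %in% names(panel$global_only)) {
    v <- panel$global_only[[kind]]
  } else {
    stop(sprintf("kind %s not present in panel", kind), call. = FALSE)
  }
  flux_series(v, panel$years, kind, region = "GLOBAL",
              dataset = panel$dataset_id)
}

#' Remove regions from a panel
#'
#' Used by the leave-one-out / leave-two-out attribution: the returned
#' panel contains only the retained regions, and its GLOBAL series are
#' re-derived as sums over those regions. Global-only budget terms (ocean
#' sink, atmospheric growth) are kept unchanged.
#'
#' @param panel a `flux_panel`.
#' @param drop character vector of regions to remove (may be empty).
#' @return a `flux_panel` over the remaining regions.
#' @export
remove_regions <- function(panel, drop) {
  stopifnot(inherits(panel, "flux_panel"))
  drop <- as.character(drop)
  if (length(drop) == 0) return(panel)
  bad <- setdiff(drop, panel$regions)
  if (length(bad)) {
    stop("cannot drop unknown region(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keep <- setdiff(panel$regions, drop)
  if (length(keep) == 0) stop("cannot drop all regions", call. = FALSE)
  panel$regions <- keep
  panel$flux <- lapply(panel$flux, function(m) m[keep, , drop = FALSE])
  panel
}

#' Read a tidy flux CSV into panel(s)
#'
#' Expects columns `dataset,region,year,kind,value` (header required).
#' Rows with region `"GLOBAL"` for a kind that also has regional rows are
#' validated against the regional sum and then dropped (GLOBAL is derived).
#'
#' @param path CSV file path.
#' @param regions optional region ordering passed to [flux_panel()].
#' @return a `flux_panel`, or a named list of panels if the file holds
#'   several dataset ids.
#' @export
read_flux_table <- function(path, regions = NULL) {
  # read as character first: type sniffing would turn kind "F" into a
  # logical and mangle full-precision values
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("dataset", "region", "year", "kind", "value")
  if (!all(need %in% names(df))) {
    stop("flux CSV must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df$year <- as.integer(df$year)
  df$value <- as.numeric(df$value)
  bad <- setdiff(unique(df$kind), names(flux_kinds))
  if (length(bad)) {
    stop("unknown flux kind label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  one <- function(d) {
    # keep regions in file-appearance order (split() would sort them)
    key <- paste(d$region, d$kind, sep = "\r")
    key <- factor(key, levels = unique(key))
    series <- lapply(split(d, key), function(g) {
      g <- g[order(g$year), ]
      flux_series(g$value, g$year, g$kind[1], region = g$region[1],
                  dataset = g$dataset[1])
    })
    flux_panel(unname(series), regions = regions)
  }
  datasets <- unique(df$dataset)
  if (length(datasets) == 1) return(one(df))
  out <- lapply(split(df, df$dataset), one)
  out[datasets]
}

#' Write a panel to a tidy flux CSV
#'
#' @param panel a `flux_panel`.
#' @param path output CSV path.
#' @param include_global also write derived GLOBAL rows for regional kinds.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(panel, path, include_global = FALSE) {
  stopifnot(inherits(panel, "flux_panel"))
  rows <- list()
  for (k in names(panel$flux)) {
    m <- panel$flux[[k]]
    rows[[k]] <- data.frame(
      dataset = panel$dataset_id,
      region = rep(rownames(m), each = ncol(m)),
      year = rep(panel$years, times = nrow(m)),
      kind = k,
      value = as.vector(t(m)),
      stringsAsFactors = FALSE
    )
    if (include_global) {
      rows[[paste0(k, ".g")]] <- as.data.frame(panel_global(panel, k))
    }
  }
  for (k in names(panel$global_only)) {
    rows[[paste0(k, ".go")]] <- as.data.frame(panel_global(panel, k))
  }
  df <- do.call(rbind, rows)
  # %.17g keeps doubles bit-exact across a write/read round trip
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
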