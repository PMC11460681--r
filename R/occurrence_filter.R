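#' Clean occurrence records with the standard rule cascade
#'
#' A record survives iff it passes every rule. Rules are applied in a fixed
#' order and each rejection is charged to the first rule that fails, so the
#' per-rule tally is reproducible; the survivor set itself is independent of
#' both record order and rule order.
#'
#' Rules, in application order:
#' \enumerate{
#'   \item `malformed`: missing or out-of-range coordinates.
#'   \item `out_of_period`: event date outside `study_period`.
#'   \item `basis_of_record`: fossil or unknown basis of record.
#'   \item `coordinate_uncertainty`: kept iff uncertainty < 1000 m, or
#'     uncertainty is missing and both coordinates are reported with at
#'     least two decimal places.
#'   \item `not_on_land`: cell is water or outside the grid extent.
#'   \item `missing_covariates`: any covariate is missing at the cell.
#'   \item `zero_season_length`: activity-season length is 0 at the cell
#'     (skipped when `season_length` is `NULL`, i.e. year-round species).
#' }
#'
#' @param records data.frame of occurrence records (see
#'   [sample_occurrences] for the schema; `coord_decimals` is the reported
#'   decimal places of the source coordinates, which cannot be recovered
#'   from parsed floats).
#' @param world a `synthetic_world` providing covariates and the land mask.
#' @param season_length optional numeric vector of season length (days) per
#'   cell id, or `NULL` for year-round species.
#' @param study_period length-2 Date vector (inclusive).
#' @param max_uncertainty_m uncertainty threshold in meters (strict `<`).
#' @param min_decimals minimum reported decimal places when uncertainty is
#'   missing.
#' @return list with `records` (survivors, with `cell_id` attached) and
#'   `tally` (named integer vector of rejections per rule, plus `survived`).
#' @export
filter_records <- function(records, world, season_length = NULL,
                           study_period = as.Date(c("2000-01-01",
                                                    "2019-12-31")),
                           max_uncertainty_m = 1000,
                           min_decimals = 2L) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no occurrence records supplied")
  }
  g <- world$grids[[1]]
  n <- nrow(records)
  rules <- c("malformed", "out_of_period", "basis_of_record",
             "coordinate_uncertainty", "not_on_land", "missing_covariates",
             "zero_season_length")
  reject <- rep(NA_character_, n)

  lon <- suppressWarnings(as.numeric(records$lon))
  lat <- suppressWarnings(as.numeric(records$lat))
  bad <- is.na(lon) | is.na(lat) | abs(lat) > 90 | abs(lon) > 180
  reject[bad] <- "malformed"

  dt <- suppressWarnings(as.Date(records$date))
  bad <- is.na(reject) & (is.na(dt) | dt < study_period[1] | dt > study_period[2])
  reject[bad] <- "out_of_period"

  basis <- toupper(trimws(as.character(records$basis_of_record)))
  bad <- is.na(reject) &
    (is.na(basis) | basis %in% c("FOSSIL_SPECIMEN", "FOSSIL", "UNKNOWN", ""))
  reject[bad] <- "basis_of_record"

  unc <- records$coord_uncertainty_m
  dec <- records$coord_decimals
  unc_ok <- (!is.na(unc) & unc < max_uncertainty_m) |
    (is.na(unc) & !is.na(dec) & dec >= min_decimals)
  bad <- is.na(reject) & !unc_ok
  reject[bad] <- "coordinate_uncertainty"

  cell <- cell_from_lonlat(g, lon, lat)
  on_land <- !is.na(cell)
  ij <- cell_ij(g, ifelse(is.na(cell), 1L, cell))
  on_land[on_land] <- world$land[ij[on_land, , drop = FALSE]]
  bad <- is.na(reject) & !on_land
  reject[bad] <- "not_on_land"

  cov_ok <- rep(TRUE, n)
  for (nm in names(world$grids)) {
    cov_ok <- cov_ok & !is.na(cell_value(world$grids[[nm]], cell))
  }
  bad <- is.na(reject) & !cov_ok
  reject[bad] <- "missing_covariates"

  if (!is.null(season_length)) {
    sl <- rep(NA_real_, n)
    ok <- !is.na(cell)
    sl[ok] <- season_length[cell[ok]]
    bad <- is.na(reject) & (is.na(sl) | sl <= 0)
    reject[bad] <- "zero_season_length"
  }

  tally <- vapply(rules, function(r) sum(reject == r, na.rm = TRUE), 0L)
  survivors <- records[is.na(reject), , drop = FALSE]
  survivors$cell_id <- cell[is.na(reject)]
  stopifnot(sum(tally) + nrow(survivors) == n)  # conservation
  list(records = survivors,
       tally = c(tally, survived = nrow(survivors)))
}

#' Spatially thin records to unique cell centroids
#'
#' Collapses filtered occurrence records to one representative per occupied
#' grid cell, positioned at the cell centroid. Idempotent: thinning an
#' already-thinned set returns it unchanged.
#'
#' @param records filtered records carrying a `cell_id` column (or raw
#'   records, in which case cells are computed from coordinates).
#' @param grid the shared [raster_grid] geometry.
#' @return data.frame of class `cell_centroids`: `cell_id`, `lon`, `lat`,
#'   `label` (1 for presence), sorted by cell id.
#' @export
thin_to_centroids <- function(records, grid) {
  cell <- records$cell_id %||% cell_from_lonlat(grid, records$lon, records$lat)
  ids <- sort(unique(cell[!is.na(cell)]))
  out <- cell_centroid(grid, ids)
  out$label <- rep(1L, nrow(out))
  class(out) <- c("cell_centroids", "data.frame")
  out
}

#' Attach covariate values to cell centroids
#'
#' Reads one value per covariate from each centroid's containing cell.
#' Centroids whose cell has any missing covariate are dropped (with a
#' count); a centroid outside the grid extent is an error naming the point.
#'
#' @param centroids a `cell_centroids` data.frame.
#' @param world a `synthetic_world` (covariate stack).
#' @return list with `centroids` (input rows plus one column per covariate)
#'   and `n_dropped_missing`.
#' @export
attach_covariates <- function(centroids, world) {
  g <- world$grids[[1]]
  cell <- centroids$cell_id %||% cell_from_lonlat(g, centroids$lon, centroids$lat)
  if (anyNA(cell)) {
    i <- which(is.na(cell))[1]
    stop(sprintf("centroid outside grid extent: (%g, %g)",
                 centroids$lon[i], centroids$lat[i]))
  }
  out <- centroids
  out$cell_id <- cell
  for (nm in names(world$grids)) {
    out[[nm]] <- cell_value(world$grids[[nm]], cell)
  }
  keep <- stats::complete.cases(out[names(world$grids)])
  list(centroids = out[keep, , drop = FALSE],
       n_dropped_missing = sum(!keep))
}
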