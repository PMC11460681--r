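#' Accessible area from buffered occurrences and ecoregion adjacency
#'
#' Selects every ecoregion that intersects any occurrence centroid buffered
#' by `buffer_km` (equirectangular km distance evaluated at the occurrence's
#' latitude), plus every ecoregion rook-adjacent to a selected one. The
#' eligible cell set is all land cells whose centroid falls in a selected
#' ecoregion.
#'
#' @param centroids presence `cell_centroids` (one row per occupied cell).
#' @param ecoregions an `ecoregion_set` (see [generate_ecoregions]).
#' @param world the `synthetic_world` providing the land mask.
#' @param buffer_km buffer radius in km (default 200, an upper bound on
#'   wind-assisted mosquito dispersal).
#' @return list of class `accessible_area`: `eco_ids` (selected regions),
#'   `core_eco_ids` (selected before adjacency expansion), `eligible_cells`
#'   (integer cell ids), `buffer_km`.
#' @export
accessible_area <- function(centroids, ecoregions, world, buffer_km = 200) {
  stopifnot(nrow(centroids) >= 1)
  g <- ecoregions$grid
  occ_eco <- ecoregion_at(ecoregions, centroids$cell_id)
  if (all(is.na(occ_eco))) {
    stop("no occurrence centroid intersects any ecoregion")
  }
  # ecoregions intersecting the buffered centroids: any cell centroid of the
  # region within buffer_km of any occurrence centroid
  all_ids <- seq_len(n_cells(g))
  cen <- cell_centroid(g, all_ids)
  eco_of_cell <- ecoregion_at(ecoregions, all_ids)
  hit <- rep(FALSE, length(all_ids))
  for (k in seq_len(nrow(centroids))) {
    d <- equirect_dist_km(centroids$lon[k], centroids$lat[k],
                          cen$lon, cen$lat, ref_lat = centroids$lat[k])
    hit <- hit | d <= buffer_km
  }
  core <- sort(unique(eco_of_cell[hit]))
  core <- union(core, occ_eco[!is.na(occ_eco)])
  expanded <- sort(unique(c(core, unlist(ecoregions$adjacency[as.character(core)]))))
  ij <- cell_ij(g, all_ids)
  eligible <- all_ids[world$land[ij] & eco_of_cell %in% expanded]
  structure(list(eco_ids = expanded, core_eco_ids = sort(core),
                 eligible_cells = eligible, buffer_km = buffer_km),
            class = "accessible_area")
}

#' @export
print.accessible_area <- function(x, ...) {
  cat(sprintf("<accessible_area> %d ecoregions (%d core), %d eligible cells, buffer %g km\n",
              length(x$eco_ids), length(x$core_eco_ids),
              length(x$eligible_cells), x$buffer_km))
  invisible(x)
}

#' Build the pseudo-absence bias mask from effort tallies
#'
#' Restricts per-cell sampling-effort tallies to the eligible cells of the
#' accessible area and renormalizes them into proportions. If every eligible
#' cell has a zero tally, falls back to uniform weights (documented
#' fallback: with no effort information, every eligible cell is equally
#' plausible).
#'
#' @param tallies data.frame `cell_id`, `tally` (nonnegative counts).
#' @param area an `accessible_area`.
#' @return `bias_mask` data.frame `cell_id`, `weight` over eligible cells,
#'   weights summing to 1.
#' @export
build_bias_mask <- function(tallies, area) {
  if (any(tallies$tally < 0)) stop("effort tallies must be nonnegative")
  t_map <- structure(tallies$tally, names = as.character(tallies$cell_id))
  w <- t_map[as.character(area$eligible_cells)]
  w[is.na(w)] <- 0
  if (sum(w) == 0) {
    w <- rep(1, length(area$eligible_cells))
  }
  out <- data.frame(cell_id = area$eligible_cells, weight = w / sum(w))
  rownames(out) <- NULL
  class(out) <- c("bias_mask", "data.frame")
  out
}

#' Draw bias-weighted background (pseudo-absence) centroids
#'
#' Samples `2 * n_occurrence_centroids` distinct cells from the accessible
#' area, excluding occurrence cells, without replacement with per-draw
#' probabilities proportional to the remaining bias weights (implemented by
#' Efraimidis-Spirakis exponential keys, distributionally identical to
#' sequential draw-and-renormalize).
#'
#' @param area an `accessible_area`.
#' @param bias a `bias_mask` over the area's eligible cells.
#' @param occurrence_cells integer cell ids of presence centroids (excluded
#'   from sampling).
#' @param n_occurrence_centroids presence centroid count; `2 *` this many
#'   background cells are drawn.
#' @param seed RNG seed.
#' @param ratio background:presence ratio (default 2).
#' @param grid the shared [raster_grid], for centroid coordinates.
#' @return `cell_centroids` data.frame with `label = 0`.
#' @export
sample_background <- function(area, bias, occurrence_cells,
                              n_occurrence_centroids = length(occurrence_cells),
                              seed = 1L, ratio = 2, grid) {
  m <- ratio * n_occurrence_centroids
  cand <- bias[!(bias$cell_id %in% occurrence_cells) & bias$weight > 0, ]
  if (nrow(cand) < m) {
    stop(sprintf(paste0("insufficient eligible background cells: need %d, ",
                        "have %d positive-weight cells (deficit %d)"),
                 m, nrow(cand), m - nrow(cand)))
  }
  with_seed(seed, {
    # Efraimidis-Spirakis: order by Exp(w) keys; top-m = weighted WOR
    keys <- stats::rexp(nrow(cand)) / cand$weight
    picked <- cand$cell_id[order(keys)[seq_len(m)]]
  })
  out <- cell_centroid(grid, sort(picked))
  out$label <- 0L
  class(out) <- c("cell_centroids", "data.frame")
  out
}

#' Check background thermal breadth against occurrences
#'
#' Passes iff the background temperature range covers the occurrence range
#' on both tails (boundary inclusive); otherwise warns, naming the failing
#' tail(s). Never a hard failure: a narrow background limits what the model
#' can learn about thermal limits but does not invalidate the fit.
#'
#' @param occ_temps,bg_temps numeric temperature vectors (nonempty).
#' @return list `pass` (logical), `failing_tails` (character),
#'   `occ_range`, `bg_range`.
#' @export
thermal_breadth_check <- function(occ_temps, bg_temps) {
  stopifnot(length(occ_temps) > 0, length(bg_temps) > 0)
  occ_r <- range(occ_temps, na.rm = TRUE)
  bg_r <- range(bg_temps, na.rm = TRUE)
  tails <- character(0)
  if (bg_r[1] > occ_r[1]) tails <- c(tails, "lower")
  if (bg_r[2] < occ_r[2]) tails <- c(tails, "upper")
  pass <- length(tails) == 0
  if (!pass) {
    warning("background temperature range narrower than occurrences at the ",
            paste(tails, collapse = " and "), " tail",
            if (length(tails) > 1) "s" else "")
  }
  list(pass = pass, failing_tails = tails, occ_range = occ_r, bg_range = bg_r)
}
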