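# Plain-text serialization of the pipeline's objects. Grids travel as
# long-format CSV (one row per cell), ecoregions as CSV assignment plus an
# optional GeoJSON FeatureCollection of cell-box MultiPolygons; occurrence
# and trait-draw CSV schemas match what the simulators produce.

#' Write occurrence records to CSV
#'
#' Canonical schema:
#' `species,lon,lat,date,coord_uncertainty_m,basis_of_record,coord_decimals`.
#'
#' @param records occurrence data.frame.
#' @param path output file.
#' @export
write_occurrences_csv <- function(records, path) {
  cols <- c("species", "lon", "lat", "date", "coord_uncertainty_m",
            "basis_of_record", "coord_decimals")
  utils::write.csv(records[cols], path, row.names = FALSE, na = "")
}

#' Read occurrence records from CSV
#'
#' Lines starting with `#` are treated as documentation comments.
#'
#' @param path input file.
#' @return occurrence data.frame with typed columns.
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$coord_uncertainty_m <- suppressWarnings(as.numeric(df$coord_uncertainty_m))
  df$coord_decimals <- suppressWarnings(as.integer(df$coord_decimals))
  df
}

#' Write a world's covariate stack to long-format CSV
#'
#' One row per cell: `cell_id,lon,lat,land,<covariates...>`.
#'
#' @param world a `synthetic_world`.
#' @param path output file.
#' @export
write_world_csv <- function(world, path) {
  utils::write.csv(world_cells(world), path, row.names = FALSE)
}

#' Write trait posterior draws to long-format CSV
#'
#' Schema: `trait,draw,param,value`.
#'
#' @param posterior a `trait_posterior`.
#' @param path output file.
#' @export
write_trait_draws_csv <- function(posterior, path) {
  rows <- lapply(names(posterior$draws), function(tr) {
    df <- posterior$draws[[tr]]
    do.call(rbind, lapply(names(df), function(p) {
      data.frame(trait = tr, draw = seq_len(nrow(df)), param = p,
                 value = df[[p]])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Write ecoregions as a GeoJSON FeatureCollection
#'
#' One feature per ecoregion with integer property `eco_id` and a
#' MultiPolygon geometry made of the region's cell boxes. Written by hand
#' through jsonlite (no geometry engine involved); intended for
#' interchange and plotting, not precise topology.
#'
#' @param ecoregions an `ecoregion_set`.
#' @param path output file.
#' @export
write_ecoregions_geojson <- function(ecoregions, path) {
  g <- ecoregions$grid
  ids <- sort(unique(as.vector(ecoregions$assignment)))
  features <- lapply(ids, function(k) {
    cells <- which(ecoregions$assignment == k, arr.ind = TRUE)
    polys <- lapply(seq_len(nrow(cells)), function(r) {
      i <- cells[r, 1]; j <- cells[r, 2]
      x0 <- g$origin[1] + (j - 1) * g$cell_size
      y0 <- g$origin[2] + (i - 1) * g$cell_size
      x1 <- x0 + g$cell_size; y1 <- y0 + g$cell_size
      list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
    })
    list(type = "Feature",
         properties = list(eco_id = k),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
}

#' Write a study report to JSON
#'
#' Serializes per-species field/lab extrema and the cross-species
#' correlations.
#'
#' @param report a `study_report` from [run_study].
#' @param path output file.
#' @export
write_study_json <- function(report, path) {
  species <- lapply(seq_len(nrow(report$pairs)), function(k) {
    sp <- report$pairs$species[k]
    fx <- report$field[[sp]]$extrema
    lx <- report$lab[[sp]]$extrema
    list(
      field = list(tmin = fx$tmin[c("median", "min", "max")],
                   topt = fx$topt[c("median", "min", "max")]),
      lab = list(tmin = lx$tmin, topt = lx$topt)
    )
  })
  names(species) <- report$pairs$species
  out <- list(species = species,
              correlations = list(tmin = report$comparison$r_tmin,
                                  topt = report$comparison$r_topt))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
}
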