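#' Configuration for a synthetic study world
#'
#' Bundles everything needed to generate a self-contained world with a known
#' ground-truth thermal response: grid geometry, the true thermal limits, the
#' number of occurrence reports, the spatial unevenness of sampling effort,
#' and covariate noise. The defaults are the package's reference study
#' conditions for parameter-recovery experiments.
#'
#' @param seed integer RNG seed; the world is a pure function of the config.
#' @param extent named numeric: `lon_min`, `lon_max`, `lat_min`, `lat_max`
#'   (degrees).
#' @param cell_size cell edge in degrees.
#' @param n_ecoregions number of ecoregions to tessellate the extent into.
#' @param true_thermal a [true_suitability_params] object (the ground truth).
#' @param n_occurrences number of occurrence reports to simulate.
#' @param bias_concentration positive real; larger values concentrate
#'   sampling effort into fewer places.
#' @param covariate_noise_sd standard deviation of the smooth noise added to
#'   the temperature field (degrees C).
#' @param violation_fraction fraction of occurrence records injected with a
#'   labeled filter violation (see [sample_occurrences]).
#' @return list of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(seed = 1L,
                                   extent = c(lon_min = 0, lon_max = 3,
                                              lat_min = 0, lat_max = 3),
                                   cell_size = 0.05,
                                   n_ecoregions = 6L,
                                   true_thermal = true_suitability_params(),
                                   n_occurrences = 1000L,
                                   bias_concentration = 1,
                                   covariate_noise_sd = 0.4,
                                   violation_fraction = 0.05) {
  stopifnot(cell_size > 0, n_occurrences >= 1, bias_concentration > 0,
            extent["lon_max"] > extent["lon_min"],
            extent["lat_max"] > extent["lat_min"],
            violation_fraction >= 0, violation_fraction < 1)
  structure(list(seed = as.integer(seed), extent = extent,
                 cell_size = cell_size, n_ecoregions = as.integer(n_ecoregions),
                 true_thermal = true_thermal,
                 n_occurrences = as.integer(n_occurrences),
                 bias_concentration = bias_concentration,
                 covariate_noise_sd = covariate_noise_sd,
                 violation_fraction = violation_fraction),
            class = "synthetic_world_config")
}

#' Ground-truth thermal suitability parameters
#'
#' The true occurrence-probability response to temperature used by the
#' synthetic world: zero at and below `tmin`, zero at and above `tmax`,
#' maximal (`peak_prob`) exactly at `topt`.
#'
#' @param tmin,topt,tmax critical temperatures in degrees C,
#'   `tmin < topt < tmax`.
#' @param peak_prob peak occurrence probability in (0, 1].
#' @return list of class `true_suitability_params`.
#' @export
true_suitability_params <- function(tmin = 12, topt = 27, tmax = 36,
                                    peak_prob = 0.9) {
  stopifnot(tmin > 0, tmin < topt, topt < tmax, peak_prob > 0, peak_prob <= 1)
  structure(list(tmin = tmin, topt = topt, tmax = tmax,
                 peak_prob = peak_prob),
            class = "true_suitability_params")
}

#' True thermal suitability curve
#'
#' Generalized-Briere unimodal curve: the Briere-1 polynomial with a free
#' right-tail exponent,
#' `s(T) = peak_prob * g(T) / g(topt)` with
#' `g(T) = T * (T - tmin) * (tmax - T)^b` on `(tmin, tmax)` and 0 outside.
#' A plain Briere-1 curve's optimum is determined by its two zeroes, so the
#' exponent `b` is solved in closed form from the interior critical-point
#' condition `1/T + 1/(T - tmin) = b/(tmax - T)` at `T = topt`, placing the
#' maximum (value `peak_prob`) exactly at `topt`.
#'
#' @param temp temperatures in degrees C (vectorized).
#' @param params a [true_suitability_params] object.
#' @return occurrence probabilities in `[0, peak_prob]`.
#' @export
true_suitability <- function(temp, params) {
  stopifnot(inherits(params, "true_suitability_params"))
  b <- (params$tmax - params$topt) *
    (1 / params$topt + 1 / (params$topt - params$tmin))
  g <- function(t) t * (t - params$tmin) * (params$tmax - t)^b
  s <- rep(0, length(temp))
  inside <- temp > params$tmin & temp < params$tmax
  s[inside] <- params$peak_prob * g(temp[inside]) / g(params$topt)
  s
}

#' Generate the synthetic world's covariate stack
#'
#' Builds a temperature-mean grid spanning a range strictly containing the
#' true thermal limits (a smooth south-to-north gradient from
#' `tmax + 7` down to `tmin - 7`, plus smooth noise), a temperature-SD grid,
#' five auxiliary covariates (vegetation index, dry-quarter precipitation,
#' human density, wind speed, relative humidity) each built as a controlled
#' mixture of the standardized temperature field and independent smooth
#' noise so that their correlation with temperature stays below 0.8 in
#' absolute value, and a land mask carving out a small fraction of water
#' cells.
#'
#' @param config a [synthetic_world_config].
#' @return list of class `synthetic_world` with elements `grids` (named list
#'   of [raster_grid]), `land` (logical matrix), `config`, `truth`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synthetic_world_config"))
  ext <- config$extent
  n_cols <- round((ext[["lon_max"]] - ext[["lon_min"]]) / config$cell_size)
  n_rows <- round((ext[["lat_max"]] - ext[["lat_min"]]) / config$cell_size)
  if (n_rows < 8 || n_cols < 8) {
    stop("extent too small to hold the requested temperature gradient: need ",
         "at least 8 x 8 cells, got ", n_rows, " x ", n_cols)
  }
  tp <- config$true_thermal
  origin <- c(ext[["lon_min"]], ext[["lat_min"]])

  with_seed(config$seed, {
    # south (row 1) hot -> north cold; endpoints give slack beyond the truth
    t_hi <- tp$tmax + 7
    t_lo <- tp$tmin - 7
    grad <- seq(t_hi, t_lo, length.out = n_rows)
    temp <- matrix(grad, n_rows, n_cols) +
      config$covariate_noise_sd * smooth_field(n_rows, n_cols)

    temp_sd <- 4 + 1.5 * smooth_field(n_rows, n_cols)
    temp_sd <- pmax(temp_sd, 0.2)

    tz <- zstd(as.vector(temp))
    mix_cov <- function(a, lo, hi) {
      z <- a * tz + sqrt(1 - a^2) * zstd(as.vector(smooth_field(n_rows, n_cols)))
      m <- matrix(z, n_rows, n_cols)
      lo + (hi - lo) * (m - min(m)) / (max(m) - min(m))
    }
    aux <- list(
      vegetation_index   = mix_cov(0.45, 0, 1),
      precip_dry_quarter = mix_cov(-0.35, 0, 300),
      human_density      = mix_cov(0.25, 0, 500),
      wind_speed         = mix_cov(-0.15, 0, 12),
      relative_humidity  = mix_cov(0.30, 20, 95)
    )

    # water where an independent smooth field is most negative (~8% of cells)
    wf <- smooth_field(n_rows, n_cols)
    land <- wf > stats::quantile(wf, 0.08)

    grids <- c(
      list(temperature_mean = temp, temperature_sd = temp_sd),
      aux
    )
    grids <- mapply(function(v, nm) {
      v[!land] <- NA_real_
      raster_grid(nm, origin, config$cell_size, v)
    }, grids, names(grids), SIMPLIFY = FALSE)

    world <- structure(list(grids = grids, land = land, config = config,
                            truth = tp),
                       class = "synthetic_world")
    if (!check_identifiability(world)) {
      stop("generated temperature field does not span the true thermal ",
           "limits; enlarge the extent or the gradient")
    }
    world
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells (%.3g deg), %d covariates, %d land cells\n",
              x$grids[[1]]$n_rows, x$grids[[1]]$n_cols, x$grids[[1]]$cell_size,
              length(x$grids), sum(x$land)))
  invisible(x)
}

#' Check that the world makes its thermal limits identifiable
#'
#' Land-cell temperatures must extend both below the true thermal minimum
#' and above the true optimum, so the downstream extrema extraction is
#' well-posed by construction.
#'
#' @param world a `synthetic_world`.
#' @return logical.
#' @export
check_identifiability <- function(world) {
  tv <- world$grids$temperature_mean$values[world$land]
  min(tv, na.rm = TRUE) < world$truth$tmin &&
    max(tv, na.rm = TRUE) > world$truth$topt
}

#' All cells of a world as a data frame
#'
#' @param world a `synthetic_world`.
#' @param land_only keep only land cells.
#' @return data.frame with `cell_id`, `lon`, `lat`, `land`, and one column
#'   per covariate.
#' @export
world_cells <- function(world, land_only = FALSE) {
  g <- world$grids[[1]]
  ids <- seq_len(n_cells(g))
  out <- cell_centroid(g, ids)
  ij <- cell_ij(g, ids)
  out$land <- world$land[ij]
  for (nm in names(world$grids)) {
    out[[nm]] <- cell_value(world$grids[[nm]], ids)
  }
  if (land_only) out <- out[out$land, , drop = FALSE]
  out
}

#' Tessellate the world into ecoregions
#'
#' Discrete Voronoi tessellation: `n_ecoregions` seed points are placed
#' uniformly over the extent and every cell is assigned to its nearest seed
#' (equirectangular km distance at the cell's latitude). Every cell (land or
#' water) belongs to exactly one ecoregion; adjacency is derivable from the
#' cell grid (rook neighborhood).
#'
#' @param world a `synthetic_world`.
#' @param n_ecoregions number of regions, at least 2.
#' @param seed RNG seed.
#' @return list of class `ecoregion_set`: `assignment` (integer matrix of
#'   eco ids per cell), `seeds` (data.frame), `adjacency` (named list of
#'   integer vectors), `grid` (geometry donor [raster_grid]).
#' @export
generate_ecoregions <- function(world, n_ecoregions = world$config$n_ecoregions,
                                seed = world$config$seed + 1L) {
  stopifnot(n_ecoregions >= 2)
  g <- world$grids[[1]]
  ext <- world$config$extent
  with_seed(seed, {
    seeds <- data.frame(
      eco_id = seq_len(n_ecoregions),
      lon = runif(n_ecoregions, ext[["lon_min"]], ext[["lon_max"]]),
      lat = runif(n_ecoregions, ext[["lat_min"]], ext[["lat_max"]])
    )
    cen <- cell_centroid(g, seq_len(n_cells(g)))
    d <- sapply(seq_len(n_ecoregions), function(k) {
      equirect_dist_km(cen$lon, cen$lat, seeds$lon[k], seeds$lat[k],
                       ref_lat = cen$lat)
    })
    assign_vec <- max.col(-d, ties.method = "first")
    ij <- cell_ij(g, cen$cell_id)
    assignment <- matrix(NA_integer_, g$n_rows, g$n_cols)
    assignment[ij] <- assign_vec
    structure(list(assignment = assignment, seeds = seeds,
                   adjacency = ecoregion_adjacency(assignment),
                   grid = g),
              class = "ecoregion_set")
  })
}

# Rook adjacency between ecoregions: ids whose cells share an edge.
ecoregion_adjacency <- function(assignment) {
  h <- cbind(as.vector(assignment[, -ncol(assignment)]),
             as.vector(assignment[, -1]))
  v <- cbind(as.vector(assignment[-nrow(assignment), ]),
             as.vector(assignment[-1, ]))
  pairs <- rbind(h, v)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  ids <- sort(unique(as.vector(assignment)))
  adj <- lapply(ids, function(k) {
    nb <- unique(c(pairs[pairs[, 1] == k, 2], pairs[pairs[, 2] == k, 1]))
    sort(nb)
  })
  names(adj) <- as.character(ids)
  adj
}

#' Ecoregion id at cells
#'
#' @param ecoregions an `ecoregion_set`.
#' @param cell_id integer cell ids.
#' @return integer ecoregion ids.
#' @export
ecoregion_at <- function(ecoregions, cell_id) {
  ij <- cell_ij(ecoregions$grid, cell_id)
  ecoregions$assignment[ij]
}

#' Generate a spatial sampling-effort (bias) surface
#'
#' Emulates uneven collection effort: weights proportional to
#' `exp(concentration * z)` for a standardized smooth random field `z`,
#' restricted to land cells and normalized to sum to one. As
#' `concentration -> 0` the weights approach uniform; larger values
#' concentrate effort into fewer clusters.
#'
#' @param world a `synthetic_world`.
#' @param concentration positive real.
#' @param seed RNG seed.
#' @return data.frame of class `bias_mask` with `cell_id` (land cells) and
#'   `weight` (nonnegative, summing to 1).
#' @export
generate_bias_surface <- function(world,
                                  concentration = world$config$bias_concentration,
                                  seed = world$config$seed + 2L) {
  stopifnot(concentration > 0)
  g <- world$grids[[1]]
  with_seed(seed, {
    f <- smooth_field(g$n_rows, g$n_cols)
    z <- matrix(zstd(as.vector(f)), g$n_rows, g$n_cols)
    w <- exp(concentration * z)
    ids <- seq_len(n_cells(g))
    ij <- cell_ij(g, ids)
    land <- world$land[ij]
    out <- data.frame(cell_id = ids[land], weight = w[ij][land])
    out$weight <- out$weight / sum(out$weight)
    class(out) <- c("bias_mask", "data.frame")
    out
  })
}

#' Simulate presence-only occurrence records
#'
#' Cells are drawn (with replacement, mimicking repeated reporting) with
#' probability proportional to `true_suitability(T_cell) * bias_weight`;
#' each record's coordinates are jittered uniformly within its cell and
#' carry reporting metadata (date, coordinate uncertainty, basis of record,
#' reported decimal places). A fixed fraction of records is injected with a
#' labeled violation of the cleaning rules (excess uncertainty, too few
#' coordinate decimals, fossil or unknown basis, out-of-period date) so
#' filter tests have known expected survivor counts; the `violation` column
#' names the injected defect ("" for clean records).
#'
#' @param world a `synthetic_world`.
#' @param params a [true_suitability_params]; defaults to the world's truth.
#' @param n number of records, at least 1.
#' @param bias a `bias_mask` (see [generate_bias_surface]).
#' @param seed RNG seed.
#' @param violation_fraction overrides the config's fraction if given.
#' @param species species label carried on every record.
#' @return data.frame of occurrence records with columns `species`, `lon`,
#'   `lat`, `date`, `coord_uncertainty_m`, `basis_of_record`,
#'   `coord_decimals`, `cell_id`, `violation`.
#' @export
sample_occurrences <- function(world, params = world$truth,
                               n = world$config$n_occurrences,
                               bias = generate_bias_surface(world),
                               seed = world$config$seed + 3L,
                               violation_fraction = world$config$violation_fraction,
                               species = "synthetic_species") {
  stopifnot(n >= 1)
  g <- world$grids[[1]]
  tcell <- cell_value(world$grids$temperature_mean, bias$cell_id)
  p <- true_suitability(tcell, params) * bias$weight
  if (all(p == 0)) {
    stop("all-zero sampling probability: no land cell is both suitable and ",
         "reachable by sampling effort")
  }
  p <- p / sum(p)
  with_seed(seed, {
    picked <- sample(bias$cell_id, n, replace = TRUE, prob = p)
    ij <- cell_ij(g, picked)
    lon <- g$origin[1] + (ij[, "j"] - 1 + runif(n)) * g$cell_size
    lat <- g$origin[2] + (ij[, "i"] - 1 + runif(n)) * g$cell_size
    unc <- sample(c(30, 100, 250, 500, NA), n, replace = TRUE,
                  prob = c(0.25, 0.25, 0.15, 0.1, 0.25))
    rec <- data.frame(
      species = species,
      lon = round(lon, 4), lat = round(lat, 4),
      date = as.Date("2000-01-01") +
        sample.int(as.integer(as.Date("2019-12-31") - as.Date("2000-01-01")),
                   n, replace = TRUE),
      coord_uncertainty_m = unc,
      basis_of_record = "HUMAN_OBSERVATION",
      coord_decimals = 4L,
      cell_id = picked,
      violation = "",
      stringsAsFactors = FALSE
    )
    n_bad <- round(violation_fraction * n)
    if (n_bad > 0) {
      idx <- sample.int(n, n_bad)
      kinds <- rep(c("uncertainty_1500m", "one_decimal", "fossil",
                     "unknown_basis", "out_of_period"),
                   length.out = n_bad)
      for (k in seq_len(n_bad)) {
        i <- idx[k]
        rec$violation[i] <- kinds[k]
        switch(kinds[k],
          uncertainty_1500m = { rec$coord_uncertainty_m[i] <- 1500 },
          one_decimal = {
            rec$coord_uncertainty_m[i] <- NA
            rec$coord_decimals[i] <- 1L
            rec$lon[i] <- round(rec$lon[i], 1)
            rec$lat[i] <- round(rec$lat[i], 1)
          },
          fossil = { rec$basis_of_record[i] <- "FOSSIL_SPECIMEN" },
          unknown_basis = { rec$basis_of_record[i] <- "UNKNOWN" },
          out_of_period = { rec$date[i] <- as.Date("1995-06-15") }
        )
      }
    }
    rec
  })
}

#' Simulate Insecta sampling-effort tallies
#'
#' Draws a multinomial count of "all insect" records over land cells with
#' probabilities given by the bias surface; standing in for the per-cell
#' tally of insect occurrences used to build the pseudo-absence bias mask.
#'
#' @param bias a `bias_mask`.
#' @param total total insect records to distribute.
#' @param seed RNG seed.
#' @return data.frame `cell_id`, `tally`.
#' @export
simulate_effort_tallies <- function(bias, total = 50000L, seed = 1L) {
  with_seed(seed, {
    counts <- as.vector(rmultinom(1, total, bias$weight))
    data.frame(cell_id = bias$cell_id, tally = counts)
  })
}
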