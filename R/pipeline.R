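#' Run the field (SDM) side of the study end-to-end on a synthetic world
#'
#' Orchestrates the full chain: simulate occurrence records over the
#' world's true thermal response and bias surface; clean and spatially thin
#' them to unique cell centroids; build the ecoregion-constrained
#' accessible area from 200 km-buffered centroids; restrict and renormalize
#' the sampling-effort tallies into a bias mask; draw twice as many
#' bias-weighted background centroids without replacement; screen
#' covariates; fit the gradient-boosted occurrence model over repeated
#' stratified splits with Bayesian hyperparameter tuning; and extract
#' thermal minima and optima from temperature partial-dependence curves.
#'
#' @param world a `synthetic_world`.
#' @param master_seed master RNG seed; every stochastic stage draws a
#'   derived child seed from it.
#' @param profile a `fit_profile` ([profile_desk] or [profile_paper]).
#' @param n_occurrences occurrence records to simulate (default from the
#'   world config).
#' @param exclusion optional list of bounding boxes (`lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`) whose occurrences and background candidates are
#'   dropped before fitting (regional sensitivity refits).
#' @param ecoregions,bias optionally precomputed [generate_ecoregions] /
#'   [generate_bias_surface] outputs (reused across refits).
#' @param min_occurrences fail if fewer filtered centroids remain.
#' @return list of class `field_pipeline`: `table`, `bundle`, `extrema`,
#'   `importance`, `breadth`, `screen`, `filter_tally`, `n_centroids`,
#'   `area`.
#' @export
run_field_pipeline <- function(world, master_seed = 1L,
                               profile = profile_desk(),
                               n_occurrences = world$config$n_occurrences,
                               exclusion = NULL,
                               ecoregions = NULL, bias = NULL,
                               min_occurrences = 25L) {
  seeds <- derive_seeds(master_seed, 5L)
  g <- world$grids[[1]]
  ecoregions <- ecoregions %||% generate_ecoregions(world, seed = seeds[1])
  bias <- bias %||% generate_bias_surface(world, seed = seeds[2])

  records <- sample_occurrences(world, n = n_occurrences, bias = bias,
                                seed = seeds[3])
  filt <- filter_records(records, world)
  occ <- filt$records
  if (!is.null(exclusion)) occ <- drop_in_boxes(occ, exclusion)
  centroids <- thin_to_centroids(occ, g)
  if (nrow(centroids) < min_occurrences) {
    stop("too few occurrence centroids after filtering/exclusion: ",
         nrow(centroids), " < ", min_occurrences)
  }
  occ_cov <- attach_covariates(centroids, world)$centroids

  area <- accessible_area(centroids, ecoregions, world)
  if (!is.null(exclusion)) {
    cen_all <- cell_centroid(g, area$eligible_cells)
    keep <- !in_boxes(cen_all$lon, cen_all$lat, exclusion)
    area$eligible_cells <- area$eligible_cells[keep]
  }
  tallies <- simulate_effort_tallies(bias, seed = seeds[4])
  mask <- build_bias_mask(tallies, area)
  bg <- sample_background(area, mask, occurrence_cells = centroids$cell_id,
                          seed = seeds[5], grid = g)
  bg_cov <- attach_covariates(bg, world)$centroids

  breadth <- withCallingHandlers(
    thermal_breadth_check(occ_cov$temperature_mean, bg_cov$temperature_mean),
    warning = function(w) invokeRestart("muffleWarning")
  )

  table <- rbind(occ_cov, bg_cov)
  table <- table[c("label", names(world$grids))]
  screen <- screen_covariates(table[names(world$grids)])

  bundle <- bootstrap_models(table, master_seed = master_seed,
                             profile = profile)
  extrema <- field_thermal_extrema(bundle, "temperature_mean")
  importance <- variable_importance(bundle)

  structure(list(table = table, bundle = bundle, extrema = extrema,
                 importance = importance, breadth = breadth,
                 screen = screen, filter_tally = filt$tally,
                 n_centroids = nrow(centroids), area = area),
            class = "field_pipeline")
}

in_boxes <- function(lon, lat, boxes) {
  hit <- rep(FALSE, length(lon))
  for (b in boxes) {
    hit <- hit | (lon >= b[["lon_min"]] & lon <= b[["lon_max"]] &
                    lat >= b[["lat_min"]] & lat <= b[["lat_max"]])
  }
  hit
}

drop_in_boxes <- function(records, boxes) {
  records[!in_boxes(records$lon, records$lat, boxes), , drop = FALSE]
}

#' Regional-exclusion sensitivity refit
#'
#' Re-runs the field pipeline with occurrences and background candidates
#' inside the exclusion boxes removed, using the same master seed and the
#' same ecoregions/bias surface, and reports baseline and refit extrema
#' side by side. An empty exclusion reproduces the baseline exactly.
#'
#' @param world a `synthetic_world`.
#' @param exclusion list of bounding boxes (possibly empty).
#' @param master_seed master RNG seed shared with the baseline.
#' @param profile a `fit_profile`.
#' @param baseline optionally a precomputed baseline `field_pipeline`.
#' @param ... passed to [run_field_pipeline].
#' @return list with `baseline`, `refit`, `comparison` (data.frame of
#'   extrema medians side by side).
#' @export
region_exclusion_refit <- function(world, exclusion, master_seed = 1L,
                                   profile = profile_desk(),
                                   baseline = NULL, ...) {
  seeds <- derive_seeds(master_seed, 5L)
  eco <- generate_ecoregions(world, seed = seeds[1])
  bias <- generate_bias_surface(world, seed = seeds[2])
  baseline <- baseline %||%
    run_field_pipeline(world, master_seed, profile,
                       ecoregions = eco, bias = bias, ...)
  refit <- run_field_pipeline(world, master_seed, profile,
                              exclusion = exclusion,
                              ecoregions = eco, bias = bias, ...)
  comparison <- data.frame(
    quantity = c("tmin", "topt"),
    baseline = c(baseline$extrema$tmin$median, baseline$extrema$topt$median),
    refit = c(refit$extrema$tmin$median, refit$extrema$topt$median)
  )
  list(baseline = baseline, refit = refit, comparison = comparison)
}

#' Run the lab (mechanistic) side for one species
#'
#' Generates pseudo-posterior trait draws around the species' trait
#' parameters, composes the abundance curve M(T), and summarizes its
#' thermal extrema with credible intervals.
#'
#' @param trait_params named trait list (see [trait_params_for_truth]).
#' @param n_draws posterior draws (study default 5000).
#' @param dispersion pseudo-posterior spread (degrees C on thresholds).
#' @param seed RNG seed.
#' @param grid temperature grid for M(T).
#' @return list with `posterior`, `curve`, `extrema`.
#' @export
run_lab_pipeline <- function(trait_params = default_trait_params(),
                             n_draws = 5000L, dispersion = 0.5, seed = 1L,
                             grid = seq(0, 45, by = 0.1)) {
  posterior <- generate_trait_posteriors(trait_params, n_draws = n_draws,
                                         dispersion = dispersion, seed = seed)
  curve <- abundance_curve(posterior, grid = grid)
  list(posterior = posterior, curve = curve,
       extrema = posterior_summary(curve))
}

#' Full lab-versus-field study over several synthetic species
#'
#' For each species (a named true thermal parameter set), runs the field
#' pipeline on its own synthetic world and the lab pipeline on a matched
#' trait set, then correlates the median thermal minima and optima across
#' species.
#'
#' @param species_truths named list of [true_suitability_params].
#' @param master_seed master RNG seed.
#' @param profile a `fit_profile`.
#' @param n_occurrences occurrence records per species.
#' @param n_draws,dispersion lab-side posterior settings.
#' @param world_seed_offset per-species worlds use
#'   `master_seed + offset + species index` as their config seed.
#' @return list of class `study_report`: `pairs` (per-species medians),
#'   `comparison` ([compare_lab_field] output), `field` and `lab`
#'   per-species results.
#' @export
run_study <- function(species_truths, master_seed = 1L,
                      profile = profile_desk(), n_occurrences = 1000L,
                      n_draws = 1000L, dispersion = 0.5,
                      world_seed_offset = 100L) {
  stopifnot(length(species_truths) >= 1, !is.null(names(species_truths)))
  seeds <- derive_seeds(master_seed, length(species_truths))
  field <- list(); lab <- list()
  for (k in seq_along(species_truths)) {
    sp <- names(species_truths)[k]
    tp <- species_truths[[k]]
    cfg <- synthetic_world_config(
      seed = master_seed + world_seed_offset + k,
      true_thermal = tp, n_occurrences = n_occurrences
    )
    world <- generate_world(cfg)
    field[[sp]] <- run_field_pipeline(world, master_seed = seeds[k],
                                      profile = profile)
    lab[[sp]] <- run_lab_pipeline(
      trait_params_for_truth(tp$tmin, tp$topt, tp$tmax),
      n_draws = n_draws, dispersion = dispersion, seed = seeds[k]
    )
  }
  pairs <- data.frame(
    species = names(species_truths),
    field_tmin = vapply(field, function(f) f$extrema$tmin$median, 0),
    field_topt = vapply(field, function(f) f$extrema$topt$median, 0),
    lab_tmin = vapply(lab, function(l) l$extrema$tmin$median, 0),
    lab_topt = vapply(lab, function(l) l$extrema$topt$median, 0),
    true_tmin = vapply(species_truths, function(t) t$tmin, 0),
    true_topt = vapply(species_truths, function(t) t$topt, 0),
    row.names = NULL
  )
  structure(list(pairs = pairs,
                 comparison = compare_lab_field(pairs),
                 field = field, lab = lab),
            class = "study_report")
}
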