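# Deterministic hand-built fixtures shared across test files.

# A 10 x 10 world (cell 0.1 deg, extent [0,1] x [0,1]) with fully known
# structure: temperature rises with latitude row (11..20 degC), cell (1,1)
# is water, cell (2,2) has a missing vegetation value. Used wherever tests
# need hand-derivable filtering/lookup outcomes.
fixture_world <- function() {
  origin <- c(0, 0); cs <- 0.1
  temp <- matrix(rep(10 + 1:10, 10), 10, 10)          # row i -> 10 + i degC
  tsd <- matrix(3, 10, 10)
  veg <- matrix(0.5, 10, 10); veg[2, 2] <- NA
  land <- matrix(TRUE, 10, 10); land[1, 1] <- FALSE
  temp[1, 1] <- NA; tsd[1, 1] <- NA; veg[1, 1] <- NA
  grids <- list(
    temperature_mean = raster_grid("temperature_mean", origin, cs, temp),
    temperature_sd = raster_grid("temperature_sd", origin, cs, tsd),
    vegetation_index = raster_grid("vegetation_index", origin, cs, veg)
  )
  structure(list(grids = grids, land = land, config = NULL,
                 truth = true_suitability_params()),
            class = "synthetic_world")
}

# Season length per cell of fixture_world: year-round except cell (3,3)
# (cell id 23), which has a zero-length season.
fixture_season_length <- function() {
  sl <- rep(365, 100)
  sl[23] <- 0
  sl
}

# Path to the shipped 12-record occurrence fixture.
fixture_occurrences_path <- function() {
  system.file("extdata", "occurrences_fixture.csv", package = "thermoniche",
              mustWork = TRUE)
}

# A small generated world for sampler statistics: coarse enough that
# Monte-Carlo frequency checks have adequate power.
small_world <- function(seed = 11, n_occurrences = 200L) {
  generate_world(synthetic_world_config(
    seed = seed,
    extent = c(lon_min = 0, lon_max = 1, lat_min = 0, lat_max = 1),
    cell_size = 0.05, n_ecoregions = 3L, n_occurrences = n_occurrences
  ))
}

# Minimal fitting profile for unit tests of the model-fitting chain.
# max_bin exceeds the row counts used, so histogram quantization cannot
# merge distinct feature values (separable toy tables stay separable).
tiny_profile <- function() {
  profile_desk(space = hyperparameter_space(max_boost_rounds = 40L,
                                            max_opt_rounds = 3L),
               n_iterations = 2L, early_stopping_rounds = 10L,
               max_bin = 2048L)
}

# Quick labeled table with a separable signal on one feature.
separable_table <- function(n = 400, seed = 5) {
  withr::with_seed(seed, {
    x1 <- rnorm(n); x2 <- rnorm(n)
    data.frame(label = as.integer(x1 > 0),
               temperature_mean = 20 + 10 * x1, other = x2)
  })
}
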