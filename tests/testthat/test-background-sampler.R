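# Hand-built 3-strip ecoregion world: 20 (lat) x 80 (lon) cells of 0.05 deg
# at the equator, vertical strips [0,1.4), [1.4,2.7), [2.7,4) degrees lon.
# At the equator 1 deg lon ~ 111.3 km, so strip borders sit at known km
# offsets from any test centroid.
strip_world <- function() {
  vals <- matrix(20, 20, 80)
  g <- raster_grid("temperature_mean", c(0, 0), 0.05, vals)
  land <- matrix(TRUE, 20, 80)
  world <- structure(list(grids = list(temperature_mean = g), land = land,
                          config = NULL, truth = true_suitability_params()),
                     class = "synthetic_world")
  strip <- function(lon) ifelse(lon < 1.4, 1L, ifelse(lon < 2.7, 2L, 3L))
  cen <- cell_centroid(g, seq_len(20 * 80))
  assignment <- matrix(NA_integer_, 20, 80)
  assignment[thermoniche:::cell_ij(g, cen$cell_id)] <- strip(cen$lon)
  eco <- structure(list(assignment = assignment,
                        adjacency = thermoniche:::ecoregion_adjacency(assignment),
                        grid = g),
                   class = "ecoregion_set")
  list(world = world, eco = eco, grid = g)
}

test_that("accessible area = buffer-intersected ecoregions plus rook-adjacent ones", {
  sw <- strip_world()
  # centroid at lon 0.125: ~142 km from the strip-2 border (1.4 deg)
  cen <- thin_to_centroids(data.frame(lon = 0.125, lat = 0.525), sw$grid)
  ar <- accessible_area(cen, sw$eco, sw$world, buffer_km = 200)
  expect_setequal(ar$core_eco_ids, c(1, 2))  # strip 2 reached via the buffer
  expect_setequal(ar$eco_ids, c(1, 2, 3))    # strip 3 only by adjacency to 2
  # a short buffer stays within the home strip; adjacency still adds strip 2
  ar2 <- accessible_area(cen, sw$eco, sw$world, buffer_km = 50)
  expect_equal(ar2$core_eco_ids, 1)
  expect_setequal(ar2$eco_ids, c(1, 2))
  # enlarging the buffer never shrinks the selection
  ar3 <- accessible_area(cen, sw$eco, sw$world, buffer_km = 400)
  expect_true(all(ar2$eco_ids %in% ar3$eco_ids))
})

test_that("two-ecoregion worlds always select both regions", {
  w <- small_world()
  eco <- generate_ecoregions(w, n_ecoregions = 2, seed = 4)
  b <- generate_bias_surface(w, seed = 2)
  occ <- sample_occurrences(w, n = 50, bias = b, seed = 3)
  cen <- thin_to_centroids(filter_records(occ, w)$records, w$grids[[1]])
  ar <- accessible_area(cen, eco, w)
  expect_setequal(ar$eco_ids, c(1, 2))
})

test_that("bias mask restricts, renormalizes and falls back to uniform", {
  g <- fixture_world()$grids[[1]]
  ar <- structure(list(eco_ids = 1L, eligible_cells = c(45L, 46L, 47L)),
                  class = "accessible_area")
  tal <- data.frame(cell_id = c(45L, 46L, 47L, 99L), tally = c(3, 1, 0, 50))
  m <- build_bias_mask(tal, ar)
  expect_equal(m$weight, c(0.75, 0.25, 0))   # cell 99 outside the area
  expect_lt(abs(sum(m$weight) - 1), 1e-12)
  # all-zero tallies within the area -> documented uniform fallback
  m0 <- build_bias_mask(data.frame(cell_id = 45:47, tally = c(0, 0, 0)), ar)
  expect_equal(m0$weight, rep(1 / 3, 3))
  expect_error(build_bias_mask(data.frame(cell_id = 45L, tally = -1), ar),
               "nonnegative")
})

test_that("background draws are 2x, distinct, in-area, replayable, and exclude occurrences", {
  w <- small_world()
  eco <- generate_ecoregions(w, seed = 4)
  b <- generate_bias_surface(w, seed = 2)
  occ <- sample_occurrences(w, n = 150, bias = b, seed = 3)
  cen <- thin_to_centroids(filter_records(occ, w)$records, w$grids[[1]])
  ar <- accessible_area(cen, eco, w)
  mask <- build_bias_mask(simulate_effort_tallies(b, seed = 5), ar)
  bg <- sample_background(ar, mask, cen$cell_id, seed = 9, grid = w$grids[[1]])
  expect_equal(nrow(bg), 2 * nrow(cen))
  expect_equal(anyDuplicated(bg$cell_id), 0L)
  expect_true(all(bg$cell_id %in% ar$eligible_cells))
  expect_false(any(bg$cell_id %in% cen$cell_id))
  expect_identical(bg, sample_background(ar, mask, cen$cell_id, seed = 9,
                                         grid = w$grids[[1]]))
  # asking for more cells than exist fails with the deficit
  expect_error(sample_background(ar, mask, cen$cell_id,
                                 n_occurrence_centroids = 10 * nrow(mask),
                                 seed = 1, grid = w$grids[[1]]),
               "insufficient eligible background cells")
})

test_that("thermal breadth check compares tails inclusively", {
  expect_true(thermal_breadth_check(c(5, 35), c(0, 40))$pass)
  expect_true(thermal_breadth_check(c(5, 35), c(5, 35))$pass)  # equal ranges
  res <- suppressWarnings(thermal_breadth_check(c(5, 35), c(10, 30)))
  expect_false(res$pass)
  expect_setequal(res$failing_tails, c("lower", "upper"))
  expect_warning(thermal_breadth_check(c(5, 35), c(10, 40)), "lower tail")
})
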