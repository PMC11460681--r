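test_that("world generation is deterministic given the seed", {
  cfg <- synthetic_world_config(seed = 3, extent = c(lon_min = 0, lon_max = 1,
                                                     lat_min = 0, lat_max = 1))
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$grids$temperature_mean$values,
                   w2$grids$temperature_mean$values)
  expect_identical(w1$land, w2$land)
})

test_that("temperature spans beyond the true limits and extrema are identifiable", {
  w <- generate_world(synthetic_world_config(seed = 5))
  tv <- w$grids$temperature_mean$values
  expect_lt(min(tv, na.rm = TRUE), w$truth$tmin - 5)
  expect_gt(max(tv, na.rm = TRUE), w$truth$tmax + 5)
  expect_true(check_identifiability(w))
})

test_that("auxiliary covariates stay under the collinearity screen by construction", {
  w <- generate_world(synthetic_world_config(seed = 9))
  df <- world_cells(w, land_only = TRUE)
  feats <- df[names(w$grids)]
  sc <- screen_covariates(feats, threshold = 0.8)
  expect_equal(nrow(sc$flagged), 0)
  for (nm in setdiff(names(w$grids), "temperature_mean")) {
    expect_lt(abs(cor(df$temperature_mean, df[[nm]])), 0.8)
  }
})

test_that("an extent too small for the gradient fails explicitly", {
  cfg <- synthetic_world_config(extent = c(lon_min = 0, lon_max = 0.2,
                                           lat_min = 0, lat_max = 0.2))
  expect_error(generate_world(cfg), "extent too small")
})

test_that("true suitability is zero at the limits and peaks exactly at the optimum", {
  p <- true_suitability_params(tmin = 10, topt = 25, tmax = 34, peak_prob = 0.7)
  expect_equal(true_suitability(10, p), 0)
  expect_equal(true_suitability(34, p), 0)
  expect_equal(true_suitability(c(5, 40), p), c(0, 0))
  expect_equal(true_suitability(25, p), 0.7)
  # dense-grid brute force argmax
  tg <- seq(5, 40, by = 0.01)
  s <- true_suitability(tg, p)
  expect_lt(abs(tg[which.max(s)] - 25), 0.011)
  expect_true(all(s[tg > 10 & tg < 34] > 0))
})

test_that("occurrences avoid unsuitable cells and replay exactly under a seed", {
  w <- small_world()
  b <- generate_bias_surface(w, seed = 2)
  occ1 <- sample_occurrences(w, n = 300, bias = b, seed = 10)
  occ2 <- sample_occurrences(w, n = 300, bias = b, seed = 10)
  expect_identical(occ1, occ2)
  tocc <- cell_value(w$grids$temperature_mean, occ1$cell_id)
  expect_true(all(tocc > w$truth$tmin & tocc < w$truth$tmax))
})

test_that("occurrence sampling fails when nothing is suitable", {
  w <- small_world()
  b <- generate_bias_surface(w, seed = 2)
  cold <- true_suitability_params(tmin = 60, topt = 70, tmax = 80)
  expect_error(sample_occurrences(w, params = cold, n = 10, bias = b, seed = 1),
               "all-zero sampling probability")
})

test_that("occurrence cell frequencies track suitability-times-bias probabilities", {
  # coarse world so per-cell Monte-Carlo error is small relative to TV budget
  w <- generate_world(synthetic_world_config(
    seed = 21, extent = c(lon_min = 0, lon_max = 0.4, lat_min = 0, lat_max = 0.4),
    cell_size = 0.05
  ))
  b <- generate_bias_surface(w, seed = 3)
  p <- true_suitability(cell_value(w$grids$temperature_mean, b$cell_id),
                        w$truth) * b$weight
  p <- p / sum(p)
  occ <- sample_occurrences(w, n = 50000, bias = b, seed = 4,
                            violation_fraction = 0)
  phat <- tabulate(match(occ$cell_id, b$cell_id), nbins = nrow(b)) / nrow(occ)
  tv <- 0.5 * sum(abs(phat - p))
  expect_lt(tv, 0.02)
})

test_that("ecoregions tessellate the world with derivable adjacency", {
  w <- small_world()
  eco <- generate_ecoregions(w, n_ecoregions = 4, seed = 7)
  expect_false(anyNA(eco$assignment))                     # full cover
  expect_setequal(unique(as.vector(eco$assignment)), 1:4) # every region used
  ids <- seq_len(prod(dim(eco$assignment)))
  expect_true(all(ecoregion_at(eco, ids) %in% 1:4))       # one region per cell
  # two regions are each other's only neighbor
  eco2 <- generate_ecoregions(w, n_ecoregions = 2, seed = 8)
  expect_equal(eco2$adjacency[["1"]], 2)
  expect_equal(eco2$adjacency[["2"]], 1)
})

test_that("bias surface normalizes, clusters with concentration, and replays", {
  w <- small_world()
  b <- generate_bias_surface(w, concentration = 2, seed = 5)
  expect_lt(abs(sum(b$weight) - 1), 1e-12)
  expect_true(all(b$weight >= 0))
  expect_identical(b, generate_bias_surface(w, concentration = 2, seed = 5))
  # vanishing concentration -> near-uniform weights
  b0 <- generate_bias_surface(w, concentration = 1e-6, seed = 5)
  expect_lt(max(b0$weight) / min(b0$weight), 1.5)
  # clustering grows with concentration (max weight share increases)
  expect_gt(max(b$weight), max(b0$weight))
})
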