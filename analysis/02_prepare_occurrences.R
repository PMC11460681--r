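#!/usr/bin/env Rscript
# Stage 2: clean occurrences and assemble the training table.
#
# Applies the record-cleaning cascade (period, basis of record, coordinate
# uncertainty/precision, land, covariate completeness), thins survivors to
# unique cell centroids, builds the 200-km-buffered ecoregion accessible
# area, restricts and renormalizes the effort tallies into the bias mask,
# draws twice as many bias-weighted background centroids without
# replacement, and checks the background's thermal breadth.

suppressMessages(library(thermoniche))
sim <- "results/sim"; out_dir <- "results/prepared"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_world_config(seed = 42)
world <- generate_world(cfg)           # deterministic regeneration
eco <- generate_ecoregions(world)
bias <- generate_bias_surface(world)
occ <- read_occurrences_csv(file.path(sim, "occurrences.csv"))

filt <- filter_records(occ, world)
cen <- thin_to_centroids(filt$records, world$grids[[1]])
occ_cov <- attach_covariates(cen, world)$centroids

area <- accessible_area(cen, eco, world)
tallies <- simulate_effort_tallies(bias, seed = cfg$seed + 4L)
mask <- build_bias_mask(tallies, area)
bg <- sample_background(area, mask, cen$cell_id, seed = cfg$seed + 5L,
                        grid = world$grids[[1]])
bg_cov <- attach_covariates(bg, world)$centroids
breadth <- thermal_breadth_check(occ_cov$temperature_mean,
                                 bg_cov$temperature_mean)

table <- rbind(occ_cov, bg_cov)[c("cell_id", "lon", "lat", "label",
                                  names(world$grids))]
write.csv(table, file.path(out_dir, "training_table.csv"), row.names = FALSE)
jsonlite::write_json(as.list(filt$tally), file.path(out_dir, "filter_tally.json"),
                     auto_unbox = TRUE)
jsonlite::write_json(breadth, file.path(out_dir, "breadth_check.json"),
                     auto_unbox = TRUE)

message(sprintf(
  "Filtered %d -> %d records (%d rejected); %d unique presence centroids; accessible area %d/%d ecoregions, %d eligible cells; %d background centroids; thermal breadth %s.",
  nrow(occ), nrow(filt$records), nrow(occ) - nrow(filt$records), nrow(cen),
  length(area$eco_ids), cfg$n_ecoregions, length(area$eligible_cells),
  nrow(bg), if (breadth$pass) "OK" else "NARROW"
))
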