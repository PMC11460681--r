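#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study world.
#
# Builds the reference 60 x 60 world (temperature mean/SD plus five
# auxiliary covariates and a land mask), a 6-region ecoregion tessellation,
# a clustered sampling-effort surface, 1,000 presence-only occurrence
# records drawn from the known thermal truth (Tmin* 12, Topt* 27, Tmax* 36),
# and pseudo-posterior trait draws. Everything is written as plain text
# under results/sim/ for the later stages.

suppressMessages(library(thermoniche))
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_world_config(seed = 42)
world <- generate_world(cfg)
eco <- generate_ecoregions(world)
bias <- generate_bias_surface(world)
occ <- sample_occurrences(world, bias = bias)
post <- generate_trait_posteriors(
  trait_params_for_truth(cfg$true_thermal$tmin, cfg$true_thermal$topt,
                         cfg$true_thermal$tmax),
  n_draws = 2000, dispersion = 0.5, seed = cfg$seed
)

write_world_csv(world, file.path(out_dir, "world_covariates.csv"))
write_occurrences_csv(occ, file.path(out_dir, "occurrences.csv"))
write_ecoregions_geojson(eco, file.path(out_dir, "ecoregions.geojson"))
write.csv(data.frame(cell_id = bias$cell_id, weight = bias$weight),
          file.path(out_dir, "bias_surface.csv"), row.names = FALSE)
write_trait_draws_csv(post, file.path(out_dir, "trait_draws.csv"))

tv <- range(world$grids$temperature_mean$values, na.rm = TRUE)
message(sprintf(
  "World: %d land cells; temperature %.1f..%.1f degC (truth %g/%g/%g); %d occurrence records (%d with injected filter violations).",
  sum(world$land), tv[1], tv[2], cfg$true_thermal$tmin, cfg$true_thermal$topt,
  cfg$true_thermal$tmax, nrow(occ), sum(occ$violation != "")
))
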