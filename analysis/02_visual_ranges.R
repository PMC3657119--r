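#!/usr/bin/env Rscript

# Stage 2: per-species visual ranges.
# Models every pigment with the A1 template, applies oil-droplet filtering
# where it routes (birds, diurnal reptiles; non-UV receptors), and extracts
# the outermost half-maximum wavelengths per species.

suppressPackageStartupMessages(library(lampvision))

SEED <- 1L
cfg <- pipeline_config(seed = SEED)
grid <- wavelength_grid(cfg$grid_from, cfg$grid_to, cfg$grid_step)

species <- read_species_table("results/inputs/species_photoreceptors.csv")
ranges <- species_visual_ranges(species, grid = grid, level = cfg$half_level,
                                slope = cfg$droplet_slope,
                                renormalize = cfg$renormalize)
write_result_csv(ranges, "results/species_visual_ranges.csv", cfg)

cat(sprintf("computed lambda_0.5 ranges for %d species\n", nrow(ranges)))
cat("\nclass medians (nm):\n")
agg <- stats::aggregate(cbind(min_lambda_half_nm, max_lambda_half_nm) ~ class,
                        data = ranges, FUN = stats::median)
print(agg, row.names = FALSE)
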