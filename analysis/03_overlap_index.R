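#!/usr/bin/env Rscript

# Stage 3: lamp emission ranges and the overlap index.
# Determines each lamp's emission span (1% of baseline-corrected peak) and
# computes the percentage of every species' lambda_0.5 range it stimulates.

suppressPackageStartupMessages({
  library(lampvision)
  library(readr)
})

SEED <- 1L
cfg <- pipeline_config(seed = SEED)
grid <- wavelength_grid(cfg$grid_from, cfg$grid_to, cfg$grid_step)

lamp_files <- list.files("results/inputs", pattern = "^lamp_.*\\.txt$",
                         full.names = TRUE)
lamps <- lapply(lamp_files, function(f) {
  read_lamp_spectrum(f, sub("^lamp_(.*)\\.txt$", "\\1", basename(f)),
                     grid = grid)
})
names(lamps) <- vapply(lamps, `[[`, character(1), "lamp_type")
emissions <- lapply(lamps, emission_range, rel_threshold = cfg$rel_threshold,
                    gap_merge = cfg$gap_merge)
for (em in emissions) print(em)

ranges <- read_csv("results/species_visual_ranges.csv", comment = "#",
                   show_col_types = FALSE)
overlap <- overlap_table(ranges, emissions, mode = cfg$emission_mode)
write_result_csv(overlap, "results/overlap_table.csv", cfg)
cat(sprintf("\noverlap table: %d species x %d lamps = %d rows\n",
            length(unique(overlap$species_id)), length(emissions),
            nrow(overlap)))
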