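#!/usr/bin/env Rscript

# Stage 1: synthesize the study inputs.
# Generates the default synthetic fleet (213 species across five classes,
# one row per photoreceptor, droplet parameters for birds and diurnal
# reptiles) and the four street-lamp archetype spectra, and writes them as
# the plain-text inputs every later stage reads.

suppressPackageStartupMessages(library(lampvision))

SEED <- 1L
cfg <- pipeline_config(seed = SEED)
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)

species <- generate_species_table(seed = cfg$seed)
write_species_table(species, "results/inputs/species_photoreceptors.csv")
cat(sprintf("species table: %d rows, %d species\n",
            nrow(species), length(unique(species$species_id))))
print(table(species$class[!duplicated(species$species_id)]))

grid <- wavelength_grid(cfg$grid_from, cfg$grid_to, cfg$grid_step)
arch <- default_lamp_archetypes()
for (i in seq_along(arch)) {
  sp <- generate_lamp_spectrum(arch[[i]], grid = grid, seed = cfg$seed + i)
  path <- sprintf("results/inputs/lamp_%s.txt", names(arch)[i])
  write_lamp_spectrum(sp, path)
  cat(sprintf("lamp %-3s -> %s (peak %.3f)\n", names(arch)[i], path,
              max(sp$irradiance)))
}
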