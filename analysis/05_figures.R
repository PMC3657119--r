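#!/usr/bin/env Rscript

# Stage 5: figures.
# Class-level visual-range limits and % range stimulated per lamp, from the
# posterior summaries written by stage 4.

suppressPackageStartupMessages({
  library(lampvision)
  library(readr)
  library(ggplot2)
})

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

range_summaries <- read_csv("results/class_visual_ranges.csv", comment = "#",
                            show_col_types = FALSE)
ggsave("results/figures/class_visual_ranges.png",
       plot_visual_ranges(range_summaries), width = 7, height = 4, dpi = 150)

percent_summaries <- read_csv("results/percent_stimulated_summaries.csv",
                              comment = "#", show_col_types = FALSE)
ggsave("results/figures/percent_stimulated.png",
       plot_percent_stimulated(percent_summaries), width = 7, height = 4,
       dpi = 150)

cat("wrote results/figures/class_visual_ranges.png and percent_stimulated.png\n")
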