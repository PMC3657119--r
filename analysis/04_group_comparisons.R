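#!/usr/bin/env Rscript

# Stage 4: Bayesian group estimates and pairwise comparisons.
# Zero-intercept cell-means regression gives posterior class means (of the
# half-maximum limits and of % range stimulated); fitted-intercept refits
# give pairwise differences between lamps within classes and between classes
# within lamps, flagged credible when the 95% interval excludes zero.

suppressPackageStartupMessages({
  library(lampvision)
  library(readr)
})

SEED <- 1L
cfg <- pipeline_config(seed = SEED)
mcmc <- list(burnin = cfg$burnin, samples = cfg$samples,
             c0 = cfg$c0, d0 = cfg$d0)

ranges <- read_csv("results/species_visual_ranges.csv", comment = "#",
                   show_col_types = FALSE)
overlap <- read_csv("results/overlap_table.csv", comment = "#",
                    show_col_types = FALSE)

range_summaries <- dplyr::bind_rows(
  dplyr::mutate(do.call(group_means, c(list(ranges, "min_lambda_half_nm",
                                            "class", seed = cfg$seed + 101L),
                                       mcmc)),
                quantity = "min_lambda_half_nm"),
  dplyr::mutate(do.call(group_means, c(list(ranges, "max_lambda_half_nm",
                                            "class", seed = cfg$seed + 102L),
                                       mcmc)),
                quantity = "max_lambda_half_nm"))
write_result_csv(range_summaries, "results/class_visual_ranges.csv", cfg)

lamps <- sort(unique(overlap$lamp_type))
percent_summaries <- dplyr::bind_rows(lapply(seq_along(lamps), function(i) {
  sub <- overlap[overlap$lamp_type == lamps[i], ]
  out <- do.call(group_means, c(list(sub, "percent_stimulated", "class",
                                     seed = cfg$seed + 200L + i), mcmc))
  out$lamp_type <- lamps[i]
  out
}))
write_result_csv(percent_summaries,
                 "results/percent_stimulated_summaries.csv", cfg)

classes <- sort(unique(overlap$class))
within_class <- dplyr::bind_rows(lapply(seq_along(classes), function(i) {
  sub <- overlap[overlap$class == classes[i], ]
  out <- do.call(pairwise_differences,
                 c(list(sub, "percent_stimulated", "lamp_type",
                        seed = cfg$seed + 300L + 10L * i), mcmc))
  out$class <- classes[i]
  out
}))
write_result_csv(within_class, "results/lamp_pairs_within_class.csv", cfg)

within_lamp <- dplyr::bind_rows(lapply(seq_along(lamps), function(i) {
  sub <- overlap[overlap$lamp_type == lamps[i], ]
  out <- do.call(pairwise_differences,
                 c(list(sub, "percent_stimulated", "class",
                        seed = cfg$seed + 400L + 10L * i), mcmc))
  out$lamp_type <- lamps[i]
  out
}))
write_result_csv(within_lamp, "results/class_pairs_within_lamp.csv", cfg)

cat("posterior class means of % range stimulated:\n")
print(tidyr::pivot_wider(percent_summaries[, c("level_label", "lamp_type", "mean")],
                         names_from = "lamp_type", values_from = "mean"))
cat("\ncredible class-pair differences per lamp:\n")
print(tapply(within_lamp$credible, within_lamp$lamp_type, sum))
cat("\nlamp pairs within each class (mean difference, 95% CI):\n")
for (cls in classes) {
  cat("--", cls, "--\n")
  print(format_pairwise(within_class[within_class$class == cls,
                                     c("level_a", "level_b", "diff_mean",
                                       "diff_ci_low", "diff_ci_high",
                                       "mcse", "credible")]))
}
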