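#!/usr/bin/env Rscript
# Stage 1 — simulate the reference serum cohort.
#
# Generates the package's default synthetic cohort (n = 2000; 41 serum
# metabolites + 112 lipoprotein parameters in correlated blocks;
# profile prevalences on the scale of a large working-population
# cohort, asymptomatic ~68.5%, WHO-MetS ~2%) and writes it, with its
# variable-type sidecar and a demographic summary, for the later
# stages. The full table goes to scratch/ (it is regenerated by code);
# the summary table to results/.

suppressPackageStartupMessages(library(metscore))

seed <- 20260920L
dir.create("scratch/analysis", showWarnings = FALSE, recursive = TRUE)
dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)

gen <- default_generator_config(n_samples = 2000, seed = seed)
cohort <- generate_cohort(gen)
print(cohort)

write_cohort(cohort, "scratch/analysis/cohort.csv")
write.csv(generator_block_map(gen), "results/analysis/variable_blocks.csv",
          row.names = FALSE)

summ <- cohort_summary(cohort)
write.csv(summ, "results/analysis/cohort_summary.csv", row.names = FALSE)

who <- summ[summ$block == "mets_who", ]
message(sprintf(
  "Simulated %d samples; MetS (WHO): %d (%.1f%%); asymptomatic: %.1f%%",
  n_samples(cohort), who$n[who$level == "MetS"], who$pct[who$level == "MetS"],
  summ$pct[summ$block == "profile" & summ$level == "0000"]))
message("Cohort written to scratch/analysis/cohort.csv")
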