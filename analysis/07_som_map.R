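#!/usr/bin/env Rscript
# Stage 7 — self-organizing map of individuals.
#
# Trains a batch Kohonen map on the autoscaled selected serum
# variables, groups the codebook cells into 6 regions by Ward.D2, and
# summarizes each cell by sample count, observed MetS fraction and
# mean MetSCORE. The map's MetS-fraction and mean-score surfaces
# should agree (the score recovers the metadata geography). An 8 x 8
# grid keeps ~30 samples per cell so the per-cell MetS fraction is
# informative at ~2% prevalence.

suppressPackageStartupMessages(library(metscore))

seed <- 20260920L
cohort <- read_cohort("scratch/analysis/cohort.csv")
final <- fit_mets_model(cohort)
scores <- predict_mets(final, cohort)

Z <- opls_preprocess(cohort_values(cohort, variables = final$selected),
                     params = final$opls)$Z
som <- fit_som(Z, rows = 8, cols = 8, epochs = 20, seed = seed)
print(som)

groups <- group_cells(som, k = 6)
stats <- cell_statistics(som, cohort_mets(cohort), scores$metscore, groups)
write.csv(stats, "results/analysis/som_map.csv", row.names = FALSE)

ok <- !stats$empty & stats$n >= 3
rho <- cor(stats$mets_fraction[ok], stats$mean_score[ok],
           method = "spearman")
message(sprintf(
  "SOM %d x %d, %d groups; Spearman(MetS fraction, mean MetSCORE) across cells = %.2f",
  som$rows, som$cols, length(unique(groups)), rho))
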