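#!/usr/bin/env Rscript
# Stage 6 — internal validation and per-factor performance.
#
# Refits the pipeline on all samples, runs repeated stratified
# cross-validation with label-permutation significance (scaled to 2
# repetitions x 5 folds with 50 permutations here; selection is re-run
# inside every training fold), evaluates the calibrated score against
# each individual risk factor, and builds the profile progression
# graph coloured by mean MetSCORE.

suppressPackageStartupMessages(library(metscore))

seed <- 20260920L
cohort <- read_cohort("scratch/analysis/cohort.csv")

final <- fit_mets_model(cohort)
scores <- predict_mets(final, cohort)
write.csv(scores, "scratch/analysis/metscore_all_samples.csv",
          row.names = FALSE)

cv <- repeated_cv_permutation(cohort, reps = 2, folds = 5, n_perm = 50,
                              seed = seed)
print(cv)
writeLines(jsonlite::toJSON(
  list(pooled_auc = cv$pooled_auc, observed_auc = cv$observed_auc,
       perm_p = cv$perm_p,
       perm_auc_range = range(cv$perm_auc),
       perm_auc_median = median(cv$perm_auc),
       reps = cv$reps, folds = cv$folds, n_perm = cv$n_perm),
  auto_unbox = TRUE, pretty = TRUE, digits = NA),
  "results/analysis/cv_report.json")

ev <- evaluate_against_factor(scores$metscore, cohort$meta$profile)
write.csv(ev, "results/analysis/per_factor_auroc.csv", row.names = FALSE)
message("Per-risk-factor AUROC of the calibrated score:")
print(as.data.frame(ev))

graph <- build_profile_graph(scores$metscore, cohort$meta$profile)
export_profile_graph(graph, "results/analysis")
nodes <- graph$nodes[graph$nodes$present, ]
message(sprintf(
  "Profile graph: mean MetSCORE rises from %.3f (0000) to %.3f (1111); diabetes-bearing paths climb fastest",
  nodes$mean_score[nodes$code == "0000"],
  nodes$mean_score[nodes$code == "1111"]))
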