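#!/usr/bin/env Rscript
# Stage 5 — discriminant model and MetSCORE calibration.
#
# Fits the O-PLS-DA (one predictive + one orthogonal component, log +
# autoscale preprocessing) on the training set against the WHO-MetS
# label, sets the Youden threshold on t_pred, calibrates the
# class-weighted sigmoid so the threshold maps to MetSCORE 0.5, and
# evaluates on the held-out test set. Also rebuilds the reduced model
# without glucose and the HDL/LDL clusters that molecularly define
# diabetes and dyslipidemia.

suppressPackageStartupMessages(library(metscore))

cohort <- read_cohort("scratch/analysis/cohort.csv")
train <- cohort_subset(cohort, readLines("scratch/analysis/train_ids.txt"))
test <- cohort_subset(cohort, readLines("scratch/analysis/test_ids.txt"))

model <- fit_mets_model(train)
print(model)
write_opls_model(model, "results/analysis/model.json")

vi <- variable_influence(model$opls)
write.csv(vi, "results/analysis/variable_influence.csv", row.names = FALSE)
message("Most influential variables (sign = direction in MetS):")
print(head(as.data.frame(vi), 8))

pred <- predict_mets(model, test)
auc <- roc_auc(pred$t_pred, cohort_mets(test))
message(sprintf("Held-out AUROC %.3f (95%% CI %.3f-%.3f), %d test samples",
                auc$auc, auc$ci_lower, auc$ci_upper, nrow(test$meta)))
write.csv(pred, "results/analysis/test_scores.csv", row.names = FALSE)

# reduced model: uncorrelated from the molecular definitions of the
# diabetes / dyslipidemia risk factors
cfg_red <- pipeline_config(
  exclusion_patterns = c(default_exclusion_patterns(),
                         reduced_model_exclusions()))
model_red <- fit_mets_model(train, cfg_red)
pred_red <- predict_mets(model_red, test)
auc_red <- roc_auc(pred_red$t_pred, cohort_mets(test))
message(sprintf(
  "Reduced model (no glucose / HDL / dense-LDL): %d variables, held-out AUROC %.3f",
  length(model_red$selected), auc_red$auc))
writeLines(jsonlite::toJSON(
  list(full_auc = auc$auc, full_ci = c(auc$ci_lower, auc$ci_upper),
       reduced_auc = auc_red$auc,
       reduced_variables = model_red$selected),
  auto_unbox = TRUE, pretty = TRUE, digits = NA),
  "results/analysis/model_metrics.json")
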