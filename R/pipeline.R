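# End-to-end pipeline: split -> univariate contrasts -> variable
# clustering and filtering cascade -> O-PLS-DA -> Youden threshold ->
# MetSCORE calibration -> test evaluation -> final refit with repeated
# CV + permutation -> SOM map and profile graph.

#' Pipeline configuration
#'
#' All tunable parameters of the workflow with their reference defaults:
#' dendrogram cut heights 0.5 (serum) / 0.85 (urine bins), effect-size
#' threshold 0.5 SD, FDR level 0.05, near-zero-variance rule 19 and 10%,
#' 80/20 train/test split, one predictive + one orthogonal component,
#' 10 x 5-fold CV with 100 permutations, 6 SOM cell groups.
#'
#' @param dataset `"serum_only"` (metabolites + lipoproteins) or
#'   `"serum_plus_urine"` (adds urine bins).
#' @param split_fraction training fraction of the initial split.
#' @param alpha FDR significance level.
#' @param effect_threshold minimum absolute effect size (SD units).
#' @param cut_heights named cut heights per dataset type.
#' @param exclusion_patterns manual-exclusion regular expressions;
#'   append [reduced_model_exclusions()] for the reduced model.
#' @param n_orth orthogonal components.
#' @param cv_reps,cv_folds,n_perm cross-validation / permutation sizes.
#' @param som_groups SOM cell groups (Ward.D2 cut).
#' @param som_epochs SOM training epochs.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(dataset = c("serum_only", "serum_plus_urine"),
                            split_fraction = 0.8,
                            alpha = 0.05,
                            effect_threshold = 0.5,
                            cut_heights = c(serum_metabolite = 0.5,
                                            serum_lipoprotein = 0.5,
                                            urine_bin = 0.85),
                            exclusion_patterns = default_exclusion_patterns(),
                            n_orth = 1L,
                            cv_reps = 10L, cv_folds = 5L, n_perm = 100L,
                            som_groups = 6L, som_epochs = 20L,
                            seed = 1L) {
  dataset <- match.arg(dataset)
  stopifnot(split_fraction > 0, split_fraction < 1,
            alpha > 0, alpha < 1, effect_threshold >= 0,
            all(cut_heights >= 0), n_orth >= 1, cv_folds >= 2)
  structure(list(dataset = dataset, split_fraction = split_fraction,
                 alpha = alpha, effect_threshold = effect_threshold,
                 cut_heights = cut_heights,
                 exclusion_patterns = exclusion_patterns,
                 n_orth = as.integer(n_orth),
                 cv_reps = as.integer(cv_reps),
                 cv_folds = as.integer(cv_folds),
                 n_perm = as.integer(n_perm),
                 som_groups = as.integer(som_groups),
                 som_epochs = as.integer(som_epochs),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_types <- function(config) {
  switch(config$dataset,
         serum_only = c("serum_metabolite", "serum_lipoprotein"),
         serum_plus_urine = c("serum_metabolite", "serum_lipoprotein",
                              "urine_bin"))
}

#' Fit the MetS discriminant pipeline on a training cohort
#'
#' Runs, in order: univariate profile contrasts with FDR control,
#' the per-type filtering cascade (manual discards, near-zero-variance,
#' Spearman clustering, effect/significance filter, representative
#' selection), O-PLS-DA on the selected variables against the WHO MetS
#' label, Youden thresholding of the training t_pred, and sigmoid
#' calibration of the MetSCORE.
#'
#' @param cohort training `cohort_table`.
#' @param config a `pipeline_config`.
#' @param selection_fallback_k forwarded to [filter_variables()]; NULL
#'   (the default) keeps the strict empty-survivor error.
#' @return Object of class `mets_model`: list with `opls`, `selected`,
#'   `selection` (per-type `selection_result`), `effects`, `youden`,
#'   `calibration`, `config`.
#' @export
fit_mets_model <- function(cohort, config = pipeline_config(),
                           selection_fallback_k = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  types <- intersect(config_types(config), unique(cohort$variable_types))
  vars <- names(cohort$variable_types)[cohort$variable_types %in% types]
  effects <- univariate_effects(cohort, variables = vars,
                                alpha = config$alpha)
  selection <- lapply(stats::setNames(types, types), function(tp) {
    filter_variables(cohort, tp, effects,
                     cut_height = config$cut_heights[[tp]],
                     effect_threshold = config$effect_threshold,
                     exclusion_patterns = config$exclusion_patterns,
                     fallback_top_k = selection_fallback_k)
  })
  selected <- sort(unique(unlist(lapply(selection, `[[`, "selected"))))
  y <- cohort_mets(cohort)
  opls <- fit_oplsda(cohort_values(cohort, variables = selected), y,
                     n_orth = config$n_orth)
  yt <- youden_threshold(opls$t_pred, y)
  cal <- calibrate_metscore(opls$t_pred, y, yt$threshold)
  structure(list(opls = opls, selected = selected, selection = selection,
                 effects = effects, youden = yt, calibration = cal,
                 config = config),
            class = "mets_model")
}

#' @export
print.mets_model <- function(x, ...) {
  cat("MetS discriminant pipeline fit\n")
  cat("  selected variables: ", length(x$selected), "\n", sep = "")
  cat(sprintf("  Youden threshold %.4f (sens %.3f, spec %.3f)\n",
              x$youden$threshold, x$youden$sensitivity,
              x$youden$specificity))
  print(x$calibration)
  invisible(x)
}

#' Score samples with a fitted pipeline
#'
#' @param model a `mets_model` (or an `opls_model` carrying a
#'   `calibration`).
#' @param cohort a `cohort_table` (or raw value matrix) containing the
#'   model's variables.
#' @return Tibble with `sample_id`, `t_pred`, `metscore`, `mets_call`
#'   (TRUE when the score exceeds 0.5, equivalently t_pred above the
#'   Youden threshold).
#' @export
predict_mets <- function(model, cohort) {
  if (inherits(model, "mets_model")) {
    opls <- model$opls; cal <- model$calibration
  } else if (inherits(model, "opls_model")) {
    opls <- model; cal <- model$calibration
    if (is.null(cal)) stop("model carries no MetSCORE calibration")
  } else stop("unsupported model object")
  if (inherits(cohort, "cohort_table")) {
    X <- cohort_values(cohort, variables = opls$variables)
    ids <- cohort$meta$sample_id
  } else {
    X <- as.matrix(cohort)
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  pr <- opls_project(opls, X)
  score <- cal$metscore(pr$t_pred)
  tibble::tibble(sample_id = ids, t_pred = pr$t_pred, metscore = score,
                 mets_call = score > 0.5)
}

run_stage <- function(stage, expr, log_fun) {
  log_fun(paste0("stage: ", stage))
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline and write every artifact
#'
#' Executes the stages in order (split, fit on the training set,
#' evaluation on the test set, final refit on all samples,
#' cross-validation with permutation analysis, SOM mapping, profile
#' graph) and writes the serialized model, the effect table, selection
#' provenance, CV report, test metrics, SOM map, profile graph, cohort
#' summary and a run log into `output_dir`. Every artifact embeds the
#' config hash and global seed.
#'
#' @param cohort a `cohort_table`.
#' @param config a `pipeline_config`.
#' @param output_dir directory for artifacts (created if needed);
#'   NULL skips writing.
#' @param quiet suppress progress messages.
#' @return Object of class `pipeline_result`: list with `model`
#'   (final refit `mets_model` on all samples), `train_model`,
#'   `split`, `test_metrics`, `cv`, `som`, `graph`, `scores`,
#'   `config_hash`.
#' @export
run_full_pipeline <- function(cohort, config = pipeline_config(),
                              output_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  cfg_hash <- rlang::hash(unclass(config))
  log_lines <- character(0)
  log_fun <- function(msg) {
    line <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  log_fun(paste0("config hash ", cfg_hash, ", seed ", config$seed,
                 ", n = ", n_samples(cohort)))

  split <- run_stage("split",
    train_test_split(cohort, config$split_fraction,
                     seed = stage_seed(config$seed, "split")), log_fun)
  train <- cohort_subset(cohort, split$train)
  test <- cohort_subset(cohort, split$test)

  train_model <- run_stage("train_fit", fit_mets_model(train, config), log_fun)
  log_fun(paste0("selected ", length(train_model$selected),
                 " variables: ", paste(train_model$selected, collapse = ", ")))

  test_metrics <- run_stage("test_evaluation", {
    pred <- predict_mets(train_model, test)
    y <- cohort_mets(test)
    a <- roc_auc(pred$t_pred, y)
    list(auc = a$auc, ci_lower = a$ci_lower, ci_upper = a$ci_upper,
         n_test = nrow(test$meta), n_pos = a$n_pos,
         sensitivity = mean(pred$mets_call[y]),
         specificity = mean(!pred$mets_call[!y]))
  }, log_fun)
  log_fun(sprintf("test AUROC %.3f (%.3f-%.3f)", test_metrics$auc,
                  test_metrics$ci_lower, test_metrics$ci_upper))

  model <- run_stage("final_refit", fit_mets_model(cohort, config), log_fun)

  cv <- NULL
  if (config$cv_reps > 0L) {
    cv <- run_stage("cross_validation",
      repeated_cv_permutation(cohort, config = config,
                              reps = config$cv_reps,
                              folds = config$cv_folds,
                              n_perm = config$n_perm,
                              seed = config$seed), log_fun)
    log_fun(sprintf("CV pooled AUROC %.3f, permutation p %.4g",
                    cv$observed_auc, cv$perm_p))
  }

  scores <- run_stage("scoring", predict_mets(model, cohort), log_fun)

  som_fit <- run_stage("som", {
    Z <- opls_preprocess(cohort_values(cohort, variables = model$selected),
                         params = model$opls)$Z
    s <- fit_som(Z, epochs = config$som_epochs,
                 seed = stage_seed(config$seed, "som"))
    g <- group_cells(s, k = config$som_groups)
    stats <- cell_statistics(s, cohort_mets(cohort), scores$metscore, g)
    list(som = s, groups = g, cell_stats = stats)
  }, log_fun)

  graph <- run_stage("profile_graph",
    build_profile_graph(scores$metscore, cohort$meta$profile), log_fun)

  result <- structure(list(model = model, train_model = train_model,
                           split = split, test_metrics = test_metrics,
                           cv = cv, som = som_fit, graph = graph,
                           scores = scores, config = config,
                           config_hash = cfg_hash),
                      class = "pipeline_result")
  if (!is.null(output_dir)) {
    write_pipeline_artifacts(result, cohort, output_dir, log_lines, log_fun)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (config hash ", x$config_hash, ")\n", sep = "")
  cat(sprintf("  test AUROC %.3f (%.3f-%.3f)\n", x$test_metrics$auc,
              x$test_metrics$ci_lower, x$test_metrics$ci_upper))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV pooled AUROC %.3f, permutation p %.4g\n",
                x$cv$observed_auc, x$cv$perm_p))
  }
  print(x$model)
  invisible(x)
}

write_pipeline_artifacts <- function(result, cohort, output_dir, log_lines,
                                     log_fun) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  meta <- list(config_hash = result$config_hash, seed = result$config$seed)

  write_opls_model(result$model, p("model.json"), extra = meta)
  utils::write.csv(result$model$effects, p("effects.csv"), row.names = FALSE)
  prov <- do.call(rbind, lapply(names(result$model$selection), function(tp) {
    pr <- result$model$selection[[tp]]$provenance
    pr$type <- tp
    pr
  }))
  utils::write.csv(prov, p("selection_provenance.csv"), row.names = FALSE)
  utils::write.csv(result$scores, p("scores.csv"), row.names = FALSE)
  utils::write.csv(cohort_summary(cohort), p("cohort_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(meta, result$test_metrics), p("test_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$cv)) {
    cvj <- c(meta, list(observed_auc = result$cv$observed_auc,
                        pooled_auc = result$cv$pooled_auc,
                        perm_p = result$cv$perm_p,
                        perm_auc = result$cv$perm_auc,
                        reps = result$cv$reps, folds = result$cv$folds,
                        n_perm = result$cv$n_perm))
    jsonlite::write_json(cvj, p("cv_report.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(result$cv$fold_metrics, p("cv_fold_metrics.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(result$som$cell_stats, p("som_map.csv"),
                   row.names = FALSE)
  export_profile_graph(result$graph, output_dir)
  writeLines(log_lines, p("run_log.txt"))
  log_fun(paste0("artifacts written to ", output_dir))
  invisible(output_dir)
}

#' Score a new cohort with a serialized or in-memory model
#'
#' @param model a `mets_model`, an `opls_model` with calibration, or a
#'   path to a model JSON written by [write_opls_model()].
#' @param cohort a `cohort_table` (missing model variables raise an
#'   error naming them).
#' @return Tibble as from [predict_mets()].
#' @export
score_samples <- function(model, cohort) {
  if (is.character(model)) model <- read_opls_model(model)
  predict_mets(model, cohort)
}
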