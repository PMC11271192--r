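# Scoring and validation: train/test split, AUROC with DeLong CI,
# Youden thresholding, sigmoid calibration of t_pred into the 0-1
# MetSCORE, per-risk-factor evaluation, and repeated stratified
# cross-validation with permutation significance.

#' Random train/test split of sample ids
#'
#' Unstratified random partition: `round(fraction * n)` training
#' samples, the rest test.
#'
#' @param ids sample id vector (or a `cohort_table`, whose ids are used).
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
train_test_split <- function(ids, fraction = 0.8, seed = 1L) {
  if (inherits(ids, "cohort_table")) ids <- ids$meta$sample_id
  n <- length(ids)
  if (n < 5L) stop("need at least 5 samples to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_train <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = ids[sort(idx)], test = ids[sort(setdiff(seq_len(n), idx))])
}

#' AUROC with DeLong 95% confidence interval
#'
#' Point estimate by the rank (Mann-Whitney) formula: the probability
#' that a random positive outscores a random negative, ties counted as
#' one half. The confidence interval uses the DeLong variance method.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or 2-level factor).
#' @param ci compute the DeLong interval (default TRUE).
#' @return List with `auc`, `ci_lower`, `ci_upper`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, ci = TRUE) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  out <- list(auc = auc, ci_lower = NA_real_, ci_upper = NA_real_,
              n_pos = n_pos, n_neg = n_neg)
  if (ci) {
    ci_v <- suppressWarnings(suppressMessages(pROC::ci.auc(
      pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                quiet = TRUE), method = "delong")))
    out$ci_lower <- as.numeric(ci_v[1L])
    out$ci_upper <- as.numeric(ci_v[3L])
  }
  out
}

#' Youden-index decision threshold
#'
#' Sweeps the midpoints between consecutive distinct scores (plus
#' sentinels below the minimum and above the maximum) and returns the
#' threshold maximizing J = sensitivity + specificity - 1; a sample is
#' called positive when its score exceeds the threshold. Ties are broken
#' toward the smallest threshold.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  s <- sort(unique(scores))
  cand <- c(s[1L] - 1, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2,
            s[length(s)] + 1)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  # cumulative class counts at or below each distinct score
  idx <- match(scores, s)
  pos_le <- cumsum(tabulate(idx[labels == 1], nbins = length(s)))
  neg_le <- cumsum(tabulate(idx[labels == 0], nbins = length(s)))
  # candidate i sits between s[i-1] and s[i] (sentinels at the ends)
  pos_below <- c(0, pos_le)   # positives <= threshold
  neg_below <- c(0, neg_le)
  sens <- (n_pos - pos_below) / n_pos
  spec <- neg_below / n_neg
  j <- sens + spec - 1
  # smallest threshold among the maximizers (ties within FP noise)
  best <- which(j >= max(j) - 1e-12)[1L]
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}

#' Calibrate t_pred into the 0-1 MetSCORE
#'
#' Fits a class-weighted logistic regression of the label on `t_pred`
#' (weights inversely proportional to class frequency, so both classes
#' carry equal total weight), then replaces the fitted intercept with
#' `-slope * threshold` so the calibrated score equals exactly 0.5 at
#' the decision threshold. The result is a strictly increasing sigmoid
#' mapping t_pred into (0, 1), read as a probability-like risk of MetS.
#'
#' @param t_pred numeric predictive-component scores.
#' @param labels binary labels.
#' @param threshold decision threshold on the t_pred scale (from
#'   [youden_threshold()]).
#' @return Object of class `score_calibration`: list with `slope`,
#'   `intercept`, `threshold`, `recentering` (shift applied to the
#'   fitted intercept, on the linear-predictor scale) and `metscore`
#'   (the calibrated function).
#' @export
calibrate_metscore <- function(t_pred, labels, threshold) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  n <- length(labels)
  w <- ifelse(labels == 1, n / (2 * sum(labels == 1)),
              n / (2 * sum(labels == 0)))
  # convergence warnings under complete separation are expected: the
  # slope grows until the weighted likelihood flattens, and only its
  # sign and magnitude are consumed downstream
  fit <- suppressWarnings(
    stats::glm(labels ~ t_pred, family = stats::quasibinomial(),
               weights = w))
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("fitted slope is not positive (anti-predictive score); ",
         "check the sign convention of t_pred")
  }
  intercept <- -slope * threshold
  cal <- structure(list(slope = slope, intercept = intercept,
                        threshold = threshold,
                        recentering = intercept - unname(stats::coef(fit)[1L])),
                   class = "score_calibration")
  cal$metscore <- function(t) stats::plogis(cal$intercept + cal$slope * t)
  cal
}

#' @export
print.score_calibration <- function(x, ...) {
  cat(sprintf(
    "MetSCORE calibration: sigmoid slope %.4f, threshold %.4f (score 0.5)\n",
    x$slope, x$threshold))
  invisible(x)
}

#' Evaluate a score against each individual risk factor
#'
#' AUROC of the score against the presence of each of the four risk
#' factors separately (decoded from the profile codes). Constant factors
#' are skipped with a warning.
#'
#' @param scores numeric scores.
#' @param profiles per-sample profile codes.
#' @return Tibble with `factor`, `auc`, `ci_lower`, `ci_upper`, `n_pos`.
#' @export
evaluate_against_factor <- function(scores, profiles) {
  bits <- profile_bits(profiles)
  rows <- lapply(RISK_FACTORS, function(f) {
    y <- bits[, f]
    if (length(unique(y)) < 2L) {
      warning("risk factor '", f, "' is constant; skipped")
      return(NULL)
    }
    a <- roc_auc(scores, y)
    tibble::tibble(factor = f, auc = a$auc, ci_lower = a$ci_lower,
                   ci_upper = a$ci_upper, n_pos = a$n_pos)
  })
  do.call(rbind, rows)
}

# Stratified fold assignment: samples of each class are dealt round-robin
# into folds after a seeded shuffle, so every fold keeps both classes.
stratified_folds <- function(labels, folds, seed) {
  labels <- as_binary_labels(labels)
  if (min(table(labels)) < folds) {
    stop("rarest class has fewer samples (", min(table(labels)),
         ") than folds (", folds, "); use fewer folds")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Repeated stratified cross-validation with permutation significance
#'
#' The full fitting pipeline (variable selection + O-PLS-DA +
#' thresholding) is re-run inside every training fold — selection is
#' never performed on data that contributes to a fold's test metrics.
#' Out-of-fold scores are pooled per repetition for the AUROC; the
#' observed statistic is the mean pooled AUROC over repetitions. Each
#' permutation replicate permutes the labels once, runs a single round
#' of stratified k-fold CV on the permuted cohort, and contributes its
#' pooled AUROC to the null distribution. The permutation p-value uses
#' the add-one estimator `(1 + #{perm >= observed}) / (n_perm + 1)`, so
#' its floor is `1/(n_perm + 1)`.
#'
#' @param cohort a `cohort_table`.
#' @param fit_fun function(train_cohort) returning an object accepted by
#'   `predict_fun`; defaults to the package pipeline via `config`.
#' @param predict_fun function(fit, test_cohort) returning numeric
#'   scores for the test samples.
#' @param config pipeline configuration (see [pipeline_config()]); used
#'   by the default `fit_fun`/`predict_fun`.
#' @param reps repetitions of k-fold CV for the observed statistic.
#' @param folds number of folds.
#' @param n_perm number of label permutations (0 disables the test).
#' @param seed integer seed.
#' @return Object of class `cv_report`: list with `fold_metrics`
#'   (tibble: rep, fold, auc, sensitivity, specificity), `pooled_auc`
#'   (per-rep pooled AUROCs), `observed_auc`, `perm_auc`, `perm_p`,
#'   `reps`, `folds`, `n_perm`, `seed`.
#' @export
repeated_cv_permutation <- function(cohort, fit_fun = NULL, predict_fun = NULL,
                                    config = pipeline_config(),
                                    reps = 10L, folds = 5L, n_perm = 100L,
                                    seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(fit_fun)) {
    fit_fun <- function(train) {
      fit_mets_model(train, config, selection_fallback_k = 5L)
    }
  }
  if (is.null(predict_fun)) {
    predict_fun <- function(fit, test) {
      predict_mets(fit, test)$t_pred
    }
  }
  labels <- as.numeric(cohort_mets(cohort))

  run_cv_round <- function(cohort_x, fold) {
    lab <- as.numeric(cohort_mets(cohort_x))
    scores <- numeric(length(lab))
    fm <- vector("list", max(fold))
    for (k in seq_len(max(fold))) {
      tr <- cohort_subset(cohort_x, cohort_x$meta$sample_id[fold != k])
      te <- cohort_subset(cohort_x, cohort_x$meta$sample_id[fold == k])
      fit <- fit_fun(tr)
      sc <- predict_fun(fit, te)
      scores[fold == k] <- sc
      yt <- youden_threshold(sc, lab[fold == k])
      fold_auc <- roc_auc(sc, lab[fold == k], ci = FALSE)$auc
      fm[[k]] <- tibble::tibble(fold = k, auc = fold_auc,
                                sensitivity = yt$sensitivity,
                                specificity = yt$specificity)
    }
    list(pooled_auc = roc_auc(scores, lab, ci = FALSE)$auc,
         fold_metrics = do.call(rbind, fm))
  }

  fold_metrics <- list()
  pooled <- numeric(reps)
  for (r in seq_len(reps)) {
    fold <- stratified_folds(labels, folds, seed = stage_seed(seed, "cv") + r)
    cvr <- run_cv_round(cohort, fold)
    pooled[r] <- cvr$pooled_auc
    cvr$fold_metrics$rep <- r
    fold_metrics[[r]] <- cvr$fold_metrics
  }
  observed <- mean(pooled)

  perm_auc <- numeric(0)
  if (n_perm > 0L) {
    perm_auc <- vapply(seq_len(n_perm), function(b) {
      pseed <- stage_seed(seed, "permutation") + b
      cohort_b <- permute_profiles(cohort, seed = pseed)
      lab_b <- as.numeric(cohort_mets(cohort_b))
      fold_b <- stratified_folds(lab_b, folds, seed = pseed + 7L)
      run_cv_round(cohort_b, fold_b)$pooled_auc
    }, numeric(1))
  }
  perm_p <- if (n_perm > 0L) (1 + sum(perm_auc >= observed)) / (n_perm + 1)
            else NA_real_

  structure(list(fold_metrics = do.call(rbind, fold_metrics),
                 pooled_auc = pooled, observed_auc = observed,
                 perm_auc = perm_auc, perm_p = perm_p,
                 reps = reps, folds = folds, n_perm = n_perm, seed = seed),
            class = "cv_report")
}

#' Permute the profile assignment of a cohort
#'
#' Shuffles the profile codes across samples (a seeded permutation of
#' the whole profile vector), breaking every association between the
#' measured variables and the risk profiles while preserving profile
#' prevalences. This is the null used by the permutation analysis.
#'
#' @param cohort a `cohort_table`.
#' @param seed integer seed.
#' @return The permuted `cohort_table`.
#' @export
permute_profiles <- function(cohort, seed = 1L) {
  cohort$meta$profile <- with_seed(seed, sample(cohort$meta$profile))
  cohort
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV report: %d x %d-fold, observed pooled AUROC %.3f\n",
              x$reps, x$folds, x$observed_auc))
  if (x$n_perm > 0L) {
    cat(sprintf("  permutation: %d replicates, p = %.4f (floor %.4f)\n",
                x$n_perm, x$perm_p, 1 / (x$n_perm + 1)))
  }
  invisible(x)
}

#' Cross-validation with a fixed, pre-selected variable list (diagnostic)
#'
#' Deliberately leaks information when the variable list was chosen on
#' the full data: this helper exists only to demonstrate selection bias
#' (on null data it inflates the AUROC above chance). The pipeline's
#' cross-validation never takes a pre-selected list.
#'
#' @param cohort a `cohort_table`.
#' @param variables fixed variable list to fit on within every fold.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return Pooled out-of-fold AUROC.
#' @export
cv_with_fixed_variables <- function(cohort, variables, folds = 5L, seed = 1L) {
  labels <- as.numeric(cohort_mets(cohort))
  fold <- stratified_folds(labels, folds, seed)
  scores <- numeric(length(labels))
  for (k in seq_len(folds)) {
    Xtr <- cohort_values(cohort, variables = variables)[fold != k, , drop = FALSE]
    Xte <- cohort_values(cohort, variables = variables)[fold == k, , drop = FALSE]
    m <- fit_oplsda(Xtr, labels[fold != k])
    scores[fold == k] <- opls_project(m, Xte)$t_pred
  }
  roc_auc(scores, labels, ci = FALSE)$auc
}
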