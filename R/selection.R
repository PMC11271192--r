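# Redundancy removal and the variable filtering cascade:
# manual discards -> near-zero-variance filter -> effect/significance
# filter -> one representative per correlation cluster.

#' Hierarchical clustering of variables by Spearman correlation
#'
#' Pairwise distance is `1 - Spearman rho` (signed, so anti-correlated
#' variables are not merged), agglomerated with average linkage; the
#' tree is cut at `cut_height` on the cophenetic scale. Default cut
#' heights are 0.5 for serum variables and 0.85 for urine bins (bins are
#' more strongly cross-correlated). Variables are processed in name
#' order so ties are resolved deterministically.
#'
#' @param X numeric matrix (samples x variables), >= 2 non-constant
#'   columns.
#' @param cut_height dendrogram cut height on the 1 - rho scale.
#' @return Object of class `variable_clusters`: list with `assignment`
#'   (tibble: variable, cluster), `tree` (hclust), `cut_height`.
#' @export
cluster_variables <- function(X, cut_height = 0.5) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 variables to cluster")
  X <- X[, order(colnames(X)), drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "),
         "; apply the near-zero-variance filter first")
  }
  rho <- stats::cor(X, method = "spearman")
  d <- stats::as.dist(1 - rho)
  tree <- stats::hclust(d, method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  structure(list(assignment = tibble::tibble(variable = names(cl),
                                             cluster = unname(cl)),
                 tree = tree, cut_height = cut_height),
            class = "variable_clusters")
}

#' @export
print.variable_clusters <- function(x, ...) {
  cat("Variable clustering: ", nrow(x$assignment), " variables in ",
      length(unique(x$assignment$cluster)), " clusters (cut height ",
      x$cut_height, ")\n", sep = "")
  invisible(x)
}

#' Near-zero-variance diagnostic for one variable
#'
#' A variable is discarded iff the frequency ratio of its most common to
#' second most common value exceeds 19 (i.e. 95/5) AND the fraction of
#' unique values is below 10%. A constant vector has infinite ratio and
#' is discarded.
#'
#' @param values numeric vector.
#' @return List with `keep`, `freq_ratio`, `unique_pct`.
#' @export
near_zero_variance_filter <- function(values) {
  if (length(values) == 0L) stop("empty vector")
  if (anyDuplicated(values) == 0L) {       # all values distinct
    return(list(keep = TRUE, freq_ratio = 1, unique_pct = 100))
  }
  tab <- sort(table(values), decreasing = TRUE)
  freq_ratio <- if (length(tab) == 1L) Inf else tab[[1L]] / tab[[2L]]
  unique_pct <- 100 * length(tab) / length(values)
  list(keep = !(freq_ratio > 19 && unique_pct < 10),
       freq_ratio = freq_ratio, unique_pct = unique_pct)
}

#' Default manual-exclusion patterns
#'
#' Particle-number lipoprotein parameters (Pearson correlation of one
#' with the Apo-B parameters, different units) and the EDTA-related
#' serum signals are excluded before any statistical filtering.
#'
#' @return Character vector of regular expressions.
#' @export
default_exclusion_patterns <- function() {
  c("_PN$", "^Ca-EDTA$", "^K-EDTA$")
}

#' Exclusion patterns for the reduced (definition-independent) model
#'
#' Removes glucose and the HDL/LDL cluster variables that molecularly
#' define diabetes and dyslipidemia, so the rebuilt model relies only on
#' the remaining serum components.
#'
#' @return Character vector of regular expressions.
#' @export
reduced_model_exclusions <- function() {
  c("^Glucose$", "^HDL", "^Total_ApoA", "^LDL4", "^LDL5", "^LDL6",
    "^TG_HDL_ratio$")
}

#' Apply manual exclusion patterns to a variable list
#'
#' @param variables character vector of variable names.
#' @param patterns regular expressions; matching variables are removed.
#'   A pattern matching nothing raises a warning, not an error.
#' @return The kept names.
#' @export
manual_exclusions <- function(variables, patterns = default_exclusion_patterns()) {
  drop <- rep(FALSE, length(variables))
  for (p in patterns) {
    hit <- grepl(p, variables)
    if (!any(hit)) warning("exclusion pattern matched nothing: ", p)
    drop <- drop | hit
  }
  variables[!drop]
}

#' Select cluster representatives among effect-filtered variables
#'
#' Survivors are variables with at least one profile contrast that is
#' both significant (adjusted p below the table's threshold) and of
#' absolute effect size >= `effect_threshold`. Survivors are grouped by
#' cluster and one representative is kept per cluster: the variable with
#' the highest cumulative absolute effect size across all profiles (ties
#' broken by name).
#'
#' @param effects an `effect_table` covering the clustered variables.
#' @param clusters a `variable_clusters` object.
#' @param effect_threshold minimum absolute effect size (default 0.5).
#' @return List with `selected` (representative names), `detail`
#'   (tibble: variable, cluster, cumulative_effect, survivor,
#'   representative).
#' @export
select_variables <- function(effects, clusters, effect_threshold = 0.5) {
  stopifnot(inherits(clusters, "variable_clusters"))
  asn <- clusters$assignment
  eff <- effects[effects$variable %in% asn$variable, , drop = FALSE]
  pass <- eff$significant & abs(eff$effect) >= effect_threshold
  survivors <- unique(eff$variable[pass])
  if (length(survivors) == 0L) {
    stop("empty survivor set after the effect/significance filter; ",
         "review the effect threshold (", effect_threshold,
         ") and significance level")
  }
  cum <- tapply(abs(eff$effect), eff$variable, sum)
  detail <- tibble::tibble(
    variable = asn$variable,
    cluster = asn$cluster,
    cumulative_effect = as.numeric(cum[asn$variable]),
    survivor = asn$variable %in% survivors
  )
  detail <- detail[order(detail$cluster, -detail$cumulative_effect,
                         detail$variable), ]
  reps <- vapply(split(detail[detail$survivor, ], detail$cluster[detail$survivor]),
                 function(d) d$variable[1L], character(1))
  detail$representative <- detail$variable %in% reps
  list(selected = sort(unname(reps)), detail = detail)
}

#' Run the full variable filtering cascade for one dataset type
#'
#' Order is fixed: manual discards, near-zero-variance filter,
#' clustering, univariate effect/significance filter, representative
#' selection. Returns provenance flags that partition the input
#' variables: `kept`, `manual_discard`, `near_zero_variance`,
#' `effect_filtered`, `non_representative`.
#'
#' @param cohort a `cohort_table` (training samples).
#' @param type dataset type to filter.
#' @param effects an `effect_table` from [univariate_effects()] on the
#'   same cohort (subset to `type` internally).
#' @param cut_height dendrogram cut height (serum 0.5, urine 0.85).
#' @param effect_threshold minimum absolute effect size.
#' @param exclusion_patterns manual-exclusion regular expressions.
#' @param fallback_top_k if not NULL and no variable passes the
#'   effect/significance filter, fall back to the `fallback_top_k`
#'   cluster representatives with the highest cumulative absolute
#'   effect instead of erroring. Used by the cross-validation and
#'   permutation machinery, where every replicate must yield a score
#'   even under a null association.
#' @return Object of class `selection_result`: list with `selected`,
#'   `provenance` (tibble: variable, flag), `clusters`, `detail`,
#'   `fallback_used`.
#' @export
filter_variables <- function(cohort, type, effects,
                             cut_height = 0.5,
                             effect_threshold = 0.5,
                             exclusion_patterns = default_exclusion_patterns(),
                             fallback_top_k = NULL) {
  vars <- names(cohort$variable_types)[cohort$variable_types == type]
  if (length(vars) == 0L) stop("no variables of type ", type)
  flag <- stats::setNames(rep(NA_character_, length(vars)), vars)

  kept <- suppressWarnings(manual_exclusions(vars, exclusion_patterns))
  flag[setdiff(vars, kept)] <- "manual_discard"

  V <- cohort_values(cohort, variables = kept)
  nzv_keep <- vapply(kept, function(v) near_zero_variance_filter(V[, v])$keep,
                     logical(1))
  flag[kept[!nzv_keep]] <- "near_zero_variance"
  kept <- kept[nzv_keep]
  if (length(kept) < 2L) stop("fewer than 2 variables of type ", type,
                              " survive the pre-filters")

  clusters <- cluster_variables(V[, kept, drop = FALSE], cut_height)
  eff <- effects[effects$variable %in% kept, , drop = FALSE]
  fallback_used <- FALSE
  survivors <- unique(eff$variable[eff$significant &
                                     abs(eff$effect) >= effect_threshold])
  if (length(survivors) > 0L || is.null(fallback_top_k)) {
    sel <- select_variables(eff, clusters, effect_threshold)
  } else {
    fallback_used <- TRUE
    cum <- tapply(abs(eff$effect), eff$variable, sum)
    asn <- clusters$assignment
    detail <- tibble::tibble(variable = asn$variable, cluster = asn$cluster,
                             cumulative_effect = as.numeric(cum[asn$variable]),
                             survivor = FALSE)
    detail <- detail[order(detail$cluster, -detail$cumulative_effect,
                           detail$variable), ]
    reps <- vapply(split(detail, detail$cluster),
                   function(d) d$variable[1L], character(1))
    top <- detail[detail$variable %in% reps, ]
    top <- top[order(-top$cumulative_effect, top$variable), ]
    keep <- utils::head(top$variable, fallback_top_k)
    detail$representative <- detail$variable %in% keep
    sel <- list(selected = sort(keep), detail = detail)
  }
  flag[setdiff(kept, survivors)] <- "effect_filtered"
  flag[is.na(flag) & !names(flag) %in% sel$selected] <- "non_representative"
  flag[sel$selected] <- "kept"

  structure(list(selected = sel$selected,
                 provenance = tibble::tibble(variable = vars,
                                             flag = unname(flag[vars])),
                 clusters = clusters, detail = sel$detail,
                 fallback_used = fallback_used),
            class = "selection_result")
}
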