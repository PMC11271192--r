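# Univariate profile contrasts: per-variable OLS of the standardized
# variable on the 16-level profile factor (reference 0000), adjusted for
# gender and age group; effects are in SD units. BH-FDR control within
# each dataset-type family.

#' Standardize a variable to mean 0, SD 1
#'
#' Sample SD (n-1 denominator) is used throughout the package.
#'
#' @param values numeric vector with positive variance.
#' @return Standardized numeric vector.
#' @export
standardize_variable <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("zero-variance variable cannot be standardized; ",
         "apply the near-zero-variance filter first")
  }
  (values - mean(values)) / s
}

# Design matrix for the adjusted profile model. Profiles absent from the
# data are dropped (their coefficients are unidentifiable); 0000 must be
# present as the reference level.
profile_design <- function(profiles, gender, age_group) {
  check_profile_code(profiles)
  if (!any(profiles == "0000")) {
    stop("reference profile 0000 absent from the data")
  }
  present <- intersect(all_profiles(), unique(profiles))
  if (length(present) < 2L) stop("need at least 2 profiles including 0000")
  fp <- factor(profiles, levels = present)
  fg <- factor(gender)
  fa <- factor(age_group)
  X <- stats::model.matrix(~ fp + fg + fa)
  colnames(X) <- sub("^fp", "profile_", colnames(X))
  colnames(X) <- sub("^fg", "gender_", colnames(X))
  colnames(X) <- sub("^fa", "age_group_", colnames(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  list(X = X, qr = qrX,
       profile_cols = grep("^profile_", colnames(X)),
       profile_levels = sub("^profile_", "",
                            grep("^profile_", colnames(X), value = TRUE)))
}

# OLS of many standardized responses on one design via a single QR.
ols_many <- function(design, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(design$X)
  coefs <- qr.coef(design$qr, Y)
  res <- Y - design$X %*% coefs
  sigma2 <- colSums(res^2) / (n - p)
  XtX_inv_diag <- diag(chol2inv(qr.R(design$qr)))[order(design$qr$pivot)]
  se <- sqrt(outer(XtX_inv_diag, sigma2))
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  list(coef = coefs, se = se, p = pval, df = n - p)
}

#' Contrast every profile against 0000 for one variable
#'
#' Fits OLS of the standardized variable on the profile factor with
#' 0000 as reference, adjusted for gender and age group. Coefficients
#' are effect sizes in SD units; p-values are classical two-sided
#' t-tests. Profiles absent from the data yield no row.
#'
#' @param values numeric variable (raw scale; standardized internally).
#' @param profiles per-sample profile codes (must include 0000).
#' @param gender,age_group per-sample covariates.
#' @return Tibble with `profile`, `effect`, `se`, `p_raw`.
#' @export
fit_profile_regression <- function(values, profiles, gender, age_group) {
  design <- profile_design(profiles, gender, age_group)
  fit <- ols_many(design, standardize_variable(values))
  tibble::tibble(profile = design$profile_levels,
                 effect = fit$coef[design$profile_cols, 1L],
                 se = fit$se[design$profile_cols, 1L],
                 p_raw = fit$p[design$profile_cols, 1L])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment; in the pipeline it is applied separately within
#' each dataset-type family (serum metabolites, serum lipoproteins,
#' urine bins), pooling all profile contrasts of a family.
#'
#' @param p_raw numeric p-values in [0, 1].
#' @return Adjusted p-values, monotone in the raw values.
#' @export
adjust_fdr <- function(p_raw) {
  if (any(!is.finite(p_raw)) || any(p_raw < 0) || any(p_raw > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' Univariate effect table for a cohort
#'
#' Runs the adjusted profile contrast for every variable (one QR
#' factorization shared across variables), then BH-adjusts p-values
#' within each dataset-type family. Significance is `p_adj <
#' alpha`.
#'
#' @param cohort a `cohort_table`.
#' @param variables optional variable subset.
#' @param alpha significance level on the adjusted scale (default 0.05).
#' @return Object of class `effect_table`: tibble with `variable`,
#'   `type`, `profile`, `effect`, `se`, `p_raw`, `p_adj`, `significant`.
#' @export
univariate_effects <- function(cohort, variables = NULL, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort_table"))
  V <- cohort_values(cohort, variables = variables)
  design <- profile_design(cohort$meta$profile, cohort$meta$gender,
                           cohort$meta$age_group)
  cm <- colMeans(V)
  cs <- sqrt(colSums(sweep(V, 2L, cm)^2) / (nrow(V) - 1L))
  if (any(cs == 0)) {
    stop("zero-variance variable(s): ",
         paste(colnames(V)[cs == 0], collapse = ", "),
         "; apply the near-zero-variance filter first")
  }
  Z <- sweep(sweep(V, 2L, cm), 2L, cs, "/")
  fit <- ols_many(design, Z)
  k <- length(design$profile_cols)
  out <- tibble::tibble(
    variable = rep(colnames(V), each = k),
    type = rep(unname(cohort$variable_types[colnames(V)]), each = k),
    profile = rep(design$profile_levels, times = ncol(V)),
    effect = as.vector(fit$coef[design$profile_cols, , drop = FALSE]),
    se = as.vector(fit$se[design$profile_cols, , drop = FALSE]),
    p_raw = as.vector(fit$p[design$profile_cols, , drop = FALSE])
  )
  out$p_adj <- stats::ave(out$p_raw, out$type, FUN = adjust_fdr)
  out$significant <- out$p_adj < alpha
  class(out) <- c("effect_table", class(out))
  out
}

STAR_BREAKS <- c(0.05, 0.01, 0.001, 0.0001)

significance_stars <- function(p_adj) {
  vapply(p_adj, function(p) {
    if (!is.finite(p)) "" else strrep("*", sum(p < STAR_BREAKS))
  }, character(1))
}

#' Heatmap matrix of profile effects with dendrogram orderings
#'
#' Effects are truncated to [-1, 1] for display; rows (variables) and
#' columns (profiles) are ordered by complete-linkage hierarchical
#' clustering of the untruncated effect matrix under Euclidean distance.
#' Cells carry significance stars at adjusted-p thresholds
#' 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param effects an `effect_table`.
#' @return List with `effects` (ordered, truncated matrix), `stars`
#'   (character matrix), `row_order`, `col_order`, `row_tree`,
#'   `col_tree` (hclust objects, NULL when fewer than 3 rows/columns).
#' @export
heatmap_matrix <- function(effects) {
  stopifnot(inherits(effects, "effect_table") || is.data.frame(effects))
  if (nrow(effects) == 0L) stop("empty effect table")
  vars <- unique(effects$variable)
  profs <- unique(effects$profile)
  E <- matrix(NA_real_, length(vars), length(profs),
              dimnames = list(vars, profs))
  S <- matrix("", length(vars), length(profs), dimnames = list(vars, profs))
  E[cbind(effects$variable, effects$profile)] <- effects$effect
  S[cbind(effects$variable, effects$profile)] <-
    significance_stars(effects$p_adj)
  order_of <- function(M) {
    if (nrow(M) < 3L) return(list(order = seq_len(nrow(M)), tree = NULL))
    tr <- stats::hclust(stats::dist(M), method = "complete")
    list(order = tr$order, tree = tr)
  }
  ro <- order_of(E)
  co <- order_of(t(E))
  list(effects = pmin(pmax(E, -1), 1)[ro$order, co$order, drop = FALSE],
       stars = S[ro$order, co$order, drop = FALSE],
       row_order = vars[ro$order], col_order = profs[co$order],
       row_tree = ro$tree, col_tree = co$tree)
}
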