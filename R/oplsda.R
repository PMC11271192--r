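# Orthogonal partial least squares discriminant analysis, one predictive
# plus n_orth orthogonal components (Trygg-Wold orthogonal signal
# correction). For a single binary response the NIPALS weight step is
# closed form, so the fit is deterministic and iteration-free; the
# orthogonal components capture structured variation uncorrelated with
# the class and are removed before the predictive component is fit.

#' Log-transform and autoscale a raw data matrix
#'
#' Applies `log(x + offset)` per variable followed by centering and
#' unit-SD scaling (sample SD). Offsets default to 0 for strictly
#' positive variables and to half the smallest positive value where
#' zeros occur. When `params` is supplied (a fitted model's
#' preprocessing), its offsets, centers and scales are applied instead,
#' so new samples are mapped into the training space.
#'
#' @param X numeric matrix (samples x variables), values >= 0.
#' @param params optional list with `log_offset`, `center`, `scale`.
#' @return List with `Z` (transformed matrix), `log_offset`, `center`,
#'   `scale`.
#' @export
opls_preprocess <- function(X, params = NULL) {
  X <- as.matrix(X)
  if (any(X < 0)) {
    bad <- colnames(X)[apply(X < 0, 2L, any)]
    stop("negative value(s) in variable(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (concentrations must be nonnegative)")
  }
  if (is.null(params)) {
    log_offset <- apply(X, 2L, function(x) {
      if (all(x > 0)) 0 else if (any(x > 0)) min(x[x > 0]) / 2 else 1
    })
    L <- log(sweep(X, 2L, log_offset, "+"))
    center <- colMeans(L)
    scale <- apply(L, 2L, stats::sd)
    if (any(scale == 0)) {
      stop("zero variance after log transform in: ",
           paste(colnames(X)[scale == 0], collapse = ", "))
    }
  } else {
    log_offset <- params$log_offset
    center <- params$center
    scale <- params$scale
    L <- log(sweep(X, 2L, log_offset, "+"))
  }
  Z <- sweep(sweep(L, 2L, center, "-"), 2L, scale, "/")
  list(Z = Z, log_offset = log_offset, center = center, scale = scale)
}

# One PLS1 weight/score/loading step on a centered response.
pls1_step <- function(Z, yc) {
  w <- drop(crossprod(Z, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("degenerate weight vector: X carries no covariance with y")
  w <- w / nw
  t <- drop(Z %*% w)
  p <- drop(crossprod(Z, t)) / sum(t^2)
  list(w = w, t = t, p = p)
}

#' Fit an O-PLS-DA model
#'
#' Preprocesses the raw matrix (log + autoscale), then for each of the
#' `n_orth` orthogonal components: computes the PLS weight from the
#' centered class variable, takes the part of the X-loading orthogonal
#' to that weight as the orthogonal weight, and deflates X by the
#' resulting orthogonal component. The predictive component is then
#' refit on the filtered matrix. The sign convention makes `t_pred`
#' positively associated with class 1. If no response-orthogonal
#' structured variation exists the orthogonal weight degenerates to
#' zero and the fit reduces exactly to PLS1.
#'
#' @param X raw numeric matrix (samples x variables), nonnegative.
#' @param y binary class labels (0/1, logical, or 2-level factor);
#'   class 1 / TRUE / second level is the positive (MetS) class.
#' @param n_orth number of orthogonal components (default 1).
#' @return Object of class `opls_model`: preprocessing parameters,
#'   `w` (unit-norm predictive weights), `p_load`, `w_orth`, `p_orth`
#'   (p x n_orth matrices), `c` (response loading), `t_pred`, `t_orth`
#'   (training scores), `n_orth`, `variables`.
#' @export
fit_oplsda <- function(X, y, n_orth = 1L) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  if (nrow(X) < n_orth + 3L) stop("too few samples for ", n_orth,
                                  " orthogonal component(s)")
  prep <- opls_preprocess(X)
  Z <- prep$Z
  yc <- y - mean(y)

  p_vars <- ncol(Z)
  w_orth <- matrix(0, p_vars, n_orth)
  p_orth <- matrix(0, p_vars, n_orth)
  t_orth <- matrix(0, nrow(Z), n_orth)
  for (j in seq_len(n_orth)) {
    st <- pls1_step(Z, yc)
    wo <- st$p - drop(crossprod(st$w, st$p)) * st$w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-8) break  # no y-orthogonal structured variation left
    wo <- wo / nwo
    to <- drop(Z %*% wo)
    po <- drop(crossprod(Z, to)) / sum(to^2)
    w_orth[, j] <- wo
    p_orth[, j] <- po
    t_orth[, j] <- to
    Z <- Z - tcrossprod(to, po)
  }
  st <- pls1_step(Z, yc)
  cc <- sum(yc * st$t) / sum(st$t^2)
  sgn <- if (cc < 0) -1 else 1
  model <- structure(list(
    variables = colnames(X),
    log_offset = prep$log_offset, center = prep$center, scale = prep$scale,
    w = sgn * st$w, p_load = sgn * st$p,
    w_orth = w_orth, p_orth = p_orth,
    c = sgn * cc,
    t_pred = sgn * st$t, t_orth = t_orth,
    n_orth = as.integer(n_orth)
  ), class = "opls_model")
  model
}

as_binary_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("y must have exactly 2 levels")
    y <- as.integer(y) - 1L
  } else if (is.logical(y)) {
    y <- as.integer(y)
  }
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  as.numeric(y)
}

#' @export
print.opls_model <- function(x, ...) {
  cat("O-PLS-DA model: ", length(x$variables), " variables, 1 predictive + ",
      x$n_orth, " orthogonal component(s)\n", sep = "")
  cat("  training samples: ", length(x$t_pred), "\n", sep = "")
  if (!is.null(x$calibration)) cat("  calibrated MetSCORE attached\n")
  invisible(x)
}

#' Project new samples through a fitted O-PLS-DA model
#'
#' Applies the stored preprocessing, strips the orthogonal variation
#' with the stored orthogonal weights/loadings, and scores the filtered
#' rows on the predictive weights.
#'
#' @param model an `opls_model`.
#' @param X_new raw numeric matrix containing the model's variables.
#' @return Tibble with `t_pred` and `t_orth_<j>` columns.
#' @export
opls_project <- function(model, X_new) {
  stopifnot(inherits(model, "opls_model"))
  X_new <- as.matrix(X_new)
  miss <- setdiff(model$variables, colnames(X_new))
  if (length(miss)) {
    stop("missing model variable(s): ", paste(miss, collapse = ", "))
  }
  X_new <- X_new[, model$variables, drop = FALSE]
  Z <- opls_preprocess(X_new, params = model)$Z
  t_orth <- matrix(0, nrow(Z), model$n_orth)
  for (j in seq_len(model$n_orth)) {
    to <- drop(Z %*% model$w_orth[, j])
    if (sum(model$w_orth[, j]^2) > 0) {
      Z <- Z - tcrossprod(to, model$p_orth[, j])
      t_orth[, j] <- to
    }
  }
  out <- tibble::tibble(t_pred = unname(drop(Z %*% model$w)))
  for (j in seq_len(model$n_orth)) {
    out[[paste0("t_orth_", j)]] <- unname(t_orth[, j])
  }
  out
}

#' Signed variable influence of a fitted model
#'
#' Influence is the predictive loading: its magnitude ranks the
#' variables' contribution to the discriminant axis, its sign says
#' whether the variable is elevated (positive) or depleted (negative)
#' in the positive class.
#'
#' @param model an `opls_model`.
#' @return Tibble with `variable`, `influence`, sorted by decreasing
#'   magnitude.
#' @export
variable_influence <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  out <- tibble::tibble(variable = model$variables,
                        influence = model$p_load)
  out[order(-abs(out$influence)), ]
}
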