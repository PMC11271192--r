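# Self-organizing map of individuals: batch Kohonen training on a
# rectangular grid with a Gaussian neighborhood, Ward.D2 grouping of the
# codebook vectors into k cell groups, and per-cell summaries.

#' Default SOM grid dimensions for n samples
#'
#' The usual heuristic of about `5 * sqrt(n)` cells, in a near-square
#' rectangular grid.
#'
#' @param n number of samples.
#' @return Integer vector `c(rows, cols)`.
#' @export
som_grid_dims <- function(n) {
  cells <- max(4, ceiling(5 * sqrt(n)))
  rows <- max(2L, floor(sqrt(cells)))
  cols <- as.integer(ceiling(cells / rows))
  c(rows = as.integer(rows), cols = cols)
}

#' Fit a self-organizing map by batch training
#'
#' Codebook vectors sit on a rectangular `rows x cols` grid. Each epoch
#' assigns every sample to its best-matching unit (BMU, Euclidean
#' distance) and replaces each codebook vector by the
#' neighborhood-weighted mean of the samples, with a Gaussian
#' neighborhood whose radius decays linearly from `radius[1]` to
#' `radius[2]` over the epochs. Initial codebooks are a seeded random
#' sample of the data rows. With a fixed, vanishing radius the batch
#' update is the Lloyd step, so the quantization error is
#' non-increasing.
#'
#' @param X numeric matrix (samples x variables), typically standardized
#'   with the same autoscaling as the discriminant model.
#' @param rows,cols grid dimensions (defaults from [som_grid_dims()]).
#' @param epochs training epochs.
#' @param radius length-2 numeric: initial and final neighborhood radius
#'   (grid units); default decays from a third of the grid diagonal
#'   to 0.3.
#' @param seed integer seed.
#' @return Object of class `som_grid`: list with `codebook`
#'   (cells x variables), `grid` (tibble: cell, row, col), `bmu`
#'   (per-sample cell index), `qe_history` (per-epoch mean
#'   sample-to-BMU distance), `rows`, `cols`.
#' @export
fit_som <- function(X, rows = NULL, cols = NULL, epochs = 20L,
                    radius = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty data matrix")
  if (is.null(rows) || is.null(cols)) {
    d <- som_grid_dims(nrow(X))
    rows <- rows %||% d[["rows"]]; cols <- cols %||% d[["cols"]]
  }
  n_cells <- rows * cols
  if (nrow(X) < n_cells) {
    stop("need at least as many samples (", nrow(X), ") as cells (",
         n_cells, ")")
  }
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  grid <- tibble::tibble(cell = seq_len(n_cells),
                         row = grid$row, col = grid$col)
  gd2 <- as.matrix(stats::dist(cbind(grid$row, grid$col)))^2
  if (is.null(radius)) radius <- c(sqrt(rows^2 + cols^2) / 3, 0.3)

  codebook <- X[with_seed(seed, sample.int(nrow(X), n_cells)), , drop = FALSE]
  rownames(codebook) <- NULL
  bmu <- integer(nrow(X))
  qe <- numeric(epochs)
  radii <- seq(radius[1L], radius[2L], length.out = epochs)
  for (ep in seq_len(epochs)) {
    # BMU assignment via full distance matrix
    d2 <- outer(rowSums(X^2), rowSums(codebook^2), "+") -
      2 * X %*% t(codebook)
    bmu <- max.col(-d2, ties.method = "first")
    qe[ep] <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(X)), bmu)], 0)))
    h <- exp(-gd2 / (2 * radii[ep]^2))          # cells x cells
    W <- h[, bmu, drop = FALSE]                  # cells x samples
    denom <- rowSums(W)
    upd <- (W %*% X) / denom
    nonempty <- denom > 1e-12
    codebook[nonempty, ] <- upd[nonempty, , drop = FALSE]
  }
  structure(list(codebook = codebook, grid = grid, bmu = bmu,
                 qe_history = qe, rows = rows, cols = cols,
                 radius = radius, epochs = epochs, seed = seed),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("SOM: ", x$rows, " x ", x$cols, " grid, ", length(x$bmu),
      " samples, final quantization error ",
      sprintf("%.4f", x$qe_history[length(x$qe_history)]), "\n", sep = "")
  invisible(x)
}

#' Group SOM cells by Ward clustering of the codebook vectors
#'
#' Hierarchical agglomeration of the codebook vectors with Euclidean
#' distance and Ward.D2 linkage, cut into exactly `k` groups.
#'
#' @param som a `som_grid`.
#' @param k number of cell groups (default 6).
#' @return Integer vector of group ids (one per cell).
#' @export
group_cells <- function(som, k = 6L) {
  stopifnot(inherits(som, "som_grid"))
  if (k > nrow(som$codebook)) {
    stop("k (", k, ") exceeds the number of cells (", nrow(som$codebook), ")")
  }
  tr <- stats::hclust(stats::dist(som$codebook), method = "ward.D2")
  stats::cutree(tr, k = k)
}

#' Per-cell sample counts, MetS fractions and mean scores
#'
#' @param som a `som_grid`.
#' @param labels per-sample binary MetS labels.
#' @param scores per-sample scores (e.g. MetSCORE).
#' @param groups optional per-cell group ids from [group_cells()].
#' @return Tibble with `cell`, `row`, `col`, `group`, `n`,
#'   `mets_fraction`, `mean_score`, `empty`.
#' @export
cell_statistics <- function(som, labels, scores, groups = NULL) {
  stopifnot(inherits(som, "som_grid"))
  labels <- as_binary_labels(labels)
  stopifnot(length(labels) == length(som$bmu),
            length(scores) == length(som$bmu))
  cells <- som$grid
  agg <- function(f) vapply(cells$cell, function(cl) {
    i <- som$bmu == cl
    if (any(i)) f(i) else NA_real_
  }, numeric(1))
  out <- tibble::tibble(
    cell = cells$cell, row = cells$row, col = cells$col,
    group = if (is.null(groups)) NA_integer_ else as.integer(groups),
    n = vapply(cells$cell, function(cl) sum(som$bmu == cl), integer(1)),
    mets_fraction = agg(function(i) mean(labels[i])),
    mean_score = agg(function(i) mean(scores[i]))
  )
  out$empty <- out$n == 0L
  out
}
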