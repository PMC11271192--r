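# Rank-1 positive matrix whose log-autoscaled form stays rank one, so
# no response-orthogonal structured variation exists.
rank1_data <- function(n = 60, p = 5, seed = 1) {
  set.seed(seed)
  u <- rnorm(n)
  a <- runif(p, 0.5, 2) * sample(c(-1, 1), p, TRUE)
  X <- exp(0.1 * outer(u, a))
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, y = as.integer(u > stats::median(u)))
}

test_that("preprocessing centers, scales, and reproduces training data from stored params", {
  set.seed(2)
  X <- matrix(rexp(200, 0.2), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  pp <- opls_preprocess(X)
  expect_equal(unname(colMeans(pp$Z)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(pp$Z, 2, sd)), rep(1, 4), tolerance = 1e-10)
  # stored params reproduce the training matrix
  pp2 <- opls_preprocess(X, params = pp)
  expect_equal(pp2$Z, pp$Z, tolerance = 1e-12)
  # a sample at the training mean (log space) maps to zero
  x0 <- matrix(exp(pp$center), 1, 4, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(opls_preprocess(x0, params = pp)$Z[1, ]), rep(0, 4),
               tolerance = 1e-10)
  expect_error(opls_preprocess(matrix(c(-1, 2), 1, 2)), "nonnegative")
})

test_that("unit rescaling of a raw variable is absorbed by log + centering", {
  set.seed(3)
  X <- matrix(rexp(300, 0.1), 100, 3, dimnames = list(NULL, paste0("v", 1:3)))
  X2 <- X
  X2[, 2] <- X2[, 2] * 1000  # mg/dL -> another unit
  expect_equal(opls_preprocess(X)$Z, opls_preprocess(X2)$Z,
               tolerance = 1e-10)
})

test_that("zeros get a half-minimum offset and zero-variance columns error", {
  X <- cbind(a = c(0, 1, 2, 4), b = c(3, 4, 5, 6))
  pp <- opls_preprocess(X)
  expect_equal(unname(pp$log_offset), c(0.5, 0))
  Xc <- cbind(a = rep(2, 5), b = 1:5)
  expect_error(opls_preprocess(Xc), "zero variance")
})

test_that("a single separating variable gives training AUROC 1", {
  X <- matrix(seq(1, 5, length.out = 40), 40, 1,
              dimnames = list(NULL, "v1"))
  y <- as.integer(seq_len(40) > 20)
  m <- fit_oplsda(X, y)
  expect_equal(roc_auc(m$t_pred, y, ci = FALSE)$auc, 1.0)
})

test_that("with no orthogonal structure the fit reduces to the PLS1 oracle", {
  d <- rank1_data()
  m <- fit_oplsda(d$X, d$y)
  Z <- oracle_log_autoscale(d$X)
  t_oracle <- oracle_pls1_scores(Z, d$y)
  if (cor(t_oracle, m$t_pred) < 0) t_oracle <- -t_oracle
  expect_lt(max(abs(m$t_pred - t_oracle)), 1e-6)
  # the degenerate orthogonal component stays zero
  expect_equal(max(abs(m$w_orth)), 0)
})

test_that("model invariants: unit weights, orthogonality, positive class direction", {
  co <- tiny_cohort(n = 200, seed = 7)
  y <- as.integer(cohort_mets(co))
  m <- fit_oplsda(co$values, y)
  expect_equal(sum(m$w^2), 1, tolerance = 1e-9)
  expect_lt(abs(sum(m$w * m$w_orth[, 1])), 1e-6)
  expect_lt(abs(cor(m$t_pred, m$t_orth[, 1])), 1e-6)
  expect_gt(cor(m$t_pred, y), 0)
  expect_gt(m$c, 0)
})

test_that("an injected class-independent factor is absorbed by the orthogonal component", {
  set.seed(11)
  n <- 150
  y <- rep(c(0L, 1L), each = n / 2)
  # independent noise per variable: the only structured y-orthogonal
  # variation is the injected factor
  Xc <- sapply(1:5, function(i) 1.5 * y + rnorm(n))
  colnames(Xc) <- paste0("sig", 1:5)
  f <- rnorm(n) * 3            # strong structured factor, independent of y
  Xn <- cbind(Xc, junk = f + rnorm(n) * 0.05)
  Xc_raw <- exp(0.2 * Xc); Xn_raw <- exp(0.2 * Xn)
  m_clean <- fit_oplsda(Xc_raw, y)
  m_noise <- fit_oplsda(Xn_raw, y)
  # orthogonal loading peaks on the injected variable
  expect_equal(which.max(abs(m_noise$p_orth[, 1])), 6L)
  # predictive score barely perturbed
  expect_gt(cor(m_clean$t_pred, m_noise$t_pred), 0.99)
})

test_that("projection round-trips training scores and handles duplicates and missing variables", {
  co <- tiny_cohort(n = 120, seed = 8)
  y <- as.integer(cohort_mets(co))
  m <- fit_oplsda(co$values, y)
  pr <- opls_project(m, co$values)
  expect_equal(pr$t_pred, unname(m$t_pred), tolerance = 1e-9)
  expect_equal(pr$t_orth_1, unname(m$t_orth[, 1]), tolerance = 1e-9)
  dup <- co$values[c(1, 1), , drop = FALSE]
  prd <- opls_project(m, dup)
  expect_equal(prd$t_pred[1], prd$t_pred[2])
  expect_error(opls_project(m, co$values[, -1, drop = FALSE]),
               colnames(co$values)[1])
})

test_that("projection generalizes: held-out AUROC close to training AUROC", {
  co <- tiny_cohort(n = 400, shift = 1.5, seed = 9)
  y <- as.integer(cohort_mets(co))
  idx <- seq_len(200)
  m <- fit_oplsda(co$values[idx, ], y[idx])
  auc_tr <- roc_auc(m$t_pred, y[idx], ci = FALSE)$auc
  auc_te <- roc_auc(opls_project(m, co$values[-idx, ])$t_pred, y[-idx],
                    ci = FALSE)$auc
  expect_lt(abs(auc_tr - auc_te), 0.05)
})

test_that("variable influence ranks informative variables first with correct signs", {
  set.seed(12)
  n <- 300
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(A = rnorm(n) + 1.0 * y,
             B = rnorm(n) - 0.5 * y,
             C = rnorm(n))
  m <- fit_oplsda(exp(0.3 * X), y)
  vi <- variable_influence(m)
  expect_equal(vi$variable[1], "A")
  expect_gt(vi$influence[vi$variable == "A"], 0)
  expect_lt(vi$influence[vi$variable == "B"], 0)
  expect_gt(abs(vi$influence[vi$variable == "A"]),
            abs(vi$influence[vi$variable == "B"]))
  # exactly symmetric construction (duplicated column): equal magnitudes
  xa <- rnorm(n) + y
  ms <- fit_oplsda(exp(0.3 * cbind(A = xa, B = xa)), y)
  infl <- variable_influence(ms)
  expect_lt(abs(abs(infl$influence[1]) - abs(infl$influence[2])), 1e-6)
})

test_that("label flip reverses the sign of t_pred", {
  co <- tiny_cohort(n = 150, seed = 10)
  y <- as.integer(cohort_mets(co))
  m1 <- fit_oplsda(co$values, y)
  m2 <- fit_oplsda(co$values, 1L - y)
  expect_lt(max(abs(m1$t_pred + m2$t_pred)), 1e-9)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rexp(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_oplsda(X, rep(1L, 20)), "both classes")
  expect_error(fit_oplsda(X[1:3, ], c(0L, 1L, 0L)), "too few")
})

test_that("permutation null: test AUROC hovers around chance", {
  co <- tiny_cohort(n = 240, shift = 2, seed = 13)
  y <- as.integer(cohort_mets(co))
  idx <- seq_len(120)
  set.seed(14)
  aucs <- replicate(50, {
    yp <- sample(y[idx])
    if (length(unique(yp)) < 2) return(NA_real_)
    m <- fit_oplsda(co$values[idx, ], yp)
    roc_auc(opls_project(m, co$values[-idx, ])$t_pred, y[-idx],
            ci = FALSE)$auc
  })
  expect_gt(stats::median(aucs, na.rm = TRUE), 0.4)
  expect_lt(stats::median(aucs, na.rm = TRUE), 0.6)
})

test_that("model JSON round-trips scores and calibration", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(n = 150, seed = 15)
  y <- as.integer(cohort_mets(co))
  m <- fit_oplsda(co$values, y)
  yt <- youden_threshold(m$t_pred, y)
  m$calibration <- calibrate_metscore(m$t_pred, y, yt$threshold)
  path <- file.path(dir, "model.json")
  write_opls_model(m, path)
  m2 <- read_opls_model(path)
  expect_equal(opls_project(m2, co$values)$t_pred, unname(m$t_pred),
               tolerance = 1e-9)
  expect_equal(m2$calibration$metscore(yt$threshold), 0.5, tolerance = 1e-9)
  sc <- score_samples(path, co)
  expect_equal(nrow(sc), 150L)
  expect_true(all(sc$metscore > 0 & sc$metscore < 1))
})
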