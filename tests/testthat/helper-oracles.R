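# Independent oracles, deliberately written as plain brute force or
# closed form, sharing no code with the package implementations.

# AUROC by exhaustive pair counting (ties count one half).
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up from its definition: p_(i) * m / i, then
# enforce monotonicity by cumulative minimum from the largest p down.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Youden threshold by exhaustive grid over all midpoints and sentinels,
# scanning linearly; smallest maximizing threshold wins.
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
            s[length(s)] + 1)
  best_j <- -Inf; best_t <- NA
  for (th in cand) {
    sens <- mean(scores[labels == 1] > th)
    spec <- mean(scores[labels == 0] <= th)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- th }
  }
  list(threshold = best_t, youden = best_j)
}

# Plain NIPALS PLS1 first component on an already-centered/scaled
# matrix: w = X'y / ||X'y||, t = X w.
oracle_pls1_scores <- function(Z, y) {
  yc <- y - mean(y)
  w <- as.vector(crossprod(Z, yc))
  w <- w / sqrt(sum(w^2))
  as.vector(Z %*% w)
}

# Manual log + autoscale (base R), independent of opls_preprocess.
oracle_log_autoscale <- function(X) {
  scale(log(X))
}

# A small fully-controlled cohort: k informative variables shifted for
# the WHO-MetS profiles, plus noise variables; balanced enough for
# stratified folds.
tiny_cohort <- function(n = 300, k_inf = 4, k_noise = 6, shift = 2,
                        mets_frac = 0.15, seed = 42) {
  set.seed(seed)
  n_mets <- round(mets_frac * n)
  profile <- c(sample(c("1011", "1101", "1110", "1111"), n_mets, TRUE),
               sample(c("0000", "0001", "0010", "0100"), n - n_mets, TRUE))
  profile <- sample(profile)
  y <- classify_mets(profile)
  p <- k_inf + k_noise
  V <- matrix(stats::rnorm(n * p), n, p)
  V[, seq_len(k_inf)] <- V[, seq_len(k_inf)] + shift * y
  V <- V + 10  # keep values positive for the log transform
  colnames(V) <- sprintf("var%02d", seq_len(p))
  rownames(V) <- sprintf("S%04d", seq_len(n))
  age <- runif(n, 20, 80)
  cohort_table(
    meta = tibble::tibble(sample_id = rownames(V),
                          gender = sample(c("female", "male"), n, TRUE),
                          age = age,
                          age_group = as.character(assign_age_group(age)),
                          profile = profile),
    values = V,
    variable_types = stats::setNames(
      rep(c("serum_metabolite", "serum_lipoprotein"), c(k_inf, k_noise))[seq_len(p)],
      colnames(V))
  )
}

# Adjusted Rand index between two labelings (contingency formula).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  (nij - expected) / ((ai + bj) / 2 - expected)
}
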