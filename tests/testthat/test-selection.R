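test_that("perfectly correlated variables merge; independent ones do not", {
  set.seed(1)
  n <- 5000
  x <- rnorm(n)
  X <- cbind(a = x, b = 2 * x + 5, c = rnorm(n), d = rnorm(n))
  cl <- cluster_variables(X, cut_height = 0.5)
  asn <- setNames(cl$assignment$cluster, cl$assignment$variable)
  expect_equal(asn[["a"]], asn[["b"]])
  expect_length(unique(asn[c("c", "d")]), 2L)
  expect_false(asn[["c"]] %in% asn[c("a", "b")])
})

test_that("clustering is invariant to monotone transforms (Spearman)", {
  set.seed(2)
  n <- 800
  z <- rnorm(n)
  X <- cbind(a = z + 0.2 * rnorm(n), b = z + 0.2 * rnorm(n),
             c = rnorm(n))
  X2 <- cbind(a = exp(X[, "a"]), b = X[, "b"]^3, c = X[, "c"])
  cl1 <- cluster_variables(X, 0.5)$assignment
  cl2 <- cluster_variables(X2, 0.5)$assignment
  expect_equal(oracle_ari(cl1$cluster, cl2$cluster), 1)
})

test_that("generator blocks are recovered exactly at the serum cut height", {
  cfg <- default_generator_config(5000, seed = 21)
  co <- generate_cohort(cfg)
  cl <- cluster_variables(cohort_values(co), 0.5)
  bm <- generator_block_map(cfg)
  truth <- bm$block[match(cl$assignment$variable, bm$variable)]
  expect_equal(oracle_ari(cl$assignment$cluster, truth), 1)
})

test_that("constant variables are rejected with a pointer to the NZV filter", {
  X <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(cluster_variables(X), "near-zero-variance")
  expect_error(cluster_variables(X[, 1, drop = FALSE]), "at least 2")
})

test_that("near-zero-variance rule follows the 19 ratio and 10% unique thresholds", {
  r <- near_zero_variance_filter(rep(c(0, 1), c(97, 3)))
  expect_false(r$keep)
  expect_equal(r$freq_ratio, 97 / 3, tolerance = 1e-12)
  expect_equal(r$unique_pct, 2)
  # exactly 19 is not > 19: keep
  r2 <- near_zero_variance_filter(rep(c(0, 1), c(95, 5)))
  expect_true(r2$keep)
  expect_equal(r2$freq_ratio, 19)
  # all distinct: keep regardless of ratio
  expect_true(near_zero_variance_filter(1:100)$keep)
  # constant: infinite ratio, discard
  r3 <- near_zero_variance_filter(rep(7, 50))
  expect_false(r3$keep)
  expect_equal(r3$freq_ratio, Inf)
  expect_error(near_zero_variance_filter(numeric(0)), "empty")
})

test_that("near-zero-variance rule agrees with the caret reference on random cases", {
  skip_if_not_installed("caret")
  set.seed(3)
  for (i in 1:40) {
    k <- sample(1:6, 1)
    probs <- c(0.9, runif(k))
    x <- sample(0:k, 120, TRUE, prob = probs / sum(probs))
    mine <- near_zero_variance_filter(x)$keep
    caret_drop <- length(caret::nearZeroVar(data.frame(x = x))) > 0
    expect_equal(mine, !caret_drop)
  }
})

test_that("manual exclusions drop configured patterns and warn on dead patterns", {
  expect_equal(suppressWarnings(
    manual_exclusions(c("Glucose", "Ca-EDTA", "Alanine"))),
    c("Glucose", "Alanine"))
  expect_equal(suppressWarnings(
    manual_exclusions(c("VLDL_PN", "VLDL1_TG", "K-EDTA"))),
    "VLDL1_TG")
  expect_equal(manual_exclusions(c("a", "b"), character(0)), c("a", "b"))
  expect_warning(manual_exclusions(c("Glucose"), "^Zebra$"), "matched nothing")
})

test_that("the reduced-model exclusions remove glucose and the HDL/LDL clusters", {
  sel <- c("Glucose", "HDL1_PL", "HDL4_PL", "LDL4_FC", "LDL6_FC",
           "VLDL1_CH", "Proline", "Sarcosine")
  kept <- suppressWarnings(
    manual_exclusions(sel, c(default_exclusion_patterns(),
                             reduced_model_exclusions())))
  expect_setequal(kept, c("VLDL1_CH", "Proline", "Sarcosine"))
})

test_that("representative selection needs significance AND effect size, argmax by cumulative effect", {
  eff <- tibble::tibble(
    variable = rep(c("A", "B", "C", "D"), each = 2),
    type = "serum_metabolite",
    profile = rep(c("0010", "1111"), 4),
    effect = c(1.6, 1.6, 1.0, 1.1, 0.4, 0.4, 0.8, 0.8),
    se = 0.1, p_raw = 0.001,
    p_adj = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.2, 0.2),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  # A and B in one cluster; C and D singletons
  clusters <- structure(list(
    assignment = tibble::tibble(variable = c("A", "B", "C", "D"),
                                cluster = c(1L, 1L, 2L, 3L)),
    tree = NULL, cut_height = 0.5), class = "variable_clusters")
  sel <- select_variables(eff, clusters)
  # A wins its cluster (cumulative 3.2 > 2.1); C fails |effect| >= 0.5;
  # D fails significance despite |effect| = 0.8
  expect_equal(sel$selected, "A")
  det <- sel$detail
  expect_true(det$representative[det$variable == "A"])
  expect_false(any(det$survivor[det$variable %in% c("C", "D")]))
  # empty survivor set errors with advice
  eff0 <- eff; eff0$significant <- FALSE
  expect_error(select_variables(eff0, clusters), "survivor")
})

test_that("filter cascade provenance flags partition all variables", {
  co <- generate_cohort(default_generator_config(1500, seed = 13))
  eff <- univariate_effects(co)
  for (tp in c("serum_metabolite", "serum_lipoprotein")) {
    res <- filter_variables(co, tp, eff)
    expect_equal(sort(res$provenance$variable),
                 sort(names(co$variable_types)[co$variable_types == tp]))
    expect_false(any(is.na(res$provenance$flag)))
    expect_true(all(res$provenance$flag %in%
                      c("kept", "manual_discard", "near_zero_variance",
                        "effect_filtered", "non_representative")))
    expect_setequal(res$selected,
                    res$provenance$variable[res$provenance$flag == "kept"])
    # manual discards really are the configured patterns
    md <- res$provenance$variable[res$provenance$flag == "manual_discard"]
    if (tp == "serum_lipoprotein") expect_true(all(grepl("_PN$", md)))
    if (tp == "serum_metabolite") expect_setequal(md, c("Ca-EDTA", "K-EDTA"))
  }
})

test_that("an informative block's representative comes from that block", {
  # one informative block among noise: representative must be a member
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 400
    profile <- sample(c("0000", "1111"), n, TRUE, c(0.7, 0.3))
    z <- rnorm(n)
    inf <- sapply(1:4, function(i) z * 0.9 + rnorm(n) * sqrt(1 - 0.81) +
                    1.2 * (profile == "1111"))
    noise <- matrix(rnorm(n * 6), n, 6)
    V <- cbind(inf, noise) + 20
    colnames(V) <- c(paste0("inf", 1:4), paste0("noise", 1:6))
    rownames(V) <- sprintf("S%04d", 1:n)
    age <- runif(n, 20, 80)
    co <- cohort_table(
      tibble::tibble(sample_id = rownames(V),
                     gender = sample(c("female", "male"), n, TRUE),
                     age = age,
                     age_group = as.character(assign_age_group(age)),
                     profile = profile),
      V, setNames(rep("serum_metabolite", 10), colnames(V)))
    eff <- univariate_effects(co)
    res <- filter_variables(co, "serum_metabolite", eff,
                            exclusion_patterns = character(0))
    if (any(grepl("^inf", res$selected))) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
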