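test_that("train/test split partitions ids at the requested sizes, seeded", {
  ids <- sprintf("s%02d", 1:10)
  sp <- train_test_split(ids, 0.8, seed = 1)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, train_test_split(ids, 0.8, seed = 1))
  expect_false(identical(sp, train_test_split(ids, 0.8, seed = 2)))
  expect_error(train_test_split(ids[1:4]), "at least 5")
  expect_error(train_test_split(ids, 1.2), "fraction")
})

test_that("AUROC matches hand values and the brute-force pair-counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), ci = FALSE)$auc, 1.0)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1), ci = FALSE)$auc, 0.75)
  # one tied positive-negative pair contributes half
  expect_equal(roc_auc(c(1, 2, 2, 4), c(0, 0, 1, 1), ci = FALSE)$auc, 0.875)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(20)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq_len(n %/% 2), n, TRUE)  # force ties
    expect_identical(roc_auc(scores, labels, ci = FALSE)$auc,
                     oracle_auc_pairs(scores, labels))
  }
})

test_that("AUROC is antisymmetric under label flip and DeLong CI brackets the estimate", {
  set.seed(21)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(s))
  a <- roc_auc(s, y)
  b <- roc_auc(s, 1 - y, ci = FALSE)
  expect_equal(a$auc + b$auc, 1, tolerance = 1e-12)
  expect_lt(a$ci_lower, a$auc)
  expect_gt(a$ci_upper, a$auc)
})

test_that("Youden threshold matches the exhaustive sweep oracle with smallest-threshold ties", {
  yt <- youden_threshold(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(yt$youden, 0.5)
  expect_gt(yt$threshold, 1)
  expect_lte(yt$threshold, 2)
  # perfectly separated: J = 1, threshold between the classes
  yp <- youden_threshold(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(yp$youden, 1)
  expect_gt(yp$threshold, 2); expect_lt(yp$threshold, 8)
  expect_equal(yp$sensitivity, 1); expect_equal(yp$specificity, 1)
  set.seed(22)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq_len(max(2, n %/% 2)), n, TRUE)
    mine <- youden_threshold(scores, labels)
    orac <- oracle_youden(scores, labels)
    expect_equal(mine$youden, orac$youden, tolerance = 1e-12)
    expect_equal(mine$threshold, orac$threshold)
  }
})

test_that("null scores give a Youden index near zero", {
  set.seed(23)
  yt <- youden_threshold(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_lt(yt$youden, 0.1)
})

test_that("MetSCORE calibration centers at the threshold and maps to (0,1) monotonically", {
  set.seed(24)
  t_pred <- c(rnorm(300, 0), rnorm(100, 2))
  labels <- rep(c(0, 1), c(300, 100))
  th <- youden_threshold(t_pred, labels)$threshold
  cal <- calibrate_metscore(t_pred, labels, th)
  expect_equal(cal$metscore(th), 0.5, tolerance = 1e-9)
  expect_gt(cal$slope, 0)
  # strictly increasing within the representable range of the sigmoid
  grid <- th + seq(-20, 20, length.out = 2001) / cal$slope
  v <- cal$metscore(grid)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 1))
  expect_equal(cal$metscore(1e6), 1, tolerance = 1e-6)
  expect_equal(cal$metscore(-1e6), 0, tolerance = 1e-6)
})

test_that("a symmetric balanced problem needs almost no recentering", {
  set.seed(25)
  t_pred <- c(rnorm(500, -1), rnorm(500, 1))
  labels <- rep(c(0, 1), each = 500)
  th <- youden_threshold(t_pred, labels)$threshold
  cal <- calibrate_metscore(t_pred, labels, th)
  # compare score at threshold with and without the exact recentering
  uncentered <- stats::plogis(cal$intercept - cal$recentering +
                                cal$slope * th)
  expect_lt(abs(uncentered - 0.5), 0.1)
})

test_that("anti-predictive scores are rejected", {
  set.seed(26)
  t_pred <- rnorm(200)
  labels <- as.integer(t_pred < 0)  # negatively associated
  expect_error(calibrate_metscore(t_pred, labels, 0), "not positive")
})

test_that("per-factor evaluation isolates the driving factor", {
  set.seed(27)
  n <- 4000
  bits <- matrix(rbinom(n * 4, 1, 0.3), n, 4)
  profiles <- encode_profile(bits[, 1], bits[, 2], bits[, 3], bits[, 4])
  score <- bits[, 1] + rnorm(n, sd = 0.01)
  ev <- evaluate_against_factor(score, profiles)
  expect_gt(ev$auc[ev$factor == "diabetes"], 0.99)
  others <- ev$auc[ev$factor != "diabetes"]
  expect_true(all(others > 0.45 & others < 0.55))
  # independent score: everything near chance
  ev0 <- evaluate_against_factor(rnorm(n), profiles)
  expect_true(all(ev0$auc > 0.45 & ev0$auc < 0.55))
  # constant factor skipped with warning
  prof_const <- encode_profile(rep(0, 50), rbinom(50, 1, 0.5),
                               rbinom(50, 1, 0.5), rbinom(50, 1, 0.5))
  expect_warning(ev2 <- evaluate_against_factor(rnorm(50), prof_const),
                 "diabetes")
  expect_false("diabetes" %in% ev2$factor)
})

test_that("a generator cohort ranks diabetes as the best-identified factor", {
  co <- generate_cohort(default_generator_config(3000, seed = 31))
  m <- fit_mets_model(co)
  sc <- predict_mets(m, co)
  ev <- evaluate_against_factor(sc$metscore, co$meta$profile)
  expect_equal(ev$factor[which.max(ev$auc)], "diabetes")
})

test_that("repeated CV is seeded, leak-free by construction, and permutation p has the add-one floor", {
  co <- tiny_cohort(n = 250, shift = 2.5, mets_frac = 0.2, seed = 33)
  cfg <- pipeline_config(exclusion_patterns = character(0))
  cv1 <- repeated_cv_permutation(co, config = cfg, reps = 2, folds = 4,
                                 n_perm = 9, seed = 5)
  cv2 <- repeated_cv_permutation(co, config = cfg, reps = 2, folds = 4,
                                 n_perm = 9, seed = 5)
  expect_identical(cv1$fold_metrics, cv2$fold_metrics)
  expect_identical(cv1$perm_auc, cv2$perm_auc)
  expect_gt(cv1$observed_auc, 0.9)
  expect_equal(cv1$perm_p, 1 / 10)          # floor with 9 permutations
  expect_gte(cv1$perm_p, 1 / (cv1$n_perm + 1))
  expect_true(all(cv1$fold_metrics$auc >= 0 & cv1$fold_metrics$auc <= 1))
})

test_that("a permuted cohort yields chance-level CV performance", {
  co <- tiny_cohort(n = 250, shift = 2.5, mets_frac = 0.2, seed = 34)
  co_null <- permute_profiles(co, seed = 99)
  cfg <- pipeline_config(exclusion_patterns = character(0))
  cv <- repeated_cv_permutation(co_null, config = cfg, reps = 2, folds = 4,
                                n_perm = 0, seed = 6)
  expect_gt(cv$observed_auc, 0.35)
  expect_lt(cv$observed_auc, 0.65)
})

test_that("selecting variables on the full data then cross-validating inflates null AUROC", {
  # null cohort: many noise variables, labels independent of X
  set.seed(35)
  n <- 160; p <- 200
  V <- matrix(rnorm(n * p), n, p) + 10
  colnames(V) <- sprintf("v%03d", seq_len(p))
  rownames(V) <- sprintf("S%04d", seq_len(n))
  profile <- sample(c("0000", "1111"), n, TRUE, c(0.7, 0.3))
  age <- runif(n, 20, 80)
  co <- cohort_table(
    tibble::tibble(sample_id = rownames(V),
                   gender = sample(c("female", "male"), n, TRUE),
                   age = age, age_group = as.character(assign_age_group(age)),
                   profile = profile),
    V, setNames(rep("serum_metabolite", p), colnames(V)))
  y <- as.numeric(cohort_mets(co))
  # leaky path: pick the 10 variables most correlated with the label
  cors <- abs(cor(V, y))
  leaky_vars <- rownames(cors)[order(-cors)][1:10]
  auc_leaky <- cv_with_fixed_variables(co, leaky_vars, folds = 4, seed = 7)
  # honest path: selection re-run inside folds (with null fallback)
  cfg <- pipeline_config(exclusion_patterns = character(0))
  auc_honest <- repeated_cv_permutation(co, config = cfg, reps = 1,
                                        folds = 4, n_perm = 0,
                                        seed = 7)$observed_auc
  expect_gt(auc_leaky, 0.65)
  expect_lt(auc_honest, 0.65)
  expect_gt(auc_leaky, auc_honest + 0.05)
})
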