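small_null_config <- function(n = 5000, seed = 1) {
  default_generator_config(n, seed = seed, null_effects = TRUE)
}

test_that("generator is deterministic given the seed", {
  cfg <- default_generator_config(200, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(default_generator_config(200, seed = 10))
  expect_false(identical(a$values, c2$values))
})

test_that("under the null every profile mean stays near the global mean", {
  co <- generate_cohort(small_null_config(5000))
  vars <- c("Glucose", "VLDL1_TG", "HDL1_CH")
  for (v in vars) {
    x <- co$values[, v]
    gm <- mean(x)
    for (p in c("0000", "0010", "0100")) {
      i <- co$meta$profile == p
      # sampling tolerance: 0.1 SD for the common profiles, 3.5 SE floor
      lim <- max(0.1, 3.5 / sqrt(sum(i)))
      expect_lt(abs(mean(x[i]) - gm), lim)
    }
  }
})

test_that("within-block correlation matches the configured value; across blocks ~ 0", {
  co <- generate_cohort(small_null_config(5000))
  rho <- cor(co$values[, "VLDL1_TG"], co$values[, "IDL_PL"],
             method = "spearman")
  expect_gt(rho, 0.85)
  expect_lt(rho, 0.95)
  # different blocks, null config: near-independence
  expect_lt(abs(cor(co$values[, "VLDL1_TG"], co$values[, "HDL1_CH"],
                    method = "spearman")), 0.1)
  expect_lt(abs(cor(co$values[, "Glucose"], co$values[, "Citrate"],
                    method = "spearman")), 0.1)
})

test_that("configured effects are recovered as profile mean shifts", {
  cfg <- default_generator_config(8000, seed = 5)
  co <- generate_cohort(cfg)
  em <- cfg$effect_matrix
  for (v in c("Glucose", "VLDL1_TG", "HDL1_CH")) {
    x <- co$values[, v]
    base <- mean(x[co$meta$profile == "0000"])
    for (p in c("0010", "1111")) {
      i <- co$meta$profile == p
      se <- sqrt(1 / sum(i) + 1 / sum(co$meta$profile == "0000"))
      expect_lt(abs((mean(x[i]) - base) - em[v, p]), 3 * se + 0.02)
    }
  }
})

test_that("configuration invariants are enforced", {
  prev <- default_profile_prevalence()
  bad <- prev; bad[1] <- bad[1] + 0.01
  blocks <- list(list(name = "b", type = "serum_metabolite", rho = 0.5,
                      members = c("x", "y")))
  em <- matrix(0, 2, 16, dimnames = list(c("x", "y"), all_profiles()))
  expect_error(generator_config(10, bad, blocks, em), "sum")
  blocks_bad <- list(list(name = "b", type = "serum_metabolite", rho = 1.0,
                          members = c("x", "y")))
  expect_error(generator_config(10, prev, blocks_bad, em), "\\[0, 1\\)")
  em_bad <- matrix(0, 1, 16, dimnames = list("z", all_profiles()))
  expect_error(generator_config(10, prev, blocks, em_bad), "not in any block")
  dup <- list(list(name = "a", type = "serum_metabolite", rho = 0,
                   members = "x"),
              list(name = "b", type = "serum_metabolite", rho = 0,
                   members = "x"))
  expect_error(generator_config(10, prev, dup, em), "more than one block")
})

test_that("cohort invariants: unique ids, finite values, ages in range, typed variables", {
  cfg <- default_generator_config(500, seed = 2)
  co <- generate_cohort(cfg)
  expect_equal(anyDuplicated(co$meta$sample_id), 0L)
  expect_true(all(is.finite(co$values)))
  expect_true(all(co$meta$age >= cfg$age_range[1] &
                    co$meta$age <= cfg$age_range[2]))
  expect_equal(sort(names(co$variable_types)), sort(colnames(co$values)))
  expect_equal(sum(co$variable_types == "serum_metabolite"), 41L)
  expect_equal(sum(co$variable_types == "serum_lipoprotein"), 112L)
})

test_that("cohort summary counts, percentages and Table-1-scale prevalences", {
  # tiny deterministic check: 4 female of 10
  meta <- tibble::tibble(sample_id = sprintf("s%d", 1:10),
                         gender = rep(c("female", "male"), c(4, 6)),
                         age = rep(30, 10), age_group = "[25,35)",
                         profile = rep("0000", 10))
  V <- matrix(1:10, 10, 1, dimnames = list(meta$sample_id, "Glucose"))
  co <- cohort_table(meta, V, c(Glucose = "serum_metabolite"))
  s <- cohort_summary(co)
  expect_equal(s$n[s$block == "gender" & s$level == "female"], 4L)
  expect_equal(s$pct[s$block == "gender" & s$level == "female"], 40)
  expect_equal(s$n[s$block == "mets_who" & s$level == "MetS"], 0L)
  # percentages sum to 100 within each block
  for (b in unique(s$block)) {
    expect_equal(sum(s$pct[s$block == b]), 100, tolerance = 0.1)
  }
  # prevalence recovery at scale: asymptomatic share near 68.5%
  big <- generate_cohort(default_generator_config(20000, seed = 3,
                                                  null_effects = TRUE))
  sb <- cohort_summary(big)
  p0000 <- sb$pct[sb$block == "profile" & sb$level == "0000"]
  expect_lt(abs(p0000 - 68.5), 2)
})

test_that("urine bins can be attached via the spectrum path", {
  co <- generate_cohort(default_generator_config(5, seed = 1))
  ax <- seq(0.4, 9.6, by = 0.005)
  sps <- lapply(stats::setNames(co$meta$sample_id, co$meta$sample_id),
                function(id) {
    generate_urine_spectrum(data.frame(center = c(3, 7.2),
                                       width = 0.02, amplitude = c(2, 1)),
                            ax, noise_sd = 0.001,
                            seed = utf8ToInt(substr(id, 5, 5)))
  })
  withbins <- add_urine_bins(co, bin_spectra_matrix(sps))
  expect_equal(sum(withbins$variable_types == "urine_bin"), 290L)
  expect_equal(ncol(withbins$values), 153L + 290L)
})
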