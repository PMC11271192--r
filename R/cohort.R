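# Synthetic serum cohorts with the statistical structure the downstream
# analysis assumes: block-correlated variables (lipoprotein clusters as
# equicorrelated Gaussian blocks sharing a latent factor), additive
# profile-dependent mean shifts in SD units, gender/age covariate
# effects, and configurable profile prevalences.

AGE_BREAKS <- c(18, 25, 35, 45, 55, 64, 70, 81, 105)

age_group_labels <- function(breaks = AGE_BREAKS) {
  k <- length(breaks) - 1L
  lab <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  lab[k] <- sprintf("[%g,%g]", breaks[k], breaks[k + 1L])
  lab
}

#' Assign age groups
#'
#' Default boundaries are the cohort-study age strata:
#' 18, 25, 35, 45, 55, 64, 70, 81, 105 (last interval closed).
#'
#' @param age numeric ages in years.
#' @param breaks group boundaries.
#' @return Factor of group labels.
#' @export
assign_age_group <- function(age, breaks = AGE_BREAKS) {
  cut(age, breaks = breaks, labels = age_group_labels(breaks),
      right = FALSE, include.lowest = TRUE)
}

#' Construct and validate a cohort generator configuration
#'
#' @param n_samples positive sample count.
#' @param profile_prevalence named probability vector over the 16 profile
#'   codes; must sum to 1 (tolerance 1e-9).
#' @param variable_blocks list of blocks, each
#'   `list(name=, type=, members=, rho=)` with `type` one of
#'   `serum_metabolite`, `serum_lipoprotein`, `urine_bin` and within-block
#'   correlation `rho` in [0, 1).
#' @param effect_matrix numeric matrix (variables x 16 profiles, columns
#'   named by code) of mean shifts in SD units relative to 0000; every row
#'   name must belong to exactly one block.
#' @param covariate_effects list with named numeric vectors
#'   `gender_female` (shift for female samples, SD units) and `age_slope`
#'   (shift per year of age relative to the age-range midpoint, SD units).
#' @param age_range,age_mean,age_sd truncated-normal age model (years).
#' @param female_fraction probability a sample is female.
#' @param noise_sd marginal standard deviation of every variable.
#' @param baseline named per-variable baseline means, or NULL to derive
#'   defaults from the variable type (metabolites 10, lipoproteins 100,
#'   urine bins 5).
#' @param seed integer seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_samples,
                             profile_prevalence,
                             variable_blocks,
                             effect_matrix,
                             covariate_effects = list(),
                             age_range = c(18, 81),
                             age_mean = 45,
                             age_sd = 11,
                             female_fraction = 0.375,
                             noise_sd = 1,
                             baseline = NULL,
                             seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("configuration error: n_samples must be a positive count")
  }
  codes <- all_profiles()
  if (!all(sort(names(profile_prevalence)) == codes)) {
    stop("configuration error: profile_prevalence must name all 16 profiles")
  }
  if (abs(sum(profile_prevalence) - 1) > 1e-9) {
    stop("configuration error: profile prevalences sum to ",
         format(sum(profile_prevalence), digits = 12), ", not 1")
  }
  members <- unlist(lapply(variable_blocks, `[[`, "members"))
  if (anyDuplicated(members)) {
    stop("configuration error: variable(s) in more than one block: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  for (b in variable_blocks) {
    stopifnot(is.character(b$name), length(b$members) >= 1L)
    if (!b$type %in% c("serum_metabolite", "serum_lipoprotein", "urine_bin")) {
      stop("configuration error: unknown dataset type '", b$type, "'")
    }
    if (b$rho < 0 || b$rho >= 1) {
      stop("configuration error: block '", b$name,
           "' correlation must be in [0, 1), got ", b$rho)
    }
  }
  if (!all(rownames(effect_matrix) %in% members)) {
    bad <- setdiff(rownames(effect_matrix), members)
    stop("configuration error: effect_matrix variables not in any block: ",
         paste(bad, collapse = ", "))
  }
  if (!all(colnames(effect_matrix) %in% codes)) {
    stop("configuration error: effect_matrix columns must be profile codes")
  }
  if (noise_sd <= 0) stop("configuration error: noise_sd must be positive")
  stopifnot(female_fraction >= 0, female_fraction <= 1,
            length(age_range) == 2L, age_range[1] < age_range[2])

  types <- unlist(lapply(variable_blocks, function(b) {
    stats::setNames(rep(b$type, length(b$members)), b$members)
  }))
  if (is.null(baseline)) {
    baseline <- c(serum_metabolite = 10, serum_lipoprotein = 100,
                  urine_bin = 5)[types]
    names(baseline) <- names(types)
  }
  structure(list(n_samples = as.integer(n_samples),
                 profile_prevalence = profile_prevalence[codes],
                 variable_blocks = variable_blocks,
                 effect_matrix = effect_matrix,
                 covariate_effects = covariate_effects,
                 age_range = age_range, age_mean = age_mean, age_sd = age_sd,
                 female_fraction = female_fraction,
                 noise_sd = noise_sd, baseline = baseline,
                 variable_types = types,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic cohort
#'
#' For sample i and variable v in block b the value is
#' `baseline_v + noise_sd * (shift_iv + sqrt(rho_b) z_ib +
#' sqrt(1 - rho_b) e_iv)` where `z_ib` is a per-sample latent factor
#' shared by the block (giving equicorrelation rho_b), `e_iv` is
#' independent noise and `shift_iv` sums the profile effect, the gender
#' shift and the age slope (all in SD units). Deterministic given the
#' config seed.
#'
#' @param config a `generator_config`.
#' @return A `cohort_table`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_samples
  with_seed(config$seed, {
    profile <- sample(names(config$profile_prevalence), n, replace = TRUE,
                      prob = config$profile_prevalence)
    gender <- ifelse(stats::runif(n) < config$female_fraction,
                     "female", "male")
    lo <- config$age_range[1]; hi <- config$age_range[2]
    u <- stats::runif(n,
                      stats::pnorm(lo, config$age_mean, config$age_sd),
                      stats::pnorm(hi, config$age_mean, config$age_sd))
    age <- stats::qnorm(u, config$age_mean, config$age_sd)

    vars <- names(config$variable_types)
    values <- matrix(0, nrow = n, ncol = length(vars),
                     dimnames = list(sprintf("S%05d", seq_len(n)), vars))
    shift_base <- matrix(0, nrow = n, ncol = length(vars),
                         dimnames = list(NULL, vars))
    em <- config$effect_matrix
    if (!is.null(em) && nrow(em) > 0L) {
      hit <- intersect(vars, rownames(em))
      idx <- match(profile, colnames(em))
      shift_base[, hit] <- t(em[hit, idx, drop = FALSE])
    }
    gf <- config$covariate_effects$gender_female
    if (!is.null(gf)) {
      for (v in intersect(names(gf), vars)) {
        shift_base[, v] <- shift_base[, v] + gf[[v]] * (gender == "female")
      }
    }
    sl <- config$covariate_effects$age_slope
    age_c <- age - mean(config$age_range)
    if (!is.null(sl)) {
      for (v in intersect(names(sl), vars)) {
        shift_base[, v] <- shift_base[, v] + sl[[v]] * age_c
      }
    }
    for (b in config$variable_blocks) {
      z <- stats::rnorm(n)
      for (v in b$members) {
        e <- stats::rnorm(n)
        g <- sqrt(b$rho) * z + sqrt(1 - b$rho) * e
        values[, v] <- config$baseline[[v]] +
          config$noise_sd * (shift_base[, v] + g)
      }
    }
    cohort_table(
      meta = tibble::tibble(sample_id = rownames(values),
                            gender = gender, age = age,
                            age_group = as.character(assign_age_group(age)),
                            profile = profile),
      values = values,
      variable_types = config$variable_types
    )
  })
}

#' Construct and validate a cohort table
#'
#' @param meta tibble with columns `sample_id`, `gender`, `age`,
#'   `age_group`, `profile`.
#' @param values numeric matrix (samples x variables), row names matching
#'   `meta$sample_id`.
#' @param variable_types named character vector mapping every column of
#'   `values` to `serum_metabolite`, `serum_lipoprotein` or `urine_bin`.
#' @return Object of class `cohort_table`.
#' @export
cohort_table <- function(meta, values, variable_types) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "gender", "age", "age_group", "profile")
  if (!all(need %in% names(meta))) {
    stop("cohort metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    stop("duplicate sample id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  check_profile_code(meta$profile)
  values <- as.matrix(values)
  if (nrow(values) != nrow(meta)) stop("values and metadata row counts differ")
  if (!all(rownames(values) == meta$sample_id)) {
    stop("values row names must equal meta$sample_id, in order")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at sample '", rownames(values)[bad[1L]],
         "', variable '", colnames(values)[bad[2L]], "'")
  }
  miss <- setdiff(colnames(values), names(variable_types))
  if (length(miss)) {
    stop("variable(s) without a dataset type: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  vt <- variable_types[colnames(values)]
  if (!all(vt %in% c("serum_metabolite", "serum_lipoprotein", "urine_bin"))) {
    stop("unknown variable type(s): ",
         paste(unique(setdiff(vt, c("serum_metabolite", "serum_lipoprotein",
                                    "urine_bin"))), collapse = ", "))
  }
  structure(list(meta = meta, values = values, variable_types = vt),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  tt <- table(x$variable_types)
  cat("Cohort: ", nrow(x$meta), " samples, ", ncol(x$values), " variables (",
      paste(sprintf("%s %d", names(tt), tt), collapse = ", "), ")\n",
      sep = "")
  cat("  MetS (WHO): ", sum(classify_mets(x$meta$profile)), " samples\n",
      sep = "")
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort a `cohort_table`.
#' @export
n_samples <- function(cohort) nrow(cohort$meta)

#' Extract the value matrix, optionally restricted to a dataset type
#'
#' @param cohort a `cohort_table`.
#' @param type optional dataset type or vector of types.
#' @param variables optional variable names.
#' @return Numeric matrix.
#' @export
cohort_values <- function(cohort, type = NULL, variables = NULL) {
  v <- cohort$values
  if (!is.null(type)) v <- v[, cohort$variable_types %in% type, drop = FALSE]
  if (!is.null(variables)) {
    miss <- setdiff(variables, colnames(v))
    if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
    v <- v[, variables, drop = FALSE]
  }
  v
}

#' Per-sample MetS status under a registered definition
#' @param cohort a `cohort_table`.
#' @param definition definition name.
#' @return Logical vector.
#' @export
cohort_mets <- function(cohort, definition = "WHO") {
  classify_mets(cohort$meta$profile, definition)
}

#' Subset a cohort by sample ids
#' @param cohort a `cohort_table`.
#' @param ids sample ids to keep (order preserved).
#' @export
cohort_subset <- function(cohort, ids) {
  idx <- match(ids, cohort$meta$sample_id)
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  cohort_table(cohort$meta[idx, ], cohort$values[idx, , drop = FALSE],
               cohort$variable_types)
}

#' Attach urine bin intensities to a cohort
#'
#' Adds columns of type `urine_bin` (e.g. from [bin_spectra_matrix()])
#' for the matching sample ids.
#'
#' @param cohort a `cohort_table`.
#' @param bins numeric matrix, row names = sample ids, columns = bin names.
#' @export
add_urine_bins <- function(cohort, bins) {
  stopifnot(is.matrix(bins))
  if (!all(rownames(bins) == cohort$meta$sample_id)) {
    stop("bin matrix rows must match cohort sample ids, in order")
  }
  values <- cbind(cohort$values, bins)
  types <- c(cohort$variable_types,
             stats::setNames(rep("urine_bin", ncol(bins)), colnames(bins)))
  cohort_table(cohort$meta, values, types)
}

#' Summarize a cohort by gender, age group, profile and MetS status
#'
#' Counts and percentages per block; percentages within each block sum
#' to 100.
#'
#' @param cohort a `cohort_table`.
#' @return Tibble with columns `block`, `level`, `n`, `pct`.
#' @export
cohort_summary <- function(cohort) {
  m <- cohort$meta
  one <- function(block, values, levels) {
    n <- vapply(levels, function(l) sum(values == l), integer(1),
                USE.NAMES = FALSE)
    tibble::tibble(block = block, level = levels, n = n,
                   pct = 100 * n / length(values))
  }
  rbind(
    one("gender", m$gender, c("female", "male")),
    one("age_group", m$age_group, age_group_labels()),
    one("profile", m$profile, all_profiles()),
    one("mets_who", ifelse(classify_mets(m$profile), "MetS", "no MetS"),
        c("MetS", "no MetS"))
  )
}
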