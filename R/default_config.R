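# Default generator configuration: a serum panel of 41 metabolites and
# 112 lipoprotein parameters organised into correlated blocks that mirror
# the empirically observed lipoprotein clusters (VLDL/IDL, LDL 4-5,
# LDL 1-3, LDL 6, HDL 1-3 with and without triglycerides, HDL 4), with
# additive per-risk-factor mean shifts reproducing the qualitative
# pattern of the profile-contrast heatmap: dyslipidemia elevates
# VLDL/IDL, dense LDL and TG-rich HDL while depleting light LDL and
# non-TG HDL; diabetes is dominated by glucose, ketone bodies and
# lactate; obesity and hypertension act through amino acids.

lipo_particles <- function(p, lipids = c("TG", "CH", "FC", "PL", "ApoB")) {
  as.vector(outer(p, lipids, paste, sep = "_"))
}

default_variable_blocks <- function() {
  hdl_ap <- c("CH", "FC", "PL", "ApoA1", "ApoA2")
  list(
    list(name = "vldl_idl", type = "serum_lipoprotein", rho = 0.9,
         members = c(lipo_particles(c(paste0("VLDL", 1:5), "IDL")),
                     "VLDL_PN", "IDL_PN")),
    list(name = "ldl_45", type = "serum_lipoprotein", rho = 0.9,
         members = c(lipo_particles(c("LDL4", "LDL5")),
                     "Total_ApoB", "Total_CH", "LDL_PN", "ApoB_ApoA1_ratio")),
    list(name = "ldl_123", type = "serum_lipoprotein", rho = 0.9,
         members = c(lipo_particles(c("LDL1", "LDL2", "LDL3")),
                     "LDL_CH_total")),
    list(name = "ldl_6", type = "serum_lipoprotein", rho = 0.9,
         members = c(lipo_particles("LDL6"), "LDL6_PN")),
    list(name = "hdl_123_noTG", type = "serum_lipoprotein", rho = 0.9,
         members = c(as.vector(outer(paste0("HDL", 1:3), hdl_ap,
                                     paste, sep = "_")),
                     "Total_ApoA1", "Total_ApoA2", "HDL_CH_total")),
    list(name = "hdl_123_TG", type = "serum_lipoprotein", rho = 0.9,
         members = c(paste0("HDL", 1:3, "_TG"), "HDL_TG_total",
                     "TG_HDL_ratio", "HDL4_TG")),
    list(name = "hdl_4", type = "serum_lipoprotein", rho = 0.9,
         members = c(paste0("HDL4_", hdl_ap),
                     "HDL4_CH_ratio", "HDL4_PL_ratio", "HDL4_FC_ratio")),
    list(name = "lipo_misc", type = "serum_lipoprotein", rho = 0.7,
         members = c("Total_TG", "Total_PL", "Total_FC", "VLDL_size",
                     "LDL_size", "HDL_size", "LDL_HDL_ratio", "TG_CH_ratio",
                     "ApoB_ApoA2_ratio", "IDL_TG_ratio", "VLDL_CH_ratio",
                     "HDL_FC_ratio")),
    list(name = "aa", type = "serum_metabolite", rho = 0.6,
         members = c("Alanine", "Valine", "Leucine", "Isoleucine",
                     "Phenylalanine", "Tyrosine", "Proline", "Glutamine",
                     "Glycine", "Histidine")),
    list(name = "ketones", type = "serum_metabolite", rho = 0.7,
         members = c("Acetone", "Acetoacetate", "3-Hydroxybutyrate"))
  ) |>
    c(lapply(c("Glucose", "Lactate", "Pyruvate", "Citrate", "Creatinine",
               "Creatine", "Sarcosine", "TMAO", "Betaine", "Choline",
               "Dimethylglycine", "Formate", "Acetate", "Methanol",
               "Ethanol", "Urea", "Ornithine", "Lysine", "Methionine",
               "Threonine", "Asparagine", "Aspartate", "Glutamate",
               "2-Aminobutyrate", "Trigonelline", "Glycerol",
               "Ca-EDTA", "K-EDTA"),
             function(v) list(name = v, type = "serum_metabolite",
                              rho = 0, members = v)))
}

block_members <- function(blocks, name) {
  for (b in blocks) if (b$name == name) return(b$members)
  stop("no block named ", name)
}

# Per-risk-factor mean shifts (SD units). A named list factor -> named
# vector over variables; block-wide entries are expanded to all members,
# then variable-specific overrides applied.
default_factor_effects <- function(blocks = default_variable_blocks()) {
  expand <- function(block_shifts = list(), var_shifts = c()) {
    out <- c()
    for (bn in names(block_shifts)) {
      m <- block_members(blocks, bn)
      out <- c(out, stats::setNames(rep(block_shifts[[bn]], length(m)), m))
    }
    out[names(var_shifts)] <- var_shifts
    out
  }
  list(
    diabetes = expand(
      list(ketones = 1.0, vldl_idl = 0.3),
      c(Glucose = 1.5, Lactate = 0.4, Alanine = 0.5, Isoleucine = 0.5,
        Glycerol = 0.3)),
    obesity = expand(
      list(aa = 0.4, vldl_idl = 0.4, hdl_123_noTG = -0.3, ketones = 0.6),
      c(Proline = 0.7, Phenylalanine = 0.6, Glycerol = 0.4)),
    dyslipidemia = expand(
      list(vldl_idl = 1.0, ldl_45 = 1.0, hdl_123_TG = 0.9, ldl_6 = 0.8,
           hdl_123_noTG = -0.9, ldl_123 = -0.6, lipo_misc = 0.6),
      c(Sarcosine = 0.6)),
    hypertension = expand(
      list(vldl_idl = 0.2),
      c(Proline = 0.5, Phenylalanine = 0.5, Creatinine = 0.4))
  )
}

#' Build a profile effect matrix from per-risk-factor shifts
#'
#' Profile effects are additive over active risk factors: the shift of a
#' variable in profile p is the sum of its shifts for the factors active
#' in p (the 0000 column is zero).
#'
#' @param factor_effects named list (`diabetes`, `obesity`,
#'   `dyslipidemia`, `hypertension`) of named shift vectors in SD units.
#' @return Numeric matrix, variables x 16 profiles.
#' @export
effect_matrix_from_factors <- function(factor_effects) {
  stopifnot(all(names(factor_effects) %in% RISK_FACTORS))
  vars <- unique(unlist(lapply(factor_effects, names)))
  codes <- all_profiles()
  bits <- profile_bits(codes)
  em <- matrix(0, nrow = length(vars), ncol = length(codes),
               dimnames = list(vars, codes))
  for (f in names(factor_effects)) {
    fe <- factor_effects[[f]]
    active <- codes[bits[, f] == 1L]
    em[names(fe), active] <- em[names(fe), active] + fe
  }
  em
}

# Table-1-style profile prevalences of the serum cohort (counts over
# 20,662 donors).
default_profile_prevalence <- function() {
  counts <- c(`0000` = 14145, `0001` = 1004, `0010` = 1721, `0011` = 578,
              `0100` = 1182, `0101` = 361, `0110` = 491, `0111` = 300,
              `1000` = 166, `1001` = 139, `1010` = 86, `1011` = 124,
              `1100` = 79, `1101` = 91, `1110` = 62, `1111` = 133)
  counts / sum(counts)
}

#' Default cohort generator configuration
#'
#' The package's reference study conditions: 153 serum variables (41
#' metabolites, 112 lipoprotein parameters) in correlated blocks
#' (within-block correlation 0.9 for lipoprotein clusters), additive
#' per-factor effects on the SD scale, realistic profile prevalences
#' (asymptomatic 68.5%, WHO-MetS about 2%), 37.5% female, ages 18-81.
#'
#' @param n_samples cohort size.
#' @param seed integer seed.
#' @param null_effects if TRUE, zero out all profile and covariate
#'   effects (global null).
#' @return A `generator_config`.
#' @export
default_generator_config <- function(n_samples = 2000, seed = 1L,
                                     null_effects = FALSE) {
  blocks <- default_variable_blocks()
  em <- effect_matrix_from_factors(default_factor_effects(blocks))
  cov_eff <- list(
    gender_female = c(stats::setNames(
      rep(0.4, length(block_members(blocks, "hdl_123_noTG"))),
      block_members(blocks, "hdl_123_noTG")),
      Creatinine = -0.3, Creatine = 0.2),
    age_slope = c(stats::setNames(
      rep(0.01, length(block_members(blocks, "vldl_idl"))),
      block_members(blocks, "vldl_idl")),
      stats::setNames(rep(0.015, length(block_members(blocks, "ldl_45"))),
                      block_members(blocks, "ldl_45")),
      Glucose = 0.01)
  )
  if (null_effects) {
    em[] <- 0
    cov_eff <- list()
  }
  generator_config(
    n_samples = n_samples,
    profile_prevalence = default_profile_prevalence(),
    variable_blocks = blocks,
    effect_matrix = em,
    covariate_effects = cov_eff,
    seed = seed
  )
}

#' Block membership of the default variable roster
#'
#' @param config a `generator_config`.
#' @return Tibble with `variable`, `block`, `type`, `rho`.
#' @export
generator_block_map <- function(config) {
  do.call(rbind, lapply(config$variable_blocks, function(b) {
    tibble::tibble(variable = b$members, block = b$name, type = b$type,
                   rho = b$rho)
  }))
}
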