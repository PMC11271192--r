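# Internal helpers: seeded evaluation and per-stage seed derivation.

# Evaluate an expression under a temporary RNG state so package
# functions are seeded without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one global seed into per-stage seeds, so each
# pipeline stage is independently reproducible. Kept below 2^31.
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, split = 2L, univariate = 3L, clustering = 4L,
              selection = 5L, opls = 6L, threshold = 7L, calibration = 8L,
              cv = 9L, som = 10L, permutation = 11L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000003L) * 2017L + stages[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
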