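# File formats: cohorts as delimited text with a JSON sidecar mapping
# variables to dataset types; spectra as two-column delimited text;
# pipeline configs as YAML; models as versioned, self-contained JSON.

#' Write a cohort as delimited text plus a variable-type sidecar
#'
#' @param cohort a `cohort_table`.
#' @param path CSV path for the table (metadata columns then variables).
#' @param type_map_path JSON path for the variable -> type map; defaults
#'   to `<path>` with extension `.types.json`.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, path,
                         type_map_path = sub("\\.[^.]+$", ".types.json", path)) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cbind(as.data.frame(cohort$meta), as.data.frame(cohort$values))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(as.list(cohort$variable_types), type_map_path,
                       auto_unbox = TRUE)
  invisible(c(path, type_map_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the parsed table: unique sample ids, numeric finite values,
#' and a known dataset type for every variable; violations raise errors
#' naming the offending row or column.
#'
#' @param path CSV path.
#' @param type_map_path JSON sidecar path.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path,
                        type_map_path = sub("\\.[^.]+$", ".types.json", path)) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(sample_id = "character",
                                       gender = "character",
                                       age_group = "character",
                                       profile = "character"))
  types <- unlist(jsonlite::read_json(type_map_path))
  meta_cols <- c("sample_id", "gender", "age", "age_group", "profile")
  miss <- setdiff(meta_cols, names(df))
  if (length(miss)) stop("cohort file lacks column(s): ",
                         paste(miss, collapse = ", "))
  var_cols <- setdiff(names(df), meta_cols)
  unknown <- setdiff(var_cols, names(types))
  if (length(unknown)) {
    stop("variable(s) without a type in ", type_map_path, ": ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  V <- as.matrix(df[, var_cols, drop = FALSE])
  if (!is.numeric(V)) {
    notnum <- var_cols[!vapply(df[var_cols], is.numeric, logical(1))]
    stop("non-numeric value(s) in column(s): ",
         paste(utils::head(notnum, 5), collapse = ", "))
  }
  rownames(V) <- df$sample_id
  cohort_table(df[, meta_cols], V, types[var_cols])
}

#' Read a spectrum from two-column delimited text (ppm, intensity)
#'
#' @param path file path; comma, tab or whitespace separated, optional
#'   header.
#' @return An `nmr_spectrum`.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          comment.char = "#",
                          col.names = c("ppm", "intensity"),
                          colClasses = "character", fill = TRUE)
  if (grepl("[^0-9eE+.\\-]", df$ppm[1L])) df <- df[-1L, , drop = FALSE]
  new_spectrum(as.numeric(df$ppm), as.numeric(df$intensity))
}

#' Write a spectrum as two-column delimited text
#' @param spectrum an `nmr_spectrum`.
#' @param path output path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  utils::write.table(data.frame(ppm = spectrum$ppm,
                                intensity = spectrum$intensity),
                     path, sep = "\t", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' Write / read a pipeline configuration as YAML
#'
#' Configurations round-trip unchanged through serialization.
#'
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  doc <- unclass(config)
  doc$cut_heights <- as.list(doc$cut_heights)  # keep names in YAML
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$cut_heights <- unlist(raw$cut_heights)
  raw$exclusion_patterns <- unlist(raw$exclusion_patterns)
  do.call(pipeline_config, raw)
}

MODEL_FORMAT_VERSION <- "1.0"

#' Serialize a fitted model as self-contained JSON
#'
#' Stores the variable list, preprocessing parameters, weight and
#' loading vectors, training scores, and (when present) the Youden
#' threshold and sigmoid calibration, under a format version.
#'
#' @param model a `mets_model` or an `opls_model`.
#' @param path output JSON path.
#' @param extra named list of extra metadata (e.g. config hash, seed).
#' @return Invisibly, `path`.
#' @export
write_opls_model <- function(model, path, extra = list()) {
  cal <- NULL
  if (inherits(model, "mets_model")) {
    cal <- model$calibration
    opls <- model$opls
  } else if (inherits(model, "opls_model")) {
    opls <- model
    cal <- model$calibration
  } else stop("unsupported model object")
  doc <- c(list(format_version = MODEL_FORMAT_VERSION), extra, list(
    variables = opls$variables,
    n_orth = opls$n_orth,
    log_offset = unname(opls$log_offset),
    center = unname(opls$center),
    scale = unname(opls$scale),
    w = unname(opls$w),
    p_load = unname(opls$p_load),
    w_orth = apply(opls$w_orth, 2L, identity, simplify = FALSE),
    p_orth = apply(opls$p_orth, 2L, identity, simplify = FALSE),
    c = opls$c,
    t_pred = unname(opls$t_pred)
  ))
  if (!is.null(cal)) {
    doc$calibration <- list(slope = cal$slope, intercept = cal$intercept,
                            threshold = cal$threshold)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by [write_opls_model()]
#'
#' @param path JSON path.
#' @return An `opls_model`, with a `calibration` attached when the
#'   document carries one.
#' @export
read_opls_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format_version)) stop("not a model document: ", path)
  vars <- doc$variables
  nm <- function(x) stats::setNames(as.numeric(x), vars)
  as_mat <- function(x) {
    m <- if (is.list(x)) do.call(cbind, lapply(x, as.numeric)) else
      matrix(as.numeric(x), ncol = doc$n_orth)
    rownames(m) <- NULL; colnames(m) <- NULL
    m
  }
  model <- structure(list(
    variables = vars, n_orth = as.integer(doc$n_orth),
    log_offset = nm(doc$log_offset), center = nm(doc$center),
    scale = nm(doc$scale), w = nm(doc$w), p_load = nm(doc$p_load),
    w_orth = as_mat(doc$w_orth), p_orth = as_mat(doc$p_orth),
    c = as.numeric(doc$c), t_pred = as.numeric(doc$t_pred),
    t_orth = NULL
  ), class = "opls_model")
  if (!is.null(doc$calibration)) {
    cal <- structure(list(slope = doc$calibration$slope,
                          intercept = doc$calibration$intercept,
                          threshold = doc$calibration$threshold,
                          recentering = NA_real_),
                     class = "score_calibration")
    cal$metscore <- function(t) stats::plogis(cal$intercept + cal$slope * t)
    model$calibration <- cal
  }
  model
}
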