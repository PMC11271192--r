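# Risk-factor profile algebra: 4-bit states, MetS classification rules,
# and the Hamming-1 progression graph.

RISK_FACTORS <- c("diabetes", "obesity", "dyslipidemia", "hypertension")

# Registry of MetS definitions: each is a character vector of profile codes.
# Only the WHO rule ships built in; other consensus definitions can be
# registered from their code sets.
.mets_definitions <- new.env(parent = emptyenv())
.mets_definitions$WHO <- c("1011", "1101", "1110", "1111")

#' Encode four binary risk factors as a profile code
#'
#' The four factors (diabetes, obesity, dyslipidemia, hypertension) are
#' concatenated, in that fixed order, into a 4-character code over
#' \{0,1\}: `"0000"` is the asymptomatic state, `"1110"` a patient with
#' diabetes, obesity and dyslipidemia but no hypertension.
#'
#' @param diabetes,obesity,dyslipidemia,hypertension logical or 0/1
#'   vectors (recycled to common length).
#' @return Character vector of 4-bit profile codes.
#' @examples
#' encode_profile(1, 1, 1, 0)  # "1110"
#' @export
encode_profile <- function(diabetes, obesity, dyslipidemia, hypertension) {
  bits <- cbind(as.integer(as.logical(diabetes)),
                as.integer(as.logical(obesity)),
                as.integer(as.logical(dyslipidemia)),
                as.integer(as.logical(hypertension)))
  if (anyNA(bits)) stop("risk-factor flags must be interpretable as logical")
  apply(bits, 1L, paste0, collapse = "")
}

#' Decompose a profile code into its risk-factor bits
#'
#' @param code character vector of 4-bit profile codes.
#' @return Integer matrix with one row per code and columns
#'   `diabetes`, `obesity`, `dyslipidemia`, `hypertension`.
#' @export
profile_bits <- function(code) {
  check_profile_code(code)
  m <- t(vapply(strsplit(code, ""), function(b) as.integer(b), integer(4)))
  colnames(m) <- RISK_FACTORS
  rownames(m) <- code
  m
}

check_profile_code <- function(code) {
  ok <- grepl("^[01]{4}$", code)
  if (!all(ok)) {
    stop("invalid profile code(s): ", paste(unique(code[!ok]), collapse = ", "),
         " (expected 4 characters over {0,1})")
  }
  invisible(code)
}

#' All 16 risk profiles
#'
#' @return Character vector of the 16 codes `"0000"` .. `"1111"`, in
#'   binary order.
#' @export
all_profiles <- function() {
  g <- expand.grid(h = 0:1, d2 = 0:1, o = 0:1, d1 = 0:1)
  sort(paste0(g$d1, g$o, g$d2, g$h))
}

#' Register a MetS definition as a set of profile codes
#'
#' Consensus definitions other than WHO (EGIR, NCEP, IDF, ...) differ in
#' which profile states they call MetS; any such rule reduces to a subset
#' of the 16 codes and can be registered here by name.
#'
#' @param name definition name.
#' @param codes character vector of profile codes classified as MetS.
#' @export
register_mets_definition <- function(name, codes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_profile_code(codes)
  assign(name, unique(codes), envir = .mets_definitions)
  invisible(codes)
}

#' List registered MetS definitions
#' @return Named list of profile-code sets.
#' @export
mets_definitions <- function() {
  as.list(.mets_definitions)
}

#' Classify a profile as MetS under a registered definition
#'
#' The built-in WHO rule classifies a profile as MetS iff the diabetes
#' bit is set and at least two of the other three factors are present,
#' i.e. exactly the codes 1011, 1101, 1110 and 1111.
#'
#' @param profile character vector of profile codes.
#' @param definition definition name (default `"WHO"`).
#' @return Logical vector.
#' @examples
#' classify_mets(c("1110", "0000", "1001"))  # TRUE FALSE FALSE
#' @export
classify_mets <- function(profile, definition = "WHO") {
  check_profile_code(profile)
  if (!exists(definition, envir = .mets_definitions, inherits = FALSE)) {
    stop("unknown MetS definition '", definition, "'; registered: ",
         paste(ls(.mets_definitions), collapse = ", "))
  }
  profile %in% get(definition, envir = .mets_definitions)
}

hamming1 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) == 1L
}

#' Build the profile progression graph
#'
#' Nodes are the 16 risk profiles; edges connect profiles differing in
#' exactly one risk factor (Hamming distance 1), so every path from 0000
#' to 1111 acquires one factor at a time. Nodes are annotated with the
#' number of samples and mean score of their members, and with
#' membership flags for every registered MetS definition. Profiles with
#' no samples are flagged absent rather than given a score of zero.
#'
#' @param scores numeric vector of per-sample scores (finite).
#' @param profiles character vector of per-sample profile codes.
#' @return Object of class `profile_graph`: list with `nodes` (tibble:
#'   code, n_active, n, mean_score, present, one `mets_<def>` flag per
#'   registered definition), `edges` (tibble: from, to) and `graph`
#'   (an igraph object).
#' @export
build_profile_graph <- function(scores = numeric(), profiles = character()) {
  if (length(scores) != length(profiles)) {
    stop("scores and profiles must have equal length")
  }
  if (length(scores) && !all(is.finite(scores))) stop("scores must be finite")
  if (length(profiles)) check_profile_code(profiles)

  codes <- all_profiles()
  n <- vapply(codes, function(cd) sum(profiles == cd), integer(1),
              USE.NAMES = FALSE)
  mean_score <- vapply(codes, function(cd) {
    if (any(profiles == cd)) mean(scores[profiles == cd]) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)

  nodes <- tibble::tibble(
    code = codes,
    n_active = vapply(codes, function(cd) sum(profile_bits(cd)), integer(1)),
    n = n,
    mean_score = mean_score,
    present = n > 0L
  )
  for (def in ls(.mets_definitions)) {
    nodes[[paste0("mets_", def)]] <- classify_mets(codes, def)
  }

  pairs <- utils::combn(codes, 2L)
  keep <- apply(pairs, 2L, function(p) hamming1(p[1L], p[2L]))
  edges <- tibble::tibble(from = pairs[1L, keep], to = pairs[2L, keep])
  # orient edges from fewer to more active factors
  sw <- nodes$n_active[match(edges$from, nodes$code)] >
    nodes$n_active[match(edges$to, nodes$code)]
  tmp <- edges$from[sw]; edges$from[sw] <- edges$to[sw]; edges$to[sw] <- tmp

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = as.data.frame(nodes))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "profile_graph")
}

#' @export
print.profile_graph <- function(x, ...) {
  cat("Profile progression graph: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges; ", sum(x$nodes$present),
      " profiles populated\n", sep = "")
  invisible(x)
}

#' Export a profile graph as delimited tables and GraphML
#'
#' @param graph a `profile_graph`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_profile_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "profile_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(nodes = file.path(dir, "profile_graph_nodes.csv"),
             edges = file.path(dir, "profile_graph_edges.csv"),
             graphml = file.path(dir, "profile_graph.graphml"))
  utils::write.csv(graph$nodes, paths[["nodes"]], row.names = FALSE)
  utils::write.csv(graph$edges, paths[["edges"]], row.names = FALSE)
  igraph::write_graph(graph$graph, paths[["graphml"]], format = "graphml")
  invisible(paths)
}
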