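#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then members. Duplicate members
#' within a set are collapsed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
load_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_validation("empty GMT file: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop_validation("GMT line ", short[1], " has fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    stop_validation("duplicate set names in GMT file")
  }
  structure(sets, class = c("gene_set_collection", "list"))
}

#' Upper-tail hypergeometric over-representation test
#'
#' For each gene set, tests whether the query (e.g. the transcripts called
#' more abundant in one group) overlaps the set more than expected under
#' random draws from the universe: p = P(X >= k) with X hypergeometric
#' (universe N, set size K, query size n). A one-sided over-representation
#' test in the spirit of annotation-enrichment tools; results are sorted by
#' p (ties by set name). Sets that are empty after intersection with the
#' universe are dropped with a message; query members outside the universe
#' are dropped with a warning.
#'
#' @param query character vector of query transcript ids.
#' @param sets named list of gene sets (e.g. from [load_gmt()]).
#' @param universe character vector: the tested background (all transcripts
#'   the calling procedure could have selected from).
#' @return Data frame: set, N, K, n, k, p_value.
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) {
    stop_validation("empty universe")
  }
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query id(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  sets <- lapply(sets, intersect, universe)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    message(sum(empty), " set(s) empty after intersection with the ",
            "universe dropped: ", paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  N <- length(universe)
  n <- length(query)
  rows <- data.frame(
    set = names(sets),
    N = N,
    K = unname(lengths(sets)),
    n = n,
    k = unname(vapply(sets, function(s) length(intersect(s, query)),
                      integer(1))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  rows$p_value <- stats::phyper(rows$k - 1L, rows$K, N - rows$K, n,
                                lower.tail = FALSE)
  rows <- rows[order(rows$p_value, rows$set), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
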