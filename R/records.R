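#' Order an interaction pair canonically
#'
#' Physical interactions are unordered: the pair (a, b) denotes the same
#' binding event as (b, a).  All internal bookkeeping therefore stores each
#' pair with the lexicographically smaller identifier first.  Comparison is
#' case-sensitive (C locale), so `"Rip1"` sorts after `"RIP1"`.
#'
#' @param a,b non-empty protein identifiers.
#' @return a character vector of length 2, `c(min, max)`; self-pairs are
#'   returned unchanged.
#' @examples
#' canonicalize_pair("QCR2", "COR1")
#' @export
canonicalize_pair <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      !nzchar(a) || !nzchar(b)) {
    pd_stop("canonicalize_pair() needs two non-empty identifiers")
  }
  # C-locale byte comparison, independent of the session collation
  if (compare_c(a, b) <= 0L) c(a, b) else c(b, a)
}

# case-sensitive C-locale comparison: negative, zero or positive
compare_c <- function(a, b) {
  if (a == b) return(0L)
  sorted <- sort(c(a, b), method = "radix")
  if (sorted[1L] == a) -1L else 1L
}

# vectorised canonical ordering of two identifier columns
order_pairs <- function(a, b) {
  swap <- vapply(seq_along(a), function(i) compare_c(a[i], b[i]) > 0L,
                 logical(1))
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' Construct a table of interaction records
#'
#' An interaction record is one physical interaction between two proteins
#' together with its provenance: the set of source tags (semicolon-joined,
#' e.g. `"APID;BioGRID"`) and the number of independent observations
#' (`evidence_count`).  Evidence multiplicity is recorded but never used as
#' an edge weight, because weighting by observation count favours the most
#' studied proteins.
#'
#' @param partner_a,partner_b protein identifiers (raw or canonical).
#' @param sources character vector of source tags (recycled).
#' @param evidence_count positive integers (recycled).
#' @param is_physical logical (recycled); genetic interactions are excluded
#'   from networks, so retained records are physical.
#' @return a `data.frame` with columns `partner_a`, `partner_b`, `sources`,
#'   `evidence_count`, `is_physical`, each pair stored in canonical order.
#' @export
interaction_records <- function(partner_a, partner_b, sources = "local",
                                evidence_count = 1L, is_physical = TRUE) {
  if (length(partner_a) != length(partner_b)) {
    pd_stop("partner_a and partner_b must have the same length")
  }
  if (length(partner_a) == 0L) return(empty_records())
  if (any(is.na(partner_a)) || any(is.na(partner_b)) ||
      !all(nzchar(partner_a)) || !all(nzchar(partner_b))) {
    pd_stop("interaction records need non-empty partner identifiers")
  }
  p <- order_pairs(as.character(partner_a), as.character(partner_b))
  data.frame(partner_a = p$a, partner_b = p$b,
             sources = as.character(sources),
             evidence_count = as.integer(evidence_count),
             is_physical = as.logical(is_physical),
             stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(partner_a = character(), partner_b = character(),
             sources = character(), evidence_count = integer(),
             is_physical = logical(), stringsAsFactors = FALSE)
}

split_tags <- function(x) strsplit(x, ";", fixed = TRUE)

join_tags <- function(tags) {
  paste(sort(unique(tags), method = "radix"), collapse = ";")
}

#' Collapse duplicate interaction records
#'
#' Records describing the same unordered pair are merged into one: source
#' tags are unioned and evidence counts summed, so each unique interaction
#' is kept only once.
#'
#' @param records a record table from [interaction_records()] or a parser.
#' @return a deduplicated record table in stable (lexicographic) pair order.
#' @export
dedup_records <- function(records) {
  if (nrow(records) == 0L) return(empty_records())
  key <- pair_key(records$partner_a, records$partner_b)
  groups <- split(seq_len(nrow(records)), key)
  keys <- names(groups)
  first <- vapply(groups, `[[`, integer(1), 1L)
  out <- data.frame(
    partner_a = records$partner_a[first],
    partner_b = records$partner_b[first],
    sources = vapply(groups, function(i) {
      join_tags(unlist(split_tags(records$sources[i])))
    }, character(1)),
    evidence_count = vapply(groups, function(i) {
      sum(records$evidence_count[i])
    }, integer(1)),
    is_physical = vapply(groups, function(i) {
      all(records$is_physical[i])
    }, logical(1)),
    stringsAsFactors = FALSE)
  ord <- order(out$partner_a, out$partner_b, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
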