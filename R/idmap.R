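#' Read an identifier-mapping table
#'
#' Interaction databases name the same yeast protein differently: one by
#' UniProt accession, another by standard gene name, a third by ordered
#' locus name.  Before snapshots can be merged every record must be
#' expressed in one namespace.  The map is a two-column TSV
#' (`alias<TAB>canonical`); canonical names are upper-cased on ingestion
#' and always map to themselves, and no alias may map to two distinct
#' canonical names.
#'
#' @param file path to the TSV (ignored when `text` is given).
#' @param text optional character vector of lines.
#' @return a named character vector: `names()` are aliases, values the
#'   canonical names.
#' @export
read_idmap <- function(file, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  alias <- character(); canon <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (is_skippable(line)) next
    f <- split_fields(line)
    if (f[1L] == "alias") next                          # optional header
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      pd_stop("line %d (idmap): expected alias<TAB>canonical", i)
    }
    alias <- c(alias, f[1L]); canon <- c(canon, toupper(f[2L]))
  }
  build_idmap(alias, canon)
}

#' @rdname read_idmap
#' @param alias,canonical character vectors of equal length.
#' @export
build_idmap <- function(alias, canonical) {
  canonical <- toupper(canonical)
  # canonical names are fixed points of the map
  alias <- c(alias, unique(canonical))
  canonical <- c(canonical, unique(canonical))
  keep <- !duplicated(paste(alias, canonical, sep = "\r"))
  alias <- alias[keep]; canonical <- canonical[keep]
  dup <- alias[duplicated(alias)]
  if (length(dup) > 0L) {
    pd_stop("idmap is not single-valued; ambiguous alias(es): %s",
            paste(unique(dup), collapse = ", "))
  }
  stats::setNames(canonical, alias)
}

#' Replace record identifiers by canonical names
#'
#' @param records a record table.
#' @param idmap a named vector from [read_idmap()] / [build_idmap()].
#' @param on_unmapped `"drop"` (default) discards records containing an
#'   alias missing from the map, with a warning listing them; `"fail"`
#'   raises an error instead.
#' @return the record table over canonical names, pairs re-ordered
#'   canonically.
#' @export
apply_idmap <- function(records, idmap, on_unmapped = c("drop", "fail")) {
  on_unmapped <- match.arg(on_unmapped)
  if (nrow(records) == 0L) return(records)
  ca <- unname(idmap[records$partner_a])
  cb <- unname(idmap[records$partner_b])
  missing_alias <- unique(c(records$partner_a[is.na(ca)],
                            records$partner_b[is.na(cb)]))
  if (length(missing_alias) > 0L) {
    if (on_unmapped == "fail") {
      pd_stop("unmapped alias(es): %s", paste(missing_alias, collapse = ", "))
    }
    warning(sprintf("dropping %d record(s) with unmapped alias(es): %s",
                    sum(is.na(ca) | is.na(cb)),
                    paste(missing_alias, collapse = ", ")),
            call. = FALSE)
  }
  keep <- !is.na(ca) & !is.na(cb)
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_records())
  p <- order_pairs(ca[keep], cb[keep])
  out$partner_a <- p$a
  out$partner_b <- p$b
  rownames(out) <- NULL
  out
}
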