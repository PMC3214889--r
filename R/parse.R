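#' Parse an interaction snapshot file
#'
#' Reads one of three tab-delimited dialects into a table of interaction
#' records:
#'
#' * `simple_tsv` — columns `partner_a`, `partner_b` and an optional third
#'   `source` column; a header line is optional and `#` lines are comments.
#' * `biogrid_tab` — a BioGRID tab-format subset with five used columns:
#'   systematic name A, systematic name B, official symbol A, official
#'   symbol B, and the experimental-system type (`physical` / `genetic`).
#'   Rows whose system type is genetic are dropped: genetic screens cover
#'   genes very unevenly, so keeping them would unbalance the network.
#'   Extra columns are ignored (snapshot formats drift across releases).
#' * `psimitab` — PSI-MI TAB 2.5: columns 1-2 hold `db:accession`
#'   interactor identifiers (the bare accession is extracted), column 7 the
#'   detection method (logged only).
#'
#' @param file path to a snapshot file (ignored when `text` is given).
#' @param dialect one of `"simple_tsv"`, `"biogrid_tab"`, `"psimitab"`.
#' @param text optional character vector of lines, for in-memory parsing.
#' @param source_tag tag recorded on every record; defaults to the dialect
#'   name.
#' @return a record table (see [interaction_records()]); one record per
#'   retained data line, not deduplicated.
#' @seealso [dedup_records()], [apply_idmap()], [build_network()]
#' @export
parse_interactions <- function(file, dialect = c("simple_tsv", "biogrid_tab",
                                                 "psimitab"),
                               text = NULL, source_tag = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  tag <- source_tag %||% dialect
  switch(dialect,
         simple_tsv = parse_simple_tsv(lines, tag),
         biogrid_tab = parse_biogrid_tab(lines, tag),
         psimitab = parse_psimitab(lines, tag))
}

split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1L]]

is_skippable <- function(line) !nzchar(trimws(line)) || startsWith(line, "#")

parse_simple_tsv <- function(lines, tag) {
  a <- character(); b <- character(); src <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (is_skippable(line)) next
    f <- split_fields(line)
    if (f[1L] == "partner_a") next                      # optional header
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      pd_stop("line %d (simple_tsv): expected at least 2 tab-separated fields",
              i)
    }
    a <- c(a, f[1L]); b <- c(b, f[2L])
    src <- c(src, if (length(f) >= 3L && nzchar(f[3L])) f[3L] else tag)
  }
  interaction_records(a, b, sources = src)
}

parse_biogrid_tab <- function(lines, tag) {
  a <- character(); b <- character()
  n_genetic <- 0L
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (is_skippable(line)) next
    f <- split_fields(line)
    if (f[1L] %in% c("systematic_name_a", "INTERACTOR_A")) next   # header
    if (length(f) < 5L) {
      pd_stop("line %d (biogrid_tab): expected at least 5 tab-separated fields",
              i)
    }
    type <- tolower(f[5L])
    if (!type %in% c("physical", "genetic")) {
      pd_stop("line %d (biogrid_tab): unknown experimental system type '%s'",
              i, f[5L])
    }
    if (type == "genetic") { n_genetic <- n_genetic + 1L; next }
    # prefer the official symbol; fall back to the systematic name
    pa <- if (nzchar(f[3L]) && f[3L] != "-") f[3L] else f[1L]
    pb <- if (nzchar(f[4L]) && f[4L] != "-") f[4L] else f[2L]
    if (!nzchar(pa) || !nzchar(pb)) {
      pd_stop("line %d (biogrid_tab): empty interactor identifier", i)
    }
    a <- c(a, pa); b <- c(b, pb)
  }
  if (n_genetic > 0L) {
    pd_log("biogrid_tab: dropped %d genetic interaction row(s)", n_genetic)
  }
  interaction_records(a, b, sources = tag)
}

strip_db_prefix <- function(x) sub("^[^:]*:", "", x)

parse_psimitab <- function(lines, tag) {
  a <- character(); b <- character()
  methods <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (is_skippable(line)) next
    f <- split_fields(line)
    if (length(f) < 2L) {
      pd_stop("line %d (psimitab): expected at least 2 tab-separated fields", i)
    }
    pa <- strip_db_prefix(f[1L]); pb <- strip_db_prefix(f[2L])
    if (!nzchar(pa) || !nzchar(pb)) {
      pd_stop("line %d (psimitab): empty interactor identifier", i)
    }
    a <- c(a, pa); b <- c(b, pb)
    if (length(f) >= 7L) methods <- c(methods, f[7L])
  }
  if (length(methods) > 0L) {
    pd_log("psimitab: %d record(s), %d with a detection method annotation",
           length(a), sum(nzchar(methods)))
  }
  interaction_records(a, b, sources = tag)
}

#' Serialize interaction records as simple_tsv
#'
#' @param records a record table.
#' @param file output path.
#' @param header write the column header line (default `TRUE`).
#' @return `file`, invisibly.
#' @export
write_interactions <- function(records, file, header = TRUE) {
  lines <- character()
  if (header) lines <- "partner_a\tpartner_b\tsource"
  if (nrow(records) > 0L) {
    lines <- c(lines, paste(records$partner_a, records$partner_b,
                            records$sources, sep = "\t"))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a seed-protein list
#'
#' One protein per line with an optional tab-separated role tag (`core`,
#' `supernumerary` or `assembly_factor`); `#` lines are comments.  Names
#' are upper-cased: standard (SGD-style) gene names are upper-case by
#' convention.
#'
#' @param file path to the seed list.
#' @param text optional character vector of lines.
#' @return a `data.frame` with columns `protein` and `role`.
#' @export
read_seed_list <- function(file, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  proteins <- character(); roles <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (is_skippable(line)) next
    f <- split_fields(line)
    proteins <- c(proteins, toupper(f[1L]))
    roles <- c(roles, if (length(f) >= 2L && nzchar(f[2L])) f[2L] else "core")
  }
  if (length(proteins) == 0L) pd_stop("seed list is empty")
  if (anyDuplicated(proteins)) {
    pd_stop("duplicated seed protein(s): %s",
            paste(unique(proteins[duplicated(proteins)]), collapse = ", "))
  }
  bad <- setdiff(unique(roles), c("core", "supernumerary", "assembly_factor"))
  if (length(bad) > 0L) {
    pd_stop("unknown seed role(s): %s", paste(bad, collapse = ", "))
  }
  data.frame(protein = proteins, role = roles, stringsAsFactors = FALSE)
}

#' @rdname read_seed_list
#' @param seeds a seed `data.frame` or plain character vector.
#' @export
seed_names <- function(seeds) {
  if (is.data.frame(seeds)) as.character(seeds$protein)
  else as.character(seeds)
}
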