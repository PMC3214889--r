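#' A local interaction-database snapshot
#'
#' A snapshot is the full set of physical interaction records downloaded
#' from one database at one point in time, identified by a source tag.
#' Records are canonicalized (pairs ordered, identifiers mapped) before the
#' snapshot is queried.
#'
#' @param name source tag, e.g. `"APID"` or `"BioGRID"`.
#' @param records a record table; non-physical records are rejected.
#' @return an object of class `ppi_snapshot`.
#' @export
ppi_snapshot <- function(name, records) {
  if (!nzchar(name)) pd_stop("snapshot needs a non-empty name")
  if (nrow(records) > 0L && !all(records$is_physical)) {
    pd_stop("snapshot '%s' contains non-physical records", name)
  }
  records$sources <- rep(name, nrow(records))
  structure(list(name = name, records = dedup_records(records)),
            class = "ppi_snapshot")
}

#' @export
print.ppi_snapshot <- function(x, ...) {
  cat(sprintf("<ppi_snapshot '%s': %d unique records, %d proteins>\n",
              x$name, nrow(x$records),
              length(unique(c(x$records$partner_a, x$records$partner_b)))))
  invisible(x)
}

record_endpoints <- function(records) {
  unique(c(records$partner_a, records$partner_b))
}

#' Interactions touching a set of proteins
#'
#' Returns every snapshot record with at least one endpoint in `proteins`
#' (the direct interactions of the query set), deduplicated.
#'
#' @param snapshot a [ppi_snapshot()].
#' @param proteins character vector of canonical names.
#' @return a record table.
#' @export
direct_interactions <- function(snapshot, proteins) {
  proteins <- seed_names(proteins)
  r <- snapshot$records
  keep <- r$partner_a %in% proteins | r$partner_b %in% proteins
  dedup_records(r[keep, , drop = FALSE])
}

#' Level-1.5 neighborhood of a seed list
#'
#' The seed-centred sub-interactome used as the primary list: the union of
#' (i) every interaction with at least one seed endpoint and (ii) every
#' interaction between two proteins that each have at least one direct
#' interaction with some seed in the snapshot.  This is the "level 1.5"
#' expansion — direct partners plus the edges among them.
#'
#' @param snapshot a [ppi_snapshot()].
#' @param seeds seed list (`data.frame` from [read_seed_list()] or names).
#' @return a deduplicated record table.
#' @export
level15_neighborhood <- function(snapshot, seeds) {
  seeds <- seed_names(seeds)
  if (length(seeds) == 0L) pd_stop("seed list is empty")
  r <- snapshot$records
  touches_seed <- r$partner_a %in% seeds | r$partner_b %in% seeds
  # proteins with >= 1 direct seed interaction (the seeds' partners, and
  # any seed that itself appears in such a record)
  direct_set <- record_endpoints(r[touches_seed, , drop = FALSE])
  among_direct <- r$partner_a %in% direct_set & r$partner_b %in% direct_set
  dedup_records(r[touches_seed | among_direct, , drop = FALSE])
}

#' Expansion interactions for proteins new to the second source
#'
#' Step 3 of the assembly: proteins present in `list2` but absent from
#' `list1` are "new"; the snapshot is searched for physical interactions
#' joining a new protein to a non-seed protein of `list1`, to recover the
#' functional environment of the new proteins.  Records already present in
#' `list1` or `list2` are excluded, as are interactions among the new
#' proteins themselves (only new-to-known joins are added).
#'
#' @param list1,list2 record tables (canonicalized).
#' @param snapshot the snapshot the delta is drawn from (the updated
#'   database that produced `list2`).
#' @param seeds seed list.
#' @return a deduplicated record table (possibly empty).
#' @export
expansion_delta <- function(list1, list2, snapshot, seeds) {
  seeds <- seed_names(seeds)
  e1 <- record_endpoints(list1)
  new_proteins <- setdiff(record_endpoints(list2), e1)
  targets <- setdiff(e1, seeds)
  if (length(new_proteins) == 0L || length(targets) == 0L) {
    return(empty_records())
  }
  r <- snapshot$records
  join <- (r$partner_a %in% new_proteins & r$partner_b %in% targets) |
          (r$partner_b %in% new_proteins & r$partner_a %in% targets)
  seen <- c(pair_key(list1$partner_a, list1$partner_b),
            pair_key(list2$partner_a, list2$partner_b))
  fresh <- !pair_key(r$partner_a, r$partner_b) %in% seen
  dedup_records(r[join & fresh, , drop = FALSE])
}

#' Merge interaction lists into one un-weighted network
#'
#' The union of all lists with unique edges; per-edge source sets are the
#' union of the contributing records' tags, so the result is independent of
#' the order of the input lists.
#'
#' @param ... record tables.
#' @return an `igraph` network (see [build_network()]).
#' @export
merge_lists <- function(...) {
  lists <- list(...)
  lists <- lists[vapply(lists, nrow, integer(1)) > 0L]
  if (length(lists) == 0L) return(build_network(empty_records()))
  build_network(do.call(rbind, lists))
}

#' Five-step assembly of the merged seed-centred network
#'
#' Reproduces the snapshot-merging construction: (1) the level-1.5
#' neighborhood of the seeds in the first snapshot gives list 1, and the
#' direct interactions of the seeds in the second snapshot give list 2;
#' (2) identifiers are unified beforehand via [apply_idmap()]; (3) the
#' functional environment of proteins new to the second source is added as
#' list 3 ([expansion_delta()]); (4) the three lists are merged with
#' redundancy eliminated; (5) the result is an un-weighted network.  Seeds
#' absent from every snapshot are reported with a warning, not dropped
#' silently — mitochondrially-encoded proteins are often missing from
#' interaction screens.
#'
#' @param snapshot1,snapshot2 [ppi_snapshot()] objects (canonical names).
#' @param seeds seed list.
#' @return a list of class `ppi_assembly`: `network`, the three
#'   intermediate lists (`list1`, `list2`, `list3`) and `missing_seeds`.
#' @export
assemble_network <- function(snapshot1, snapshot2, seeds) {
  seed_nm <- seed_names(seeds)
  list1 <- level15_neighborhood(snapshot1, seed_nm)
  list2 <- direct_interactions(snapshot2, seed_nm)
  list3 <- expansion_delta(list1, list2, snapshot2, seed_nm)
  network <- merge_lists(list1, list2, list3)
  missing <- setdiff(seed_nm, node_names(network))
  if (length(missing) > 0L) {
    warning(sprintf("seed protein(s) absent from all snapshots: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  pd_log("assembled network: %d proteins, %d unique interactions (list1 %d, list2 %d, list3 %d)",
         igraph::vcount(network), igraph::ecount(network),
         nrow(list1), nrow(list2), nrow(list3))
  structure(list(network = network, list1 = list1, list2 = list2,
                 list3 = list3, missing_seeds = missing),
            class = "ppi_assembly")
}

#' Classify merged edges by source
#'
#' @param network a merged network whose edges carry `sources` tags.
#' @return a table (named integer vector) counting edges per source-set,
#'   e.g. `APID;BioGRID`, `APID`, `BioGRID`.
#' @export
source_attribution <- function(network) {
  src <- igraph::edge_attr(network, "sources")
  if (is.null(src)) pd_stop("network has no 'sources' edge attribute")
  tab <- table(src)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out), method = "radix")]
}
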