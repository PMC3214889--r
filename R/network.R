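#' Build an un-weighted PPI network from interaction records
#'
#' Duplicate pairs (including symmetric duplicates) collapse to a single
#' edge whose `sources` attribute is the union of the records' source tags;
#' the node set is the union of all endpoints.  The graph is undirected and
#' un-weighted — each interaction counts once regardless of how many
#' experiments observed it — and self-interactions (homodimers) are kept as
#' loop edges.  Vertices are stored in lexicographic order so that all
#' downstream output is stable.
#'
#' @param records a record table; identifiers are expected to be canonical
#'   already (see [apply_idmap()]).
#' @param nodes optional extra node names to include even if isolated.
#' @return an `igraph` undirected graph with vertex attribute `name` and
#'   edge attributes `sources` and `evidence_count`.
#' @export
build_network <- function(records, nodes = character()) {
  records <- dedup_records(records)
  vnames <- sort(unique(c(records$partner_a, records$partner_b,
                          as.character(nodes))), method = "radix")
  g <- igraph::graph_from_data_frame(
    d = records[, c("partner_a", "partner_b", "sources", "evidence_count")],
    directed = FALSE,
    vertices = data.frame(name = vnames, stringsAsFactors = FALSE))
  g
}

node_names <- function(network) igraph::V(network)$name

edge_ends_matrix <- function(network) {
  igraph::ends(network, igraph::E(network), names = TRUE)
}

# edge table with canonically ordered endpoints
network_edges <- function(network) {
  e <- edge_ends_matrix(network)
  if (nrow(e) == 0L) {
    return(data.frame(partner_a = character(), partner_b = character(),
                      sources = character(), stringsAsFactors = FALSE))
  }
  p <- order_pairs(e[, 1L], e[, 2L])
  src <- igraph::edge_attr(network, "sources") %||% rep("local", nrow(e))
  out <- data.frame(partner_a = p$a, partner_b = p$b, sources = src,
                    stringsAsFactors = FALSE)
  ord <- order(out$partner_a, out$partner_b, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recover the interaction records of a network
#'
#' The inverse of [build_network()] up to isolated nodes: one record per
#' edge, in stable lexicographic order, carrying the edge's source tags.
#'
#' @param network a graph from [build_network()].
#' @return a record table.
#' @export
network_records <- function(network) {
  ed <- network_edges(network)
  if (nrow(ed) == 0L) return(empty_records())
  interaction_records(ed$partner_a, ed$partner_b, sources = ed$sources)
}

#' Theoretical-maximum pair density
#'
#' Density of a node set with `m` internal edges when self-interactions are
#' permitted: the number of theoretically possible edges among `n` nodes is
#' the number of unordered pairs with repetition, `n(n+1)/2`.
#'
#' @param n_nodes number of nodes.
#' @param m_edges number of internal edges (self-loops counted once).
#' @return `m_edges / (n_nodes * (n_nodes + 1) / 2)`.
#' @export
pair_density <- function(n_nodes, m_edges) {
  if (n_nodes < 1L) pd_stop("density needs at least one node")
  m_edges / (n_nodes * (n_nodes + 1) / 2)
}

#' Internal / boundary edge statistics of a node set
#'
#' Classifies every network edge relative to `members`: internal edges have
#' both endpoints inside (self-loops count once), boundary edges exactly
#' one.  Density divides the internal count by the `n(n+1)/2` possible
#' pairs (self-interactions permitted); quality (cohesiveness) is
#' `m_internal / (m_internal + m_boundary)`, defined as 1 when the node set
#' touches no edge at all.
#'
#' @param members character vector of node names, a subset of the network.
#' @param network a graph from [build_network()].
#' @return a list with `n_nodes`, `m_internal`, `m_boundary`, `density`,
#'   `quality` and `p_value` (left `NA`; see [cluster_significance()]).
#' @export
cluster_stats <- function(members, network) {
  members <- unique(as.character(members))
  if (length(members) < 1L) pd_stop("cluster_stats() needs >= 1 member")
  missing <- setdiff(members, node_names(network))
  if (length(missing) > 0L) {
    pd_stop("member(s) not in network: %s", paste(missing, collapse = ", "))
  }
  e <- edge_ends_matrix(network)
  n_in <- (e[, 1L] %in% members) + (e[, 2L] %in% members)
  m_internal <- sum(n_in == 2L)
  m_boundary <- sum(n_in == 1L)
  n <- length(members)
  list(n_nodes = n,
       m_internal = m_internal,
       m_boundary = m_boundary,
       density = pair_density(n, m_internal),
       quality = if (m_internal + m_boundary > 0L) {
         m_internal / (m_internal + m_boundary)
       } else 1,
       p_value = NA_real_)
}

# ---- fast index used by the growth / weighting engines --------------------
#
# adjacency as integer lists with loops removed; `loop` flags nodes carrying
# a self-edge (each contributes 1 internal edge, never a boundary edge)
net_index <- function(network) {
  nv <- igraph::vcount(network)
  names <- node_names(network)
  loops <- igraph::which_loop(network)
  g0 <- if (any(loops)) {
    igraph::delete_edges(network, igraph::E(network)[loops])
  } else network
  adj <- lapply(igraph::as_adj_list(g0, mode = "all"), as.integer)
  # collapse multi-edges defensively; build_network already deduplicates
  adj <- lapply(adj, function(v) sort(unique(v)))
  loop <- logical(nv)
  if (any(loops)) {
    le <- igraph::ends(network, igraph::E(network)[loops], names = FALSE)
    loop[unique(le[, 1L])] <- TRUE
  }
  list(names = names, adj = adj, deg = lengths(adj), loop = loop, nv = nv)
}

#' Export a network as SIF
#'
#' One `node<TAB>pp<TAB>node` line per edge in stable lexicographic order;
#' isolated nodes are written as single-field lines, the SIF convention.
#'
#' @param network a graph from [build_network()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sif <- function(network, file) {
  ed <- network_edges(network)
  lines <- if (nrow(ed) > 0L) {
    paste(ed$partner_a, "pp", ed$partner_b, sep = "\t")
  } else character()
  isolated <- setdiff(node_names(network),
                      unique(c(ed$partner_a, ed$partner_b)))
  writeLines(c(lines, sort(isolated, method = "radix")), file)
  invisible(file)
}

#' Export a network as GraphML
#'
#' @inheritParams write_sif
#' @export
write_network_graphml <- function(network, file) {
  igraph::write_graph(network, file, format = "graphml")
  invisible(file)
}
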