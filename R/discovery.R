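#' Pick the cluster that best covers the seed list
#'
#' The recursion of the pipeline follows the cluster holding the complex:
#' the one containing the most seed proteins.  Ties are broken by higher
#' quality, then smaller size, then lexicographic member order.
#'
#' @param clusters a `cluster_set` or list of clusters.
#' @param seeds seed list.
#' @return the selected cluster (a list with `id`, `members`, `stats`).
#' @export
select_target_cluster <- function(clusters, seeds) {
  if (length(clusters) == 0L) pd_stop("no clusters to select from")
  seed_nm <- seed_names(seeds)
  coverage <- vapply(clusters, function(cl) {
    length(intersect(cl$members, seed_nm))
  }, integer(1))
  if (max(coverage) == 0L) {
    pd_stop(paste("no cluster contains a seed protein; consider loosening",
                  "the clustering filters (min_density, max_pvalue)"))
  }
  quality <- vapply(clusters, function(cl) cl$stats$quality, numeric(1))
  size <- vapply(clusters, function(cl) length(cl$members), integer(1))
  keys <- vapply(clusters, function(cl) paste(cl$members, collapse = ";"),
                 character(1))
  o <- order(-coverage, -quality, size, keys, method = "radix")
  clusters[[o[1L]]]
}

#' Residual proteins of a parent cluster
#'
#' The parent members minus the union of its child clusters' members —
#' the proteins that no dense sub-cluster captured.
#'
#' @param parent a cluster (or character vector of members).
#' @param children list of child clusters (or character vectors).
#' @return sorted character vector of residual node names.
#' @export
subtract_residual <- function(parent, children) {
  pm <- if (is.list(parent) && !is.null(parent$members)) parent$members
        else as.character(parent)
  cm <- lapply(children, function(ch) {
    if (is.list(ch) && !is.null(ch$members)) ch$members else as.character(ch)
  })
  stray <- setdiff(unique(unlist(cm)), pm)
  if (length(stray) > 0L) {
    pd_stop("child member(s) outside the parent cluster: %s",
            paste(sort(stray), collapse = ", "))
  }
  sort(setdiff(pm, unlist(cm)), method = "radix")
}

#' Anchor-connected candidate proteins of a residual set
#'
#' Keeps the residual proteins with at least one edge to an anchor subunit
#' and ranks them by the number of anchor edges (descending), then by the
#' number of edges to seed proteins (descending), then by name.  Residual
#' proteins that are themselves seeds are annotated `"seed"` and ranked
#' last — they are known complex members, not discoveries.
#'
#' @param residual character vector from [subtract_residual()].
#' @param anchors non-empty character vector of anchor subunits (network
#'   nodes).
#' @param network a graph from [build_network()].
#' @param seeds seed list.
#' @return an object of class `candidate_report`: `residual`, `anchors`,
#'   and a ranked `candidates` data.frame with columns `protein`,
#'   `n_edges_to_anchors`, `n_edges_to_seeds`, `annotation`.
#' @export
anchor_candidates <- function(residual, anchors, network, seeds) {
  anchors <- unique(as.character(anchors))
  if (length(anchors) == 0L) pd_stop("anchor set is empty")
  missing <- setdiff(anchors, node_names(network))
  if (length(missing) > 0L) {
    pd_stop("anchor(s) not in network: %s", paste(missing, collapse = ", "))
  }
  seed_nm <- seed_names(seeds)
  residual <- sort(unique(as.character(residual)), method = "radix")
  ix <- net_index(network)
  counts <- lapply(residual, function(p) {
    nb <- ix$names[ix$adj[[match(p, ix$names)]]]
    list(anchors = sum(nb %in% anchors), seeds = sum(nb %in% seed_nm))
  })
  n_anchor <- vapply(counts, `[[`, numeric(1), "anchors")
  n_seed <- vapply(counts, `[[`, numeric(1), "seeds")
  keep <- n_anchor >= 1
  df <- data.frame(protein = residual[keep],
                   n_edges_to_anchors = as.integer(n_anchor[keep]),
                   n_edges_to_seeds = as.integer(n_seed[keep]),
                   annotation = ifelse(residual[keep] %in% seed_nm,
                                       "seed", ""),
                   stringsAsFactors = FALSE)
  o <- order(df$annotation == "seed", -df$n_edges_to_anchors,
             -df$n_edges_to_seeds, df$protein, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(parent = NA_character_, residual = residual,
                 anchors = sort(anchors, method = "radix"),
                 candidates = df),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report: %d residual protein(s), %d candidate(s); anchors: %s>\n",
              length(x$residual), nrow(x$candidates),
              paste(x$anchors, collapse = ", ")))
  if (nrow(x$candidates) > 0L) print(x$candidates)
  invisible(x)
}

# ---- recursive partitioning ------------------------------------------------

new_tree_node <- function(id, members, stats, algorithm, parent) {
  list(id = id, members = members, stats = stats, algorithm = algorithm,
       parent = parent, children = character())
}

#' Recursive partitioning of a network along the seed-richest path
#'
#' Applies the overlapping clustering to the current induced subgraph and
#' recurses into the seed-richest accepted cluster.  A branch is declared
#' unsplittable — and handed to the disjoint algorithm exactly once —
#' when the overlapping step returns no accepted cluster, or a single
#' cluster covering at least `cover_fraction` of the input's nodes, or no
#' cluster containing a seed, or when `max_depth` is reached.  Every split
#' is recorded in the returned tree; cluster statistics are computed
#' within the subgraph in which each cluster was found.
#'
#' @param network a graph from [build_network()].
#' @param seeds seed list.
#' @param params [cluster_params()] for the overlapping stage.
#' @param mparams [mcode_params()] for the terminal disjoint split.
#' @param max_depth maximum number of overlapping splits (default 5).
#' @param cover_fraction the "cannot split further" coverage threshold
#'   (default 0.95).
#' @return an object of class `cluster_tree`: `nodes` (named list of tree
#'   nodes), `mcode_parent` (id of the node split by the disjoint
#'   algorithm, or `NA`), and the `network`.
#' @export
partition_recursive <- function(network, seeds, params = cluster_params(),
                                mparams = mcode_params(), max_depth = 5L,
                                cover_fraction = 0.95) {
  if (max_depth < 1L) pd_stop("max_depth must be >= 1")
  all_nodes <- sort(node_names(network), method = "radix")
  root_stats <- cluster_stats(all_nodes, network)
  nodes <- list(net = new_tree_node("net", all_nodes, root_stats, "root",
                                    NA_character_))
  cur_id <- "net"
  mcode_parent <- NA_character_
  for (depth in seq_len(max_depth)) {
    cur <- nodes[[cur_id]]
    sub <- igraph::induced_subgraph(network, cur$members)
    cs <- suppressWarnings(cluster_one(sub, params))
    unsplittable <- length(cs) == 0L ||
      (length(cs) == 1L &&
         length(cs[[1L]]$members) >= cover_fraction * length(cur$members))
    target <- NULL
    if (!unsplittable) {
      target <- tryCatch(select_target_cluster(cs, seeds),
                         error = function(e) NULL)
      if (is.null(target)) unsplittable <- TRUE
    }
    if (unsplittable || depth == max_depth) {
      mc <- mcode_complexes(sub, mparams)
      for (i in seq_along(mc)) {
        cid <- child_id(cur_id, i)
        nodes[[cid]] <- new_tree_node(cid, mc[[i]]$members, mc[[i]]$stats,
                                      "mcode", cur_id)
        nodes[[cur_id]]$children <- c(nodes[[cur_id]]$children, cid)
      }
      mcode_parent <- cur_id
      break
    }
    target_id <- NA_character_
    for (i in seq_along(cs)) {
      cid <- child_id(cur_id, i)
      nodes[[cid]] <- new_tree_node(cid, cs[[i]]$members, cs[[i]]$stats,
                                    "clusterone", cur_id)
      nodes[[cur_id]]$children <- c(nodes[[cur_id]]$children, cid)
      if (identical(cs[[i]]$members, target$members) && is.na(target_id)) {
        target_id <- cid
      }
    }
    cur_id <- target_id
  }
  structure(list(nodes = nodes, mcode_parent = mcode_parent,
                 network = network),
            class = "cluster_tree")
}

child_id <- function(parent_id, i) {
  if (parent_id == "net") as.character(i) else paste0(parent_id, ".", i)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree: %d node(s); disjoint split at '%s'>\n",
              length(x$nodes), x$mcode_parent))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.cluster_tree <- function(x, ...) {
  out <- do.call(rbind, lapply(x$nodes, function(nd) {
    data.frame(id = nd$id, parent = nd$parent, algorithm = nd$algorithm,
               n_nodes = nd$stats$n_nodes, m_internal = nd$stats$m_internal,
               m_boundary = nd$stats$m_boundary,
               density = nd$stats$density, quality = nd$stats$quality,
               p_value = if (is.null(nd$stats$p_value)) NA_real_ else
                 nd$stats$p_value,
               members = paste(nd$members, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' End-to-end candidate discovery
#'
#' Runs [partition_recursive()], subtracts the disjoint child clusters from
#' the node they partitioned, and reports the residual proteins connected
#' to the anchor subunits.  By default the anchors are the seed proteins
#' found in the highest-scoring disjoint child containing seeds — the
#' complex subunits that ended up clustered with the neighboring complex —
#' mirroring the way residual candidates attach to a complex through a few
#' anchor subunits.
#'
#' @inheritParams partition_recursive
#' @param anchors optional explicit anchor set overriding the default.
#' @return a list of class `discovery_result` with `tree` and `report`.
#' @export
discover_candidates <- function(network, seeds, params = cluster_params(),
                                mparams = mcode_params(), max_depth = 5L,
                                cover_fraction = 0.95, anchors = NULL) {
  tree <- partition_recursive(network, seeds, params, mparams, max_depth,
                              cover_fraction)
  if (is.na(tree$mcode_parent)) {
    pd_stop("partitioning did not reach a disjoint split")
  }
  parent <- tree$nodes[[tree$mcode_parent]]
  child_ids <- parent$children
  children <- lapply(child_ids, function(id) tree$nodes[[id]])
  residual <- subtract_residual(parent, children)
  if (is.null(anchors)) {
    seed_nm <- seed_names(seeds)
    with_seeds <- vapply(children, function(ch) {
      length(intersect(ch$members, seed_nm)) > 0L
    }, logical(1))
    if (!any(with_seeds)) {
      pd_stop("no disjoint child cluster contains a seed; supply anchors=")
    }
    anchors <- intersect(children[[which(with_seeds)[1L]]]$members, seed_nm)
  }
  report <- anchor_candidates(residual, anchors, network, seeds)
  report$parent <- parent$id
  pd_log("discovery: parent '%s' (%d nodes) minus %d child cluster(s) -> %d residual, %d candidate(s)",
         parent$id, length(parent$members), length(children),
         length(residual), nrow(report$candidates))
  structure(list(tree = tree, report = report), class = "discovery_result")
}

# ---- report files ----------------------------------------------------------

tree_to_plain <- function(tree) {
  list(mcode_parent = tree$mcode_parent,
       nodes = lapply(unname(tree$nodes), function(nd) {
         nd$stats <- nd$stats[c("n_nodes", "m_internal", "m_boundary",
                                "density", "quality", "p_value")]
         nd
       }))
}

#' Write the discovery report files
#'
#' Writes, with stable ordering so repeated runs are byte-identical:
#' `clusters.tsv` (one row per tree node), `candidates.tsv` (the ranked
#' candidate table), `tree.json` (the full tree, re-readable with
#' [read_cluster_tree()]), and `parent_cluster.graphml` (the parent
#' cluster's subgraph with a `role` vertex attribute flagging candidates,
#' anchors and residual nodes).
#'
#' @param tree a `cluster_tree`.
#' @param report a `candidate_report`.
#' @param out_dir output directory (created if needed).
#' @return the four file paths, invisibly.
#' @export
write_report <- function(tree, report, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) pd_stop("cannot create output directory '%s'", out_dir)
  }
  f_clusters <- file.path(out_dir, "clusters.tsv")
  f_cand <- file.path(out_dir, "candidates.tsv")
  f_tree <- file.path(out_dir, "tree.json")
  f_graphml <- file.path(out_dir, "parent_cluster.graphml")
  utils::write.table(as.data.frame(tree), f_clusters, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$candidates, f_cand, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(tree_to_plain(tree), f_tree, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  parent_id <- if (!is.na(report$parent)) report$parent else
    tree$mcode_parent
  parent <- tree$nodes[[parent_id]]
  sub <- igraph::induced_subgraph(tree$network, parent$members)
  role <- rep("member", igraph::vcount(sub))
  nm <- node_names(sub)
  role[nm %in% report$residual] <- "residual"
  role[nm %in% report$candidates$protein] <- "candidate"
  role[nm %in% report$anchors] <- "anchor"
  sub <- igraph::set_vertex_attr(sub, "role", value = role)
  igraph::write_graph(sub, f_graphml, format = "graphml")
  invisible(c(f_clusters, f_cand, f_tree, f_graphml))
}

#' Re-read a tree written by [write_report()]
#'
#' @param path the `tree.json` path.
#' @return a `cluster_tree` without the `network` element.
#' @export
read_cluster_tree <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- lapply(raw$nodes, function(nd) {
    new_node <- new_tree_node(nd$id, unlist(nd$members),
                              lapply(nd$stats, function(x) {
                                if (is.null(x)) NA_real_ else x
                              }),
                              nd$algorithm,
                              if (is.null(nd$parent)) NA_character_ else
                                nd$parent)
    new_node$children <- as.character(unlist(nd$children))
    new_node
  })
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  structure(list(nodes = nodes,
                 mcode_parent = raw$mcode_parent %||% NA_character_,
                 network = NULL),
            class = "cluster_tree")
}
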