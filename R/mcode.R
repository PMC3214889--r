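#' Parameters for disjoint complex detection
#'
#' The published defaults of the molecular-complex-detection procedure:
#' vertex weight percentage 0.2, haircut on, fluff off, expansion depth
#' limit 100, and a minimum core order of 2.
#'
#' @param vwp vertex weight percentage in \[0, 1\]: a neighbor joins a
#'   complex when its weight is at least `(1 - vwp)` times the seed's.
#' @param min_core smallest k-core order that gives a node a non-zero
#'   weight (default 2).
#' @param haircut iteratively remove complex nodes with fewer than two
#'   within-complex neighbors (default `TRUE`).
#' @param fluff add unassigned neighbors whose closed-neighborhood density
#'   reaches `fluff_threshold` (default `FALSE`).
#' @param fluff_threshold density cut-off used when `fluff = TRUE`.
#' @param max_depth breadth-first expansion depth limit (default 100).
#' @return a list of class `mcode_params`.
#' @export
mcode_params <- function(vwp = 0.2, min_core = 2L, haircut = TRUE,
                         fluff = FALSE, fluff_threshold = 0.1,
                         max_depth = 100L) {
  if (vwp < 0 || vwp > 1) pd_stop("vwp must lie in [0, 1]")
  if (min_core < 1L) pd_stop("min_core must be >= 1")
  structure(list(vwp = vwp, min_core = as.integer(min_core),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_threshold = fluff_threshold,
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

#' k-core numbers of every node
#'
#' The core number of a node is the largest k such that the node belongs
#' to a k-core (the maximal subgraph of minimum degree k).  Self-loops are
#' ignored: they carry no neighborhood-density information.
#'
#' @param network a graph from [build_network()].
#' @return a named numeric vector of core numbers.
#' @export
core_numbers <- function(network) {
  g0 <- igraph::simplify(network, remove.multiple = TRUE,
                         remove.loops = TRUE)
  igraph::coreness(g0)
}

# simple-graph density, self-pairs excluded
simple_density <- function(n, m) {
  if (n < 2L) return(0)
  m / (n * (n - 1) / 2)
}

#' Local-neighborhood-density vertex weight
#'
#' Let H be the subgraph induced by the closed neighborhood of the node
#' (the node and its neighbors, self-loops ignored) and k* the highest
#' core order found in H.  The weight is `k*` times the density of the
#' highest k-core of H (self-pairs excluded), or 0 when `k* < min_core`:
#' nodes whose surroundings contain no sufficiently deep core carry no
#' density signal.
#'
#' @param node a node name.
#' @param network a graph from [build_network()].
#' @param params an [mcode_params()] list.
#' @return a non-negative weight.
#' @export
vertex_weight <- function(node, network, params = mcode_params()) {
  w <- vertex_weights(network, params)
  v <- w[node]
  if (is.na(v)) pd_stop("node '%s' is not a network node", node)
  unname(v)
}

#' @rdname vertex_weight
#' @export
vertex_weights <- function(network, params = mcode_params()) {
  g0 <- igraph::simplify(network, remove.multiple = TRUE,
                         remove.loops = TRUE)
  nms <- node_names(g0)
  adj <- igraph::as_adj_list(g0, mode = "all")
  w <- vapply(seq_along(nms), function(v) {
    nb <- c(v, as.integer(adj[[v]]))
    if (length(nb) < 2L) return(0)
    h <- igraph::induced_subgraph(g0, nb)
    cores <- igraph::coreness(h)
    kstar <- max(cores)
    if (kstar < params$min_core) return(0)
    top <- which(cores >= kstar)
    hk <- igraph::induced_subgraph(h, top)
    kstar * simple_density(igraph::vcount(hk), igraph::ecount(hk))
  }, numeric(1))
  stats::setNames(w, nms)
}

# closed-neighborhood density of single nodes, used by the fluff step
neighborhood_density <- function(g0, v, adj) {
  nb <- c(v, as.integer(adj[[v]]))
  if (length(nb) < 2L) return(0)
  h <- igraph::induced_subgraph(g0, nb)
  simple_density(igraph::vcount(h), igraph::ecount(h))
}

#' Disjoint dense-complex detection by vertex-weight expansion
#'
#' Nodes are seeded in decreasing weight order (lexicographic tie-break).
#' From each still-unassigned seed, a breadth-first expansion includes
#' unassigned neighbors whose weight is at least `(1 - vwp)` times the
#' seed weight, up to `max_depth` steps from the seed; a node assigned to
#' one complex is never re-seeded or re-included, so the complexes are
#' node-disjoint.  The optional fluff step then adds unassigned boundary
#' neighbors of sufficient neighborhood density, and the haircut removes
#' complex nodes with fewer than two within-complex neighbors (applied
#' iteratively, so the property holds in the output).  Complexes smaller
#' than 3 nodes are suppressed, and the result is sorted by score
#' (density x size) descending.
#'
#' @param network a graph from [build_network()].
#' @param params an [mcode_params()] list.
#' @return a `cluster_set` of node-disjoint clusters, algorithm tag
#'   `"mcode"`.
#' @export
mcode_complexes <- function(network, params = mcode_params()) {
  if (igraph::vcount(network) == 0L) pd_stop("network is empty")
  g0 <- igraph::simplify(network, remove.multiple = TRUE,
                         remove.loops = TRUE)
  nms <- node_names(g0)
  nv <- length(nms)
  adj <- lapply(igraph::as_adj_list(g0, mode = "all"),
                function(x) sort(as.integer(x)))
  w <- unname(vertex_weights(g0, params))
  seed_order <- order(-w, nms, method = "radix")
  visited <- logical(nv)
  complexes <- list()
  for (s in seed_order) {
    if (visited[s] || w[s] <= 0) next
    thr <- (1 - params$vwp) * w[s]
    members <- integer(0)
    visited[s] <- TRUE
    queue <- s
    depth <- stats::setNames(0L, NULL)
    depths <- integer(nv)
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      members <- c(members, u)
      if (depths[u] >= params$max_depth) next
      for (v in adj[[u]]) {
        if (!visited[v] && w[v] >= thr - 1e-12) {
          visited[v] <- TRUE
          depths[v] <- depths[u] + 1L
          queue <- c(queue, v)
        }
      }
    }
    if (params$fluff) {
      extra <- integer(0)
      for (u in members) {
        for (v in adj[[u]]) {
          if (!visited[v] &&
              neighborhood_density(g0, v, adj) >= params$fluff_threshold) {
            visited[v] <- TRUE
            extra <- c(extra, v)
          }
        }
      }
      members <- c(members, extra)
    }
    if (params$haircut) {
      repeat {
        inside <- logical(nv); inside[members] <- TRUE
        indeg <- vapply(members, function(u) sum(inside[adj[[u]]]),
                        integer(1))
        if (all(indeg >= 2L)) break
        members <- members[indeg >= 2L]
        if (length(members) == 0L) break
      }
    }
    if (length(members) >= 3L) {
      member_names <- sort(nms[members], method = "radix")
      complexes[[length(complexes) + 1L]] <- member_names
    }
  }
  scored <- lapply(complexes, function(members) {
    sub <- igraph::induced_subgraph(g0, members)
    dens <- simple_density(igraph::vcount(sub), igraph::ecount(sub))
    list(members = members, score = dens * length(members))
  })
  if (length(scored) > 0L) {
    o <- order(-vapply(scored, `[[`, numeric(1), "score"),
               -lengths(lapply(scored, `[[`, "members")),
               vapply(scored, function(x) paste(x$members, collapse = ";"),
                      character(1)),
               method = "radix")
    scored <- scored[o]
  }
  clusters <- lapply(scored, function(x) {
    st <- score_cluster(x$members, network)
    list(key = paste(x$members, collapse = ";"), members = x$members,
         stats = c(st, list(score = x$score)))
  })
  set <- make_cluster_set_ordered(clusters, "mcode", params)
  set
}

# keep the caller's ordering (mcode sorts by score, not size)
make_cluster_set_ordered <- function(clusters, algorithm, params) {
  out <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    list(id = as.character(i), members = cl$members, stats = cl$stats,
         provenance = list(algorithm = algorithm, parent = NA_character_))
  })
  structure(out, class = "cluster_set", algorithm = algorithm,
            params = params, log = NULL)
}
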