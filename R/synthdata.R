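#' Specification of a planted-module synthetic PPI network
#'
#' Describes a network with dense planted modules (Bernoulli `intra_p`
#' subgraphs), sparser cross-module edges (`inter_p`), a sparse background
#' (`background_p`), designated anchor nodes inside one module, and
#' low-degree satellite candidates that attach to `satellite_degree`
#' distinct anchors and nowhere else.  The satellites emulate the defining
#' property of residual assembly-factor candidates: too weakly
#' interconnected to survive any dense-cluster filter, yet reliably tied to
#' a couple of anchor subunits.
#'
#' @param module_sizes integer vector of module sizes.
#' @param intra_p within-module edge probability.
#' @param inter_p cross-module edge probability (`inter_p < intra_p`).
#' @param background_p probability of edges involving background nodes.
#' @param overlap_map optional list of `list(a=, b=, n=)` entries declaring
#'   that modules `a` and `b` share `n` nodes.
#' @param anchor_module index of the module holding the anchors.
#' @param n_anchors number of anchor nodes (the first nodes of the module).
#' @param n_satellites number of satellite candidate proteins.
#' @param satellite_degree anchor edges per satellite (must not exceed
#'   `n_anchors`).
#' @param n_background number of background nodes.
#' @param rng_seed integer seed; generation is fully determined by it.
#' @return a list of class `planted_spec`.
#' @export
planted_spec <- function(module_sizes, intra_p = 0.9, inter_p = 0.05,
                         background_p = inter_p, overlap_map = NULL,
                         anchor_module = 1L, n_anchors = 0L,
                         n_satellites = 0L, satellite_degree = 1L,
                         n_background = 0L, rng_seed = 1L) {
  if (length(module_sizes) < 1L || any(module_sizes < 1L)) {
    pd_stop("module_sizes must be positive integers")
  }
  if (!(inter_p >= 0 && inter_p < intra_p && intra_p <= 1)) {
    pd_stop("need 0 <= inter_p < intra_p <= 1")
  }
  if (n_satellites > 0L) {
    if (n_anchors < 1L) pd_stop("satellites need anchor nodes")
    if (satellite_degree < 1L || satellite_degree > n_anchors) {
      pd_stop("satellite_degree must lie in [1, n_anchors]")
    }
  }
  if (n_anchors > module_sizes[anchor_module]) {
    pd_stop("n_anchors exceeds the anchor module size")
  }
  structure(list(module_sizes = as.integer(module_sizes), intra_p = intra_p,
                 inter_p = inter_p, background_p = background_p,
                 overlap_map = overlap_map,
                 anchor_module = as.integer(anchor_module),
                 n_anchors = as.integer(n_anchors),
                 n_satellites = as.integer(n_satellites),
                 satellite_degree = as.integer(satellite_degree),
                 n_background = as.integer(n_background),
                 rng_seed = as.integer(rng_seed)),
            class = "planted_spec")
}

# deterministic module membership over sequentially named nodes; overlap
# entries re-use the first n nodes of module a as members of module b
assign_modules <- function(spec) {
  k <- length(spec$module_sizes)
  members <- vector("list", k)
  next_id <- 1L
  for (m in seq_len(k)) {
    shared <- character(0)
    for (ov in spec$overlap_map %||% list()) {
      if (ov$b == m) {
        donor <- members[[ov$a]]
        if (is.null(donor) || length(donor) < ov$n) {
          pd_stop("overlap_map entry (%d,%d) precedes module %d or exceeds it",
                  ov$a, ov$b, ov$a)
        }
        shared <- c(shared, donor[seq_len(ov$n)])
      }
    }
    n_fresh <- spec$module_sizes[m] - length(shared)
    if (n_fresh < 0L) pd_stop("module %d smaller than its shared nodes", m)
    fresh <- sprintf("P%03d", seq.int(next_id, length.out = n_fresh))
    next_id <- next_id + n_fresh
    members[[m]] <- c(shared, fresh)
  }
  members
}

#' Generate a planted-module network with ground truth
#'
#' Edges are drawn independently: module pairs at `intra_p` (a pair lying
#' in two modules at once is drawn once), cross-module pairs at `inter_p`,
#' pairs involving background nodes at `background_p`; each satellite is
#' then attached to `satellite_degree` distinct anchors chosen at random
#' and receives no other edges.  All randomness derives from
#' `spec$rng_seed`, and isolated nodes are kept in the vertex set.
#'
#' @param spec a [planted_spec()].
#' @return a list: `network` (igraph) and `truth`, a `GroundTruth` list
#'   with `modules`, `anchors`, `satellites` and `background`.
#' @export
planted_network <- function(spec) {
  modules <- assign_modules(spec)
  module_nodes <- sort(unique(unlist(modules)), method = "radix")
  anchors <- modules[[spec$anchor_module]][seq_len(spec$n_anchors)]
  satellites <- if (spec$n_satellites > 0L) {
    sprintf("SAT%02d", seq_len(spec$n_satellites))
  } else character(0)
  background <- if (spec$n_background > 0L) {
    sprintf("BG%03d", seq_len(spec$n_background))
  } else character(0)
  # pair universe, classified once
  intra_pairs <- unique(do.call(rbind, lapply(modules, function(mm) {
    if (length(mm) < 2L) return(NULL)
    t(utils::combn(sort(mm, method = "radix"), 2L))
  })))
  co_key <- if (is.null(intra_pairs)) character(0) else
    pair_key(intra_pairs[, 1L], intra_pairs[, 2L])
  cross_pairs <- if (length(module_nodes) >= 2L) {
    all_mod <- t(utils::combn(module_nodes, 2L))
    all_mod[!pair_key(all_mod[, 1L], all_mod[, 2L]) %in% co_key, ,
            drop = FALSE]
  } else matrix(character(0), ncol = 2L)
  bg_pairs <- if (length(background) > 0L) {
    others <- c(module_nodes, background)
    bg <- expand.grid(a = background, b = others, stringsAsFactors = FALSE)
    bg <- bg[bg$a != bg$b, , drop = FALSE]
    p <- order_pairs(bg$a, bg$b)
    m <- unique(cbind(p$a, p$b))
    m
  } else matrix(character(0), ncol = 2L)
  withr::with_seed(spec$rng_seed, {
    keep_intra <- if (is.null(intra_pairs)) logical(0) else
      stats::rbinom(nrow(intra_pairs), 1L, spec$intra_p) == 1L
    keep_cross <- stats::rbinom(nrow(cross_pairs), 1L, spec$inter_p) == 1L
    keep_bg <- stats::rbinom(nrow(bg_pairs), 1L, spec$background_p) == 1L
    sat_edges <- if (length(satellites) > 0L) {
      do.call(rbind, lapply(satellites, function(s) {
        cbind(s, sample(anchors, spec$satellite_degree))
      }))
    } else matrix(character(0), ncol = 2L)
  })
  a <- c(if (!is.null(intra_pairs)) intra_pairs[keep_intra, 1L],
         cross_pairs[keep_cross, 1L], bg_pairs[keep_bg, 1L],
         sat_edges[, 1L])
  b <- c(if (!is.null(intra_pairs)) intra_pairs[keep_intra, 2L],
         cross_pairs[keep_cross, 2L], bg_pairs[keep_bg, 2L],
         sat_edges[, 2L])
  records <- if (length(a) > 0L) {
    interaction_records(a, b, sources = "synthetic")
  } else empty_records()
  network <- build_network(records,
                           nodes = c(module_nodes, satellites, background))
  truth <- list(modules = lapply(modules, sort, method = "radix"),
                anchors = sort(anchors, method = "radix"),
                satellites = satellites, background = background)
  list(network = network, truth = truth)
}

#' The fixed discovery benchmark scenario
#'
#' A fixed-shape instance mirroring the topology the subtraction step is
#' designed for: module A of 17 nodes carrying 2 anchor nodes, module B of
#' 8 nodes, both at within-module edge probability 0.85, joined at
#' cross-module probability 0.15; 5 satellite candidates with 2 anchor
#' edges each; and 60 background nodes attached at probability 0.02.  The
#' seed list is module B plus the two anchors (10 seeds), emulating a
#' complex whose subunits split across the two dense sub-clusters.
#'
#' @param rng_seed integer seed (default 1).
#' @return a list: `network`, `truth`, `seeds` (a seed `data.frame`).
#' @export
discovery_scenario <- function(rng_seed = 1L) {
  spec <- planted_spec(module_sizes = c(17L, 8L), intra_p = 0.85,
                       inter_p = 0.15, background_p = 0.02,
                       anchor_module = 1L, n_anchors = 2L,
                       n_satellites = 5L, satellite_degree = 2L,
                       n_background = 60L, rng_seed = rng_seed)
  pn <- planted_network(spec)
  seeds <- data.frame(
    protein = c(pn$truth$modules[[2L]], pn$truth$anchors),
    role = c(rep("core", length(pn$truth$modules[[2L]])),
             rep("supernumerary", length(pn$truth$anchors))),
    stringsAsFactors = FALSE)
  seeds <- seeds[order(seeds$protein, method = "radix"), , drop = FALSE]
  rownames(seeds) <- NULL
  list(network = pn$network, truth = pn$truth, seeds = seeds)
}

#' Split a network into two partially overlapping source snapshots
#'
#' Emulates two interaction databases with incomplete, overlapping
#' coverage: each edge is assigned to both snapshots with probability
#' `frac_shared`, otherwise to exactly one of them with equal probability.
#' The union of the two snapshots always recovers the input network's
#' edge set.
#'
#' @param network a graph from [build_network()].
#' @param frac_shared probability an edge appears in both snapshots.
#' @param rng_seed integer seed.
#' @param names the two source tags.
#' @return a list of two [ppi_snapshot()] objects.
#' @export
split_snapshots <- function(network, frac_shared, rng_seed = 1L,
                            names = c("dbA", "dbB")) {
  if (frac_shared < 0 || frac_shared > 1) {
    pd_stop("frac_shared must lie in [0, 1]")
  }
  ed <- network_edges(network)
  m <- nrow(ed)
  withr::with_seed(rng_seed, {
    shared <- stats::runif(m) < frac_shared
    to_a <- stats::runif(m) < 0.5
  })
  in_a <- shared | to_a
  in_b <- shared | !to_a
  rec <- function(keep, tag) {
    if (!any(keep)) return(empty_records())
    interaction_records(ed$partner_a[keep], ed$partner_b[keep],
                        sources = tag)
  }
  list(ppi_snapshot(names[1L], rec(in_a, names[1L])),
       ppi_snapshot(names[2L], rec(in_b, names[2L])))
}
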