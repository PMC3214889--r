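#' Filtering and merging thresholds for overlapping clustering
#'
#' @param min_size smallest cluster kept (default 3).
#' @param min_density smallest pair density kept (default 0.25, chosen to
#'   yield several overlapping sub-graphs of good quality).
#' @param overlap_threshold match coefficient at or above which two
#'   clusters are merged (default 0.8).
#' @param max_pvalue largest Mann-Whitney p-value kept (default 0.05).
#' @return a list of class `cluster_params`.
#' @export
cluster_params <- function(min_size = 3L, min_density = 0.25,
                           overlap_threshold = 0.8, max_pvalue = 0.05) {
  if (min_size < 1L) pd_stop("min_size must be >= 1")
  for (f in c(min_density, overlap_threshold, max_pvalue)) {
    if (f < 0 || f > 1) pd_stop("thresholds must lie in [0, 1]")
  }
  structure(list(min_size = as.integer(min_size), min_density = min_density,
                 overlap_threshold = overlap_threshold,
                 max_pvalue = max_pvalue),
            class = "cluster_params")
}

#' Cohesiveness (quality) of a node set
#'
#' The number of internal edges divided by the number of edges involving
#' nodes of the group, i.e. `m_in / (m_in + m_bound)`; 1 when the group
#' touches no edges.  Self-loops count toward the internal edges only.
#'
#' @param members non-empty character vector of node names.
#' @param network a graph from [build_network()].
#' @return a fraction in \[0, 1\].
#' @export
cohesiveness <- function(members, network) {
  s <- cluster_stats(members, network)
  s$quality
}

#' Overlap (match) coefficient of two node sets
#'
#' `|A n B|^2 / (|A| |B|)` — 1 for identical sets, 0 for disjoint ones.
#'
#' @param a,b non-empty character vectors.
#' @return a fraction in \[0, 1\].
#' @export
overlap_score <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    pd_stop("overlap_score() needs non-empty sets")
  }
  length(intersect(a, b))^2 / (length(a) * length(b))
}

# ---- one-sided Mann-Whitney U ---------------------------------------------

#' One-sided Mann-Whitney U test (x stochastically greater than y)
#'
#' Exact permutation p-value by enumeration of the U distribution
#' (dynamic programming over midranks, tie-exact) when both samples have at
#' most `exact_limit` values; tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_limit largest per-sample size for exact enumeration
#'   (default 10).
#' @return the p-value for the alternative "x shifted upward".
#' @export
mann_whitney_greater <- function(x, y, exact_limit = 10L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) pd_stop("Mann-Whitney needs two non-empty samples")
  r <- rank(c(x, y))          # midranks
  w <- sum(r[seq_len(n1)])    # rank sum of x
  if (n1 <= exact_limit && n2 <= exact_limit) {
    mw_exact_p(r, n1, w)
  } else {
    mw_normal_p(r, n1, n2, w)
  }
}

# exact P(W >= w_obs) by DP over the doubled midranks (integers)
mw_exact_p <- function(r, n1, w_obs) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  # f[k+1, s+1] = number of size-k subsets with doubled rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in seq.int(kmax, 1L)) {
      nz <- which(f[k, ] > 0)
      if (length(nz) > 0L) {
        f[k + 1L, nz + v] <- f[k + 1L, nz + v] + f[k, nz]
      }
    }
  }
  counts <- f[n1 + 1L, ]
  w2_obs <- as.integer(round(2 * w_obs))
  sum(counts[seq.int(w2_obs + 1L, total + 1L)]) / sum(counts)
}

# tie-corrected normal approximation with continuity correction, one-sided
mw_normal_p <- function(r, n1, n2, w_obs) {
  n <- n1 + n2
  u <- w_obs - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(if (u > mu) 0 else if (u < mu) 1 else 0.5)
  z <- (u - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Cluster significance by intra- vs boundary-degree comparison
#'
#' For each member node the intra-degree (edges to other members, self-loops
#' included) and the boundary-degree (edges to non-members) are computed;
#' the p-value is the one-sided Mann-Whitney U test of the intra-degrees
#' stochastically exceeding the boundary-degrees.  A significant cluster is
#' one whose nodes interact among themselves clearly more than with the
#' rest of the network.
#'
#' @param members node names, at least 2 (a singleton returns p = 1 with a
#'   warning — the test is undefined there).
#' @param network a graph from [build_network()].
#' @return a p-value in (0, 1\].
#' @export
cluster_significance <- function(members, network) {
  members <- unique(as.character(members))
  missing <- setdiff(members, node_names(network))
  if (length(missing) > 0L) {
    pd_stop("member(s) not in network: %s", paste(missing, collapse = ", "))
  }
  if (length(members) < 2L) {
    warning("cluster significance is undefined for a singleton; returning 1",
            call. = FALSE)
    return(1)
  }
  ix <- net_index(network)
  idx <- match(members, ix$names)
  memb <- logical(ix$nv); memb[idx] <- TRUE
  intra <- vapply(idx, function(v) {
    sum(memb[ix$adj[[v]]]) + as.integer(ix$loop[v])
  }, numeric(1))
  boundary <- vapply(idx, function(v) sum(!memb[ix$adj[[v]]]), numeric(1))
  mann_whitney_greater(intra, boundary)
}

# ---- greedy cohesiveness growth -------------------------------------------

# quality numerator/denominator for the optional published-variant penalty:
# q = m_in / (m_in + m_bound + penalty * n)
grow_quality <- function(m_in, m_b, n, penalty) {
  den <- m_in + m_b + penalty * n
  if (den == 0) 1 else m_in / den
}

#' Grow a cohesive cluster from a single seed node
#'
#' Starting from `{seed}`, repeatedly evaluates every single-node addition
#' (external nodes adjacent to the cluster) and removal (current members)
#' and applies the best strictly quality-improving move, stopping at a
#' local maximum of cohesiveness where no single add or remove improves the
#' quality.  Removals may drop the seed itself: in sparse surroundings the
#' walk can abandon a high-degree seed for a small quasi-isolated edge
#' set — such degenerate clusters are caught downstream by the size and
#' density filters of [cluster_one()].  Ties are broken deterministically:
#' additions before removals, then the lexicographically smallest node.
#' Quality comparisons are done exactly on the integer edge counts, so the
#' trace of qualities is strictly increasing.
#'
#' @param seed a node name in the network.
#' @param network a graph from [build_network()].
#' @param node_penalty per-node penalty term added to the quality
#'   denominator (default 0 — the plain two-term cohesiveness ratio; a
#'   positive value gives the published penalized variant).
#' @param trace record the move list (default `FALSE`).
#' @return a list with `members` (sorted names), `m_internal`,
#'   `m_boundary`, `quality`, and when requested `trace`, a `data.frame`
#'   of (move, node, quality) rows.
#' @export
grow_from_seed <- function(seed, network, node_penalty = 0, trace = FALSE) {
  ix <- net_index(network)
  grow_from_seed_ix(seed, ix, node_penalty, trace)
}

grow_from_seed_ix <- function(seed, ix, node_penalty = 0, trace = FALSE) {
  s <- match(seed, ix$names)
  if (is.na(s)) pd_stop("seed '%s' is not a network node", seed)
  memb <- logical(ix$nv)
  memb[s] <- TRUE
  in_cnt <- integer(ix$nv)
  in_cnt[ix$adj[[s]]] <- 1L
  m_in <- as.integer(ix$loop[s])
  m_b <- ix$deg[s]
  n <- 1L
  moves <- list()
  repeat {
    cand_add <- which(!memb & in_cnt > 0L)
    cand_rem <- if (n > 1L) which(memb) else integer(0)
    if (length(cand_add) + length(cand_rem) == 0L) break
    # candidate numerators / denominators after the move
    add_num <- m_in + in_cnt[cand_add] + as.integer(ix$loop[cand_add])
    add_den <- add_num + m_b - in_cnt[cand_add] +
      (ix$deg[cand_add] - in_cnt[cand_add]) + node_penalty * (n + 1L)
    rem_num <- m_in - in_cnt[cand_rem] - as.integer(ix$loop[cand_rem])
    rem_den <- rem_num + m_b + in_cnt[cand_rem] -
      (ix$deg[cand_rem] - in_cnt[cand_rem]) + node_penalty * (n - 1L)
    nodes <- c(cand_add, cand_rem)
    num <- c(add_num, rem_num)
    den <- c(add_den, rem_den)
    is_add <- c(rep(TRUE, length(cand_add)), rep(FALSE, length(cand_rem)))
    qd <- ifelse(den == 0, 1, num / den)
    best_q <- max(qd)
    sel <- which(qd >= best_q - 1e-12)
    # exact re-check of near-ties by cross multiplication
    if (length(sel) > 1L) {
      top <- sel[1L]
      for (j in sel[-1L]) {
        if (frac_gt(num[j], den[j], num[top], den[top])) top <- j
      }
      exact_ties <- sel[vapply(sel, function(j) {
        !frac_gt(num[top], den[top], num[j], den[j])
      }, logical(1))]
      # additions first, then lexicographically smallest node name
      o <- order(!is_add[exact_ties], ix$names[nodes[exact_ties]],
                 method = "radix")
      best <- exact_ties[o[1L]]
    } else {
      best <- sel
    }
    cur_den <- m_in + m_b + node_penalty * n
    if (!frac_gt(num[best], den[best], m_in, cur_den)) break
    v <- nodes[best]
    if (is_add[best]) {
      memb[v] <- TRUE
      m_in <- m_in + in_cnt[v] + as.integer(ix$loop[v])
      m_b <- m_b - in_cnt[v] + (ix$deg[v] - in_cnt[v])
      in_cnt[ix$adj[[v]]] <- in_cnt[ix$adj[[v]]] + 1L
      n <- n + 1L
    } else {
      memb[v] <- FALSE
      m_in <- m_in - in_cnt[v] - as.integer(ix$loop[v])
      m_b <- m_b + in_cnt[v] - (ix$deg[v] - in_cnt[v])
      in_cnt[ix$adj[[v]]] <- in_cnt[ix$adj[[v]]] - 1L
      n <- n - 1L
    }
    if (trace) {
      moves[[length(moves) + 1L]] <-
        data.frame(move = if (is_add[best]) "add" else "remove",
                   node = ix$names[v],
                   quality = grow_quality(m_in, m_b, n, node_penalty),
                   stringsAsFactors = FALSE)
    }
  }
  out <- list(members = sort(ix$names[memb], method = "radix"),
              m_internal = m_in, m_boundary = m_b,
              quality = grow_quality(m_in, m_b, n, node_penalty))
  if (trace) {
    out$trace <- if (length(moves) > 0L) do.call(rbind, moves) else
      data.frame(move = character(), node = character(),
                 quality = numeric(), stringsAsFactors = FALSE)
  }
  out
}

# ---- full overlapping clustering ------------------------------------------

score_cluster <- function(members, network) {
  s <- cluster_stats(members, network)
  s$p_value <- if (s$n_nodes >= 2L) {
    cluster_significance(members, network)
  } else 1
  s
}

#' Overlapping dense-subgraph detection by cohesiveness growth
#'
#' Grows a cohesive cluster from every node (processed in decreasing-degree
#' order with lexicographic tie-break, skipping nodes already covered by an
#' accepted cluster), discards candidates smaller than `min_size`, sparser
#' than `min_density`, or with a Mann-Whitney p-value above `max_pvalue`,
#' and then iteratively merges accepted clusters whose match coefficient
#' reaches `overlap_threshold`.  Merged clusters are re-scored but not
#' re-filtered.  The result is deterministic for a fixed network.
#'
#' @param network a graph from [build_network()].
#' @param params a [cluster_params()] list.
#' @param seeds optional node names to grow from (default: every node);
#'   useful for checking robustness to the choice of growth seeds.
#' @param node_penalty see [grow_from_seed()].
#' @return an object of class `cluster_set`: a list of clusters (each with
#'   `id`, `members`, `stats`, `provenance`) sorted by decreasing size,
#'   with the parameters and a discard log attached as attributes.
#' @export
cluster_one <- function(network, params = cluster_params(), seeds = NULL,
                        node_penalty = 0) {
  if (igraph::vcount(network) == 0L) pd_stop("network is empty")
  ix <- net_index(network)
  seed_idx <- if (is.null(seeds)) seq_len(ix$nv) else {
    m <- match(seed_names(seeds), ix$names)
    if (anyNA(m)) pd_stop("growth seed(s) not in network")
    m
  }
  o <- order(-ix$deg[seed_idx], ix$names[seed_idx], method = "radix")
  seed_idx <- seed_idx[o]
  covered <- logical(ix$nv)
  accepted <- list()
  n_discard <- c(size = 0L, density = 0L, pvalue = 0L, duplicate = 0L)
  for (s in seed_idx) {
    if (covered[s]) next
    gr <- grow_from_seed_ix(ix$names[s], ix, node_penalty)
    members <- gr$members
    n <- length(members)
    density <- pair_density(n, gr$m_internal)
    if (n < params$min_size) { n_discard["size"] <- n_discard["size"] + 1L; next }
    if (density < params$min_density) {
      n_discard["density"] <- n_discard["density"] + 1L; next
    }
    pval <- cluster_significance(members, network)
    if (pval > params$max_pvalue) {
      n_discard["pvalue"] <- n_discard["pvalue"] + 1L; next
    }
    key <- paste(members, collapse = ";")
    if (key %in% vapply(accepted, function(a) a$key, character(1))) {
      n_discard["duplicate"] <- n_discard["duplicate"] + 1L
    } else {
      stats <- list(n_nodes = n, m_internal = gr$m_internal,
                    m_boundary = gr$m_boundary, density = density,
                    quality = gr$quality, p_value = pval)
      accepted[[length(accepted) + 1L]] <-
        list(key = key, members = members, stats = stats)
    }
    covered[match(members, ix$names)] <- TRUE
  }
  merged <- merge_overlapping(accepted, network, params$overlap_threshold)
  make_cluster_set(merged, network, "clusterone", params,
                   log = n_discard)
}

# iterative pairwise merging at the match-coefficient threshold, highest
# overlap first, to a fixed point; merged clusters are re-scored
merge_overlapping <- function(clusters, network, threshold) {
  repeat {
    k <- length(clusters)
    if (k < 2L) return(clusters)
    best <- NULL; best_ov <- -1
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        ov <- overlap_score(clusters[[i]]$members, clusters[[j]]$members)
        if (ov > best_ov + 1e-12) { best_ov <- ov; best <- c(i, j) }
      }
    }
    if (best_ov < threshold) return(clusters)
    members <- sort(unique(c(clusters[[best[1L]]]$members,
                             clusters[[best[2L]]]$members)),
                    method = "radix")
    merged <- list(key = paste(members, collapse = ";"), members = members,
                   stats = score_cluster(members, network))
    clusters <- c(clusters[-best], list(merged))
  }
}

make_cluster_set <- function(clusters, network, algorithm, params,
                             log = NULL, id_prefix = "") {
  if (length(clusters) > 0L) {
    o <- order(-vapply(clusters, function(cl) length(cl$members), integer(1)),
               vapply(clusters, function(cl) paste(cl$members, collapse = ";"),
                      character(1)),
               method = "radix")
    clusters <- clusters[o]
  }
  out <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    list(id = paste0(id_prefix, i), members = cl$members, stats = cl$stats,
         provenance = list(algorithm = algorithm, parent = NA_character_))
  })
  structure(out, class = "cluster_set", algorithm = algorithm,
            params = params, log = log)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set (%s): %d cluster(s)>\n",
              attr(x, "algorithm"), length(x)))
  if (length(x) > 0L) print(as.data.frame(x))
  invisible(x)
}

#' Tabulate a cluster set
#'
#' One row per cluster with the node/edge counts, density, quality,
#' p-value and the semicolon-joined member list — the machine-readable twin
#' of a cluster characteristics table.
#'
#' @param x a `cluster_set`.
#' @param ... unused.
#' @return a `data.frame`.
#' @export
as.data.frame.cluster_set <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(id = character(), algorithm = character(),
                      n_nodes = integer(), m_internal = integer(),
                      m_boundary = integer(), density = numeric(),
                      quality = numeric(), p_value = numeric(),
                      members = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(x, function(cl) {
    data.frame(id = cl$id, algorithm = cl$provenance$algorithm,
               n_nodes = cl$stats$n_nodes, m_internal = cl$stats$m_internal,
               m_boundary = cl$stats$m_boundary, density = cl$stats$density,
               quality = cl$stats$quality, p_value = cl$stats$p_value,
               members = paste(cl$members, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
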