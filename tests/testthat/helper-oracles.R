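# Fixture builders and independent brute-force oracles used across the suite.
# Oracles deliberately use different code paths (adjacency matrices, full
# enumeration) than the implementation they check.

clique_pairs <- function(nodes) t(combn(nodes, 2))

path_pairs <- function(nodes) cbind(nodes[-length(nodes)], nodes[-1])

net_from_pairs <- function(pairs, nodes = character()) {
  build_network(interaction_records(pairs[, 1], pairs[, 2]), nodes = nodes)
}

# G(n, p) on names V01.., deterministic in seed, loops never sampled
random_net <- function(n, p, seed) {
  nodes <- sprintf("V%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- withr::with_seed(seed, stats::rbinom(nrow(pairs), 1, p) == 1)
  net_from_pairs(pairs[keep, , drop = FALSE], nodes = nodes)
}

# edge-classification oracle via the adjacency matrix (loops on the diagonal)
oracle_stats <- function(members, network) {
  A <- as.matrix(igraph::as_adjacency_matrix(network))
  A[A > 1] <- 1
  nm <- rownames(A)
  inside <- nm %in% members
  ut <- upper.tri(A, diag = FALSE)
  m_internal <- sum(A[ut & outer(inside, inside, "&")]) +
    sum(diag(A)[inside])
  m_boundary <- sum(A[ut & outer(inside, inside, "xor")])
  n <- sum(inside)
  list(m_internal = m_internal, m_boundary = m_boundary,
       density = m_internal / (n * (n + 1) / 2),
       quality = if (m_internal + m_boundary > 0)
         m_internal / (m_internal + m_boundary) else 1)
}

# exact one-sided Mann-Whitney p by full enumeration over label assignments
oracle_mw_p <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  r <- rank(z)
  w_obs <- sum(r[seq_len(n1)])
  idx <- combn(length(z), n1)
  w_all <- apply(idx, 2, function(i) sum(r[i]))
  mean(w_all >= w_obs - 1e-9)
}

# does any single add/remove strictly improve cohesiveness?
is_local_max <- function(members, network) {
  q0 <- cohesiveness(members, network)
  all_nodes <- igraph::V(network)$name
  for (v in setdiff(all_nodes, members)) {
    if (cohesiveness(c(members, v), network) > q0 + 1e-12) return(FALSE)
  }
  if (length(members) > 1) {
    for (v in members) {
      if (cohesiveness(setdiff(members, v), network) > q0 + 1e-12) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# independent straight-line re-implementation of the disjoint complex
# detection, written from the definition: weight = k* x density of the
# highest k-core of the closed neighborhood; seed by decreasing weight;
# BFS with threshold (1 - vwp) * seed weight; iterative haircut; size >= 3
oracle_mcode <- function(network, vwp = 0.2, min_core = 2) {
  g <- igraph::simplify(network)
  nm <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  w <- sapply(seq_along(nm), function(v) {
    nb <- c(v, which(A[v, ] > 0))
    sub <- A[nb, nb, drop = FALSE]
    cores <- igraph::coreness(igraph::graph_from_adjacency_matrix(
      sub, mode = "undirected"))
    k <- max(cores)
    if (k < min_core) return(0)
    top <- which(cores >= k)
    s <- sub[top, top, drop = FALSE]
    k * (sum(s) / 2) / (length(top) * (length(top) - 1) / 2)
  })
  visited <- rep(FALSE, length(nm))
  out <- list()
  for (s in order(-w, nm)) {
    if (visited[s] || w[s] <= 0) next
    thr <- (1 - vwp) * w[s]
    visited[s] <- TRUE
    queue <- s
    members <- integer(0)
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      members <- c(members, u)
      for (v in sort(which(A[u, ] > 0))) {
        if (!visited[v] && w[v] >= thr - 1e-12) {
          visited[v] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
    repeat {
      keep <- sapply(members, function(u) sum(A[u, members]) >= 2)
      if (all(keep)) break
      members <- members[keep]
      if (length(members) == 0) break
    }
    if (length(members) >= 3) out <- c(out, list(sort(nm[members])))
  }
  out
}
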