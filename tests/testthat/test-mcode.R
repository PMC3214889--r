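test_that("core numbers match the iterative-pruning oracle", {
  g <- net_from_pairs(clique_pairs(c("A", "B", "C")))
  expect_true(all(core_numbers(g) == 2))
  star <- net_from_pairs(cbind("HUB", sprintf("L%d", 1:5)))
  expect_true(all(core_numbers(star) == 1))
  # iterative minimum-degree removal oracle on a random fixture
  g3 <- random_net(10, 0.35, 3)
  cn <- core_numbers(g3)
  prune_core <- function(g, k) {
    repeat {
      d <- igraph::degree(g)
      if (all(d >= k) || igraph::vcount(g) == 0) break
      g <- igraph::delete_vertices(g, which(d < k))
    }
    igraph::V(g)$name
  }
  for (k in 0:max(cn)) {
    expect_setequal(names(cn)[cn >= k], prune_core(g3, k))
  }
})

test_that("vertex weights follow the closed-neighborhood core density", {
  # center of a 4-clique: k* = 3, core density 1 -> weight 3
  g <- net_from_pairs(clique_pairs(c("A", "B", "C", "D")))
  expect_equal(vertex_weight("A", g), 3)
  # a node with a single neighbor has no 2-core
  g2 <- net_from_pairs(rbind(clique_pairs(c("A", "B", "C", "D")),
                             c("A", "LEAF")))
  expect_equal(vertex_weight("LEAF", g2), 0)
  # leaf attached to a 4-clique: its closed neighborhood is the pendant
  # edge only, so every weight matches the exhaustive oracle
  w <- vertex_weights(g2)
  onms <- igraph::V(g2)$name
  A <- as.matrix(igraph::as_adjacency_matrix(igraph::simplify(g2)))
  for (v in seq_along(onms)) {
    nb <- c(v, which(A[v, ] > 0))
    sub <- igraph::induced_subgraph(g2, nb)
    cores <- igraph::coreness(sub)
    k <- max(cores)
    expected <- if (k < 2) 0 else {
      top <- igraph::induced_subgraph(sub, which(cores >= k))
      k * igraph::ecount(top) / (igraph::vcount(top) *
                                   (igraph::vcount(top) - 1) / 2)
    }
    expect_equal(unname(w[onms[v]]), expected)
  }
})

test_that("vertex weights are invariant under node relabeling", {
  g <- random_net(9, 0.4, 17)
  w <- vertex_weights(g)
  perm <- withr::with_seed(1, sample(igraph::V(g)$name))
  relabel <- setNames(sprintf("Z%02d", seq_along(perm)), perm)
  ed <- igraph::as_edgelist(g)
  g2 <- net_from_pairs(cbind(relabel[ed[, 1]], relabel[ed[, 2]]),
                       nodes = unname(relabel))
  w2 <- vertex_weights(g2)
  expect_equal(unname(w2[relabel[names(w)]]), unname(w))
})

test_that("complex detection matches the independent oracle on small fixtures", {
  # two 5-cliques joined by one edge: all weights tie, so the expansion
  # crosses the bridge and the oracle yields a single 10-node complex
  A <- sprintf("A%d", 1:5); B <- sprintf("B%d", 1:5)
  g <- net_from_pairs(rbind(clique_pairs(A), clique_pairs(B),
                            c("A1", "B1")))
  canon <- function(l) l[order(vapply(l, paste, "", collapse = ";"))]
  got <- lapply(mcode_complexes(g), `[[`, "members")
  expect_identical(canon(got), canon(oracle_mcode(g)))
  for (seed in 21:26) {
    g2 <- random_net(10, 0.35, seed)
    got2 <- lapply(suppressWarnings(mcode_complexes(g2)), `[[`, "members")
    expect_identical(canon(got2), canon(oracle_mcode(g2)))
  }
})

test_that("edgeless graphs yield no complexes", {
  g <- build_network(interaction_records(character(), character()),
                     nodes = c("A", "B", "C"))
  expect_length(mcode_complexes(g), 0L)
})

test_that("complexes are disjoint, connected, and haircut leaves no pendants", {
  for (seed in 31:35) {
    g <- random_net(18, 0.3, seed)
    cs <- suppressWarnings(mcode_complexes(g))
    mem <- lapply(cs, `[[`, "members")
    all_members <- unlist(mem)
    expect_identical(anyDuplicated(all_members), 0L)
    for (m in mem) {
      sub <- igraph::induced_subgraph(g, m)
      expect_true(igraph::is_connected(sub))
      expect_true(all(igraph::degree(igraph::simplify(sub)) >= 2))
    }
  }
})

test_that("a planted clique in a sparse background is recovered whole", {
  clique <- sprintf("K%d", 1:5)
  bgp <- t(combn(sprintf("N%02d", 1:12), 2))
  keep <- withr::with_seed(5, rbinom(nrow(bgp), 1, 0.05) == 1)
  attach <- withr::with_seed(6, {
    a <- cbind(sample(clique, 2, replace = TRUE), sample(sprintf("N%02d", 1:12), 2))
    a
  })
  g <- net_from_pairs(rbind(clique_pairs(clique), bgp[keep, , drop = FALSE],
                            attach),
                      nodes = c(clique, sprintf("N%02d", 1:12)))
  cs <- suppressWarnings(mcode_complexes(g))
  mem <- lapply(cs, `[[`, "members")
  expect_true(any(vapply(mem, function(m) all(clique %in% m), logical(1))))
})
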