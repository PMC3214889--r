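mk_cluster <- function(members, quality = 0.5) {
  list(id = paste(members, collapse = ""), members = sort(members),
       stats = list(n_nodes = length(members), m_internal = 0L,
                    m_boundary = 0L, density = 0.5, quality = quality,
                    p_value = 0.01),
       provenance = list(algorithm = "clusterone", parent = NA_character_))
}

test_that("the seed-richest cluster is selected with documented tie-breaks", {
  seeds <- c("S1", "S2", "S3")
  cs <- list(mk_cluster(c("S1", "A")), mk_cluster(c("S1", "S2", "B")))
  expect_setequal(select_target_cluster(cs, seeds)$members,
                  c("B", "S1", "S2"))
  # tie on coverage: the higher-quality cluster wins
  tie <- list(mk_cluster(c("S1", "A"), quality = 0.3),
              mk_cluster(c("S1", "B"), quality = 0.9))
  expect_setequal(select_target_cluster(tie, seeds)$members, c("B", "S1"))
  expect_identical(select_target_cluster(list(mk_cluster("S3")), seeds)$members,
                   "S3")
  expect_error(select_target_cluster(list(mk_cluster("X")), seeds),
               "loosening")
})

test_that("residual subtraction is the literal set difference", {
  parent <- LETTERS[1:10]
  expect_identical(subtract_residual(parent, list(LETTERS[1:4], c("E", "F"))),
                   c("G", "H", "I", "J"))
  expect_length(subtract_residual(parent, list(LETTERS[1:5], LETTERS[6:10])),
                0L)
  expect_error(subtract_residual(LETTERS[1:3], list(c("A", "Z"))), "Z")
  for (seed in 1:5) {
    u <- withr::with_seed(seed, {
      p <- sample(LETTERS, 12)
      k1 <- sample(p, 5); k2 <- sample(p, 3)
      list(p = p, k1 = k1, k2 = k2)
    })
    expect_identical(subtract_residual(u$p, list(u$k1, u$k2)),
                     sort(setdiff(u$p, c(u$k1, u$k2))))
  }
})

test_that("candidates are anchor-connected residual proteins, ranked", {
  # anchors AN1, AN2 also seeds; satellites SA (2 anchor edges), SB and SC
  # (1 each, SB with an extra seed edge); RX has no anchor edge
  pairs <- rbind(c("AN1", "AN2"), c("SA", "AN1"), c("SA", "AN2"),
                 c("SB", "AN1"), c("SB", "SEED3"), c("SC", "AN2"),
                 c("RX", "OTHER"), c("SEED3", "AN1"))
  g <- net_from_pairs(pairs)
  seeds <- c("AN1", "AN2", "SEED3")
  rep <- anchor_candidates(c("SA", "SB", "SC", "RX", "SEED3"),
                           anchors = c("AN1", "AN2"), g, seeds)
  expect_identical(rep$candidates$protein, c("SA", "SB", "SC", "SEED3"))
  expect_identical(rep$candidates$n_edges_to_anchors, c(2L, 1L, 1L, 1L))
  expect_identical(rep$candidates$annotation, c("", "", "", "seed"))
  expect_error(anchor_candidates("SA", character(), g, seeds), "empty")
  rep2 <- anchor_candidates("RX", c("AN1", "AN2"), g, seeds)
  expect_equal(nrow(rep2$candidates), 0L)
})

test_that("an unsplittable clique yields a one-level tree", {
  g <- net_from_pairs(clique_pairs(sprintf("K%d", 1:6)))
  tree <- suppressMessages(partition_recursive(g, seeds = "K1"))
  expect_identical(tree$mcode_parent, "net")
  kids <- tree$nodes$net$children
  expect_length(kids, 1L)
  expect_setequal(tree$nodes[[kids]]$members, sprintf("K%d", 1:6))
})

test_that("tree children are nested subsets and disjoint under mcode", {
  sc <- discovery_scenario(1)
  tree <- suppressMessages(suppressWarnings(
    partition_recursive(sc$network, sc$seeds)))
  for (nd in tree$nodes) {
    if (!is.na(nd$parent)) {
      expect_true(all(nd$members %in% tree$nodes[[nd$parent]]$members))
    }
  }
  mc <- tree$nodes[[tree$mcode_parent]]$children
  expect_identical(anyDuplicated(unlist(lapply(mc, function(id)
    tree$nodes[[id]]$members))), 0L)
})

test_that("report files are stable and the tree JSON round-trips", {
  sc <- discovery_scenario(1)
  res <- suppressMessages(suppressWarnings(
    discover_candidates(sc$network, sc$seeds)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(res$tree, res$report, d1)
  write_report(res$tree, res$report, d2)
  for (f in c("clusters.tsv", "candidates.tsv", "tree.json",
              "parent_cluster.graphml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_cluster_tree(file.path(d1, "tree.json"))
  expect_identical(back$mcode_parent, res$tree$mcode_parent)
  expect_identical(names(back$nodes), names(res$tree$nodes))
  for (id in names(back$nodes)) {
    expect_identical(back$nodes[[id]]$members, res$tree$nodes[[id]]$members)
    expect_identical(back$nodes[[id]]$children, res$tree$nodes[[id]]$children)
  }
  # empty candidate table still writes a header-only TSV
  empty <- res$report
  empty$candidates <- empty$candidates[0, , drop = FALSE]
  d3 <- withr::local_tempdir()
  write_report(res$tree, empty, d3)
  expect_length(readLines(file.path(d3, "candidates.tsv")), 1L)
})
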