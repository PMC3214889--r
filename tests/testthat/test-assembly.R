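toy_snapshot <- function() {
  # seeds S1, S2; direct partners D1..D3; second shell X1, X2; far pair F1-F2
  ppi_snapshot("toy", interaction_records(
    c("S1", "S1", "S2", "D1", "D2", "X1", "F1", "D3"),
    c("D1", "D2", "D3", "D2", "X1", "X2", "F2", "D3")))
}

test_that("direct interactions equal the brute-force endpoint filter", {
  sn <- toy_snapshot()
  got <- direct_interactions(sn, c("S1", "S2"))
  r <- sn$records
  want <- r[r$partner_a %in% c("S1", "S2") | r$partner_b %in% c("S1", "S2"), ]
  expect_equal(got[, 1:2], want[, 1:2], ignore_attr = TRUE)
  expect_equal(nrow(direct_interactions(sn, "ABSENT")), 0L)
})

test_that("level-1.5 neighborhood adds edges among direct partners only", {
  sn <- toy_snapshot()
  got <- level15_neighborhood(sn, c("S1", "S2"))
  keys <- paste(got$partner_a, got$partner_b)
  # D1-D2 joins two direct partners; D3-D3 is a self-pair of a partner
  expect_true(all(c("D1 D2", "D3 D3") %in% keys))
  # X1-X2 and F1-F2 are outside the 1.5 neighborhood
  expect_false(any(c("X1 X2", "F1 F2") %in% keys))
  expect_true(nrow(got) >= nrow(direct_interactions(sn, c("S1", "S2"))))
  # brute force: records touching a seed, plus records whose both endpoints
  # have a direct seed interaction
  r <- sn$records
  seeds <- c("S1", "S2")
  t1 <- r$partner_a %in% seeds | r$partner_b %in% seeds
  dset <- unique(c(r$partner_a[t1], r$partner_b[t1]))
  t2 <- r$partner_a %in% dset & r$partner_b %in% dset
  expect_equal(got[, 1:2], dedup_records(r[t1 | t2, ])[, 1:2],
               ignore_attr = TRUE)
  expect_equal(nrow(level15_neighborhood(sn, "ABSENT")), 0L)
  expect_error(level15_neighborhood(sn, character()), "empty")
})

test_that("the expansion delta joins new proteins to non-seed list-1 proteins", {
  seeds <- "S1"
  snap2 <- ppi_snapshot("db2", interaction_records(
    c("S1", "N1", "N1", "N2", "N1"),
    c("N1", "D1", "S1", "N1", "N2")))
  list1 <- interaction_records(c("S1", "S1", "D1"), c("D1", "D2", "D2"))
  list2 <- direct_interactions(snap2, seeds)
  delta <- expansion_delta(list1, list2, snap2, seeds)
  # N1 is new (absent from list1); its join to D1 qualifies; N1-S1 targets a
  # seed, N1-N2 is new-new: both excluded
  expect_equal(nrow(delta), 1L)
  expect_identical(c(delta$partner_a, delta$partner_b), c("D1", "N1"))
  # no new proteins -> empty delta
  expect_equal(nrow(expansion_delta(list1, list1, snap2, seeds)), 0L)
})

test_that("merging lists is commutative, associative and idempotent", {
  l1 <- interaction_records(c("A", "B"), c("B", "C"), sources = "s1")
  l2 <- interaction_records(c("B", "C"), c("A", "D"), sources = "s2")
  l3 <- interaction_records(c("D", "E"), c("E", "A"), sources = "s3")
  sig <- function(g) {
    ed <- igraph::as_edgelist(g)
    list(sort(igraph::V(g)$name),
         sort(paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))))
  }
  expect_identical(sig(merge_lists(l1, l2, l3)), sig(merge_lists(l3, l1, l2)))
  expect_identical(sig(merge_lists(merge_lists(l1, l2) |> network_records(),
                                   l3)),
                   sig(merge_lists(l1, merge_lists(l2, l3) |>
                                     network_records())))
  expect_identical(sig(merge_lists(l1, l1)), sig(merge_lists(l1)))
})

test_that("assembly reports seeds absent from every snapshot", {
  sn1 <- toy_snapshot()
  sn2 <- ppi_snapshot("db2", interaction_records("S1", "D1"))
  expect_warning(
    a <- suppressMessages(assemble_network(sn1, sn2, c("S1", "S2", "COB"))),
    "COB")
  expect_identical(a$missing_seeds, "COB")
  expect_true(all(c("S1", "S2") %in% igraph::V(a$network)$name))
})
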