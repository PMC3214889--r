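two_cliques_shared_node <- function(k = 6) {
  A <- sprintf("A%02d", seq_len(k - 1))
  B <- sprintf("B%02d", seq_len(k - 1))
  net_from_pairs(rbind(clique_pairs(c(A, "SHARED")),
                       clique_pairs(c(B, "SHARED"))))
}

test_that("cohesiveness matches direct edge counts", {
  # isolated clique
  g <- net_from_pairs(clique_pairs(c("A", "B", "C", "D")))
  expect_equal(cohesiveness(c("A", "B", "C", "D"), g), 1)
  # triangle with exactly 3 outgoing edges
  g2 <- net_from_pairs(rbind(clique_pairs(c("A", "B", "C")),
                             c("A", "X"), c("B", "Y"), c("C", "Z")))
  expect_equal(cohesiveness(c("A", "B", "C"), g2), 0.5)
})

test_that("overlap score is the match coefficient", {
  expect_equal(overlap_score(c("A", "B"), c("A", "B")), 1)
  expect_equal(overlap_score(c("A", "B"), c("C", "D")), 0)
  expect_equal(overlap_score(c("A", "B", "C", "D"),
                             c("A", "B", "C", "D", "E")), 16 / 20)
  expect_error(overlap_score(character(), "A"), "non-empty")
})

test_that("exact Mann-Whitney p-values agree with full enumeration", {
  cases <- withr::with_seed(42, {
    lapply(1:10, function(i) {
      list(x = sample(0:4, sample(3:7, 1), replace = TRUE),
           y = sample(0:4, sample(3:7, 1), replace = TRUE))
    })
  })
  for (cs in cases) {
    expect_equal(mann_whitney_greater(cs$x, cs$y), oracle_mw_p(cs$x, cs$y),
                 tolerance = 1e-12)
  }
  # tie-free samples also agree with the reference exact test
  x <- c(1.2, 3.4, 5.1, 7.9); y <- c(0.8, 2.2, 4.4, 6.1)
  expect_equal(mann_whitney_greater(x, y),
               wilcox.test(x, y, alternative = "greater",
                           exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("large-sample p-values match the tie-corrected normal reference", {
  x <- withr::with_seed(7, sample(0:6, 25, replace = TRUE))
  y <- withr::with_seed(8, sample(0:5, 25, replace = TRUE))
  expect_equal(mann_whitney_greater(x, y),
               suppressWarnings(
                 wilcox.test(x, y, alternative = "greater", exact = FALSE,
                             correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("degree separation drives the significance test", {
  # perfect separation, n = 10 each: p = 1 / choose(20, 10)
  p <- mann_whitney_greater(rep(5, 10), rep(0, 10))
  expect_equal(p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_lt(p, 0.001)
  # identical samples carry no evidence
  expect_gte(mann_whitney_greater(rep(3, 6), rep(3, 6)), 0.5)
  expect_warning(p1 <- cluster_significance("A", net_from_pairs(
    cbind("A", "B"))), "singleton")
  expect_equal(p1, 1)
})

test_that("growth recovers a clique and stops at local maxima", {
  # 5-clique attached by one edge to a star hub with 5 leaves; absorbing
  # the hub would bring 5 boundary edges, so the clique is a local maximum
  g <- net_from_pairs(rbind(clique_pairs(sprintf("C%d", 1:5)),
                            c("C1", "HUB"),
                            cbind("HUB", sprintf("L%d", 1:5))))
  gr <- grow_from_seed("C3", g, trace = TRUE)
  expect_identical(gr$members, sort(sprintf("C%d", 1:5)))
  expect_true(is_local_max(gr$members, g))
  expect_true(all(diff(c(0, gr$trace$quality)) > 0))
  # isolated node: singleton with quality one
  g2 <- build_network(interaction_records("A", "B"), nodes = "LONE")
  gr2 <- grow_from_seed("LONE", g2)
  expect_identical(gr2$members, "LONE")
  expect_equal(gr2$quality, 1)
  # seed on the shared node of two cliques terminates at a local maximum
  g3 <- two_cliques_shared_node()
  gr3 <- grow_from_seed("SHARED", g3)
  expect_true(is_local_max(gr3$members, g3))
})

test_that("two overlapping cliques are both detected", {
  g <- two_cliques_shared_node()
  cs <- cluster_one(g)
  expect_length(cs, 2L)
  mem <- lapply(cs, `[[`, "members")
  expect_true(any(vapply(mem, function(m)
    setequal(m, c(sprintf("A%02d", 1:5), "SHARED")), logical(1))))
  expect_true(any(vapply(mem, function(m)
    setequal(m, c(sprintf("B%02d", 1:5), "SHARED")), logical(1))))
  # both contain the shared node: overlapping clustering
  expect_true(all(vapply(mem, function(m) "SHARED" %in% m, logical(1))))
})

test_that("filters discard sparse graphs entirely", {
  g <- net_from_pairs(path_pairs(sprintf("P%02d", 1:12)))
  expect_length(cluster_one(g), 0L)
})

test_that("returned clusters respect the configured filters", {
  pars <- cluster_params(min_size = 4, min_density = 0.3, max_pvalue = 0.05)
  nets <- c(lapply(c(11, 12), function(s) random_net(25, 0.25, s)),
            list(two_cliques_shared_node()))
  n_seen <- 0L
  for (g in nets) {
    cs <- suppressWarnings(cluster_one(g, pars))
    n_seen <- n_seen + length(cs)
    for (cl in cs) {
      expect_gte(length(cl$members), 4L)
      expect_gte(cl$stats$density, 0.3)
      expect_lte(cl$stats$p_value, 0.05)
    }
  }
  expect_gt(n_seen, 0L)   # the check must not be vacuous
})

test_that("clustering output is deterministic across runs", {
  g <- random_net(30, 0.2, 99)
  d1 <- as.data.frame(suppressWarnings(cluster_one(g)))
  d2 <- as.data.frame(suppressWarnings(cluster_one(g)))
  expect_identical(d1, d2)
})

test_that("seeding growth from module nodes alone finds the same clusters", {
  g <- two_cliques_shared_node()
  full <- as.data.frame(cluster_one(g))
  sub <- as.data.frame(cluster_one(g, seeds = c("A01", "B01")))
  expect_identical(full$members, sub$members)
})
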