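test_that("the depicted five-node cascade replays to coverage three", {
  g <- fig4_fixture()
  cr <- simulate_cascade(g, "1", forced_outcomes = fig4_forced_outcomes())
  expect_identical(cr$activated, c("3", "5", "4"))
  expect_length(cr$activated, 3)
  expect_false("1" %in% cr$activated)            # the seed does not count
  # 1->2 failed; 3->4 failed and was not retried; 4 arrived via 5->4
  att <- cr$attempted_edges
  expect_equal(sum(att$source == "3" & att$target == "4"), 1)
  expect_false(att$outcome[att$source == "1" & att$target == "2"])
})

test_that("cascades propagate deterministically at weight 1 and 0", {
  path <- make_dmin(c("1", "2"), c("2", "3"), c(1, 1))
  set.seed(1)
  expect_identical(simulate_cascade(path, "1")$activated, c("2", "3"))
  dead <- make_dmin(c("1", "2"), c("2", "3"), c(0, 0))
  set.seed(1)
  expect_identical(simulate_cascade(dead, "1")$activated, character(0))
  expect_error(simulate_cascade(path, "9"),
               class = "mircascade_not_found_error")
})

test_that("each edge is attempted at most once per realization", {
  for (s in 1:20) {
    g <- random_small_graph(s)
    set.seed(s)
    cr <- simulate_cascade(g, g$nodes$mirna[1])
    att <- cr$attempted_edges
    if (nrow(att))
      expect_false(anyDuplicated(edge_key(att$source, att$target)) > 0)
    # every activated node is justified by a successful attempted edge
    expect_true(all(cr$activated %in% att$target[att$outcome]))
  }
})

test_that("Monte-Carlo coverage matches closed-form expectations", {
  # star with unit weights: deterministic coverage k
  star <- make_dmin(rep("hub", 4), paste0("leaf", 1:4), rep(1, 4))
  expect_equal(as.numeric(compute_coverage(star, "hub", n_sim = 200)), 4)

  # single Bernoulli edge: within 4 binomial SEs of p
  one <- make_dmin("A", "B", 0.3)
  est <- compute_coverage(one, "A", n_sim = 10000, seed = 99)
  expect_lt(abs(as.numeric(est) - 0.3), 4 * sqrt(0.3 * 0.7 / 10000))

  # two-edge chain at 0.5: expectation p + p^2 = 0.75
  chain <- make_dmin(c("1", "2"), c("2", "3"), c(0.5, 0.5))
  est2 <- compute_coverage(chain, "1", n_sim = 10000, seed = 7)
  se <- sqrt(attr(est2, "var") / 10000)
  expect_lt(abs(as.numeric(est2) - 0.75), 4 * se)
})

test_that("live-edge enumeration gives the exact expectation", {
  chain <- make_dmin(c("1", "2"), c("2", "3"), c(0.5, 0.5))
  expect_equal(exact_expected_coverage(chain, "1"), 0.75)
  expect_equal(exact_expected_coverage(chain, "2"), 0.5)
  expect_equal(exact_expected_coverage(chain, "3"), 0)

  # all weights 1: coverage is the reachable-set size
  g <- fig4_fixture(lower_weights = c(1, 1, 1))
  g$edges$weight <- 1
  expect_equal(exact_expected_coverage(g, "1"), 4)
  expect_equal(exact_expected_coverage(g, "3"), 2)

  big <- generate_random_dmin(10, 0.5, seed = 1)
  expect_gt(nrow(big$edges), 20)
  expect_error(exact_expected_coverage(big, "m001"),
               class = "mircascade_resource_error")
})

test_that("raising an edge weight never lowers exact expected coverage", {
  for (s in 1:10) {
    g <- random_small_graph(s, max_nodes = 5, max_edges = 7)
    if (!nrow(g$edges)) next
    base <- exact_expected_coverage(g)
    k <- 1 + (s %% nrow(g$edges))
    g2 <- g
    g2$edges$weight[k] <- min(1, g2$edges$weight[k] + 0.3)
    up <- exact_expected_coverage(g2)
    expect_true(all(up >= base - 1e-12))
  }
})

test_that("coverage percentages follow the share-of-network definition", {
  expect_equal(coverage_percentage(70, 100), 70)
  expect_equal(coverage_percentage(0, 10), 0)
  expect_equal(coverage_percentage(3, 4), 75)    # n - 1 of n = 4
  expect_error(coverage_percentage(5, 4), class = "mircascade_validation_error")
  expect_error(coverage_percentage(-1, 4), class = "mircascade_validation_error")
})

test_that("node ranking is coverage-descending with lexicographic ties", {
  g <- make_dmin(c("A", "A"), c("b1", "b2"), c(1, 1))
  r <- rank_all_nodes(g, n_sim = 100, seed = 1)
  expect_equal(r$mirna[1], "A")
  expect_equal(r$mean_coverage[1], 2)
  expect_equal(r$coverage_percentage[1], 2 / 3 * 100)

  iso <- dmin(data.frame(source = character(), target = character(),
                         weight = numeric()),
              nodes = data.frame(mirna = c("c", "a", "b")))
  r2 <- rank_all_nodes(iso, n_sim = 10, seed = 1)
  expect_equal(r2$mirna, c("a", "b", "c"))       # all-zero ties: id order
  expect_equal(r2$rank, 1:3)
})

test_that("identical master seeds give bit-identical results", {
  g <- generate_random_dmin(10, 0.3, seed = 4)
  r1 <- rank_all_nodes(g, n_sim = 500, seed = 123)
  r2 <- rank_all_nodes(g, n_sim = 500, seed = 123)
  expect_identical(r1, r2)
  # per-node streams: a single node's coverage does not depend on which
  # other nodes were evaluated
  solo <- compute_coverage(g, "m005", n_sim = 500, seed = 123)
  expect_identical(as.numeric(solo),
                   r1$mean_coverage[r1$mirna == "m005"])
})

test_that("the planted hub is recovered at rank one", {
  pf <- planted_influencer_network(n_nodes = 20, hub_out_degree = 15,
                                   hub_p = 0.9, background_p = 0.05, seed = 1)
  r <- rank_all_nodes(pf$network, n_sim = 2000, seed = 11)
  expect_equal(r$mirna[1], pf$hub_id)
})
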