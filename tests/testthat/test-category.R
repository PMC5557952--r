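test_that("intersection keeps shared edges with product weights", {
  d1 <- make_dmin("m1", "m2", 0.5, disease_id = "d1")
  d2 <- make_dmin("m1", "m2", 0.5, disease_id = "d2")
  res <- intersect_category(category_spec("cat", list(d1, d2), "intersection"),
                            n_sim = 200, seed = 1)
  expect_equal(res$merged_network$edges$weight, 0.25)
  expect_equal(res$ranking$mirna, "m1")          # only m1 has coverage > 0
  expect_true(all(res$ranking$score > 0))
  expect_equal(res$ranking$diseases_present, "d1;d2")

  # an edge present in only one member is dropped
  d3 <- make_dmin(c("m1", "m2"), c("m2", "m3"), c(0.8, 0.9), disease_id = "d3")
  res2 <- intersect_category(category_spec("cat", list(d1, d3), "intersection"),
                             n_sim = 100, seed = 1)
  expect_equal(nrow(res2$merged_network$edges), 1)
  expect_equal(res2$merged_network$edges$weight, 0.5 * 0.8)

  # three members at 0.9 each
  trip <- lapply(1:3, function(i) make_dmin("a", "b", 0.9,
                                            disease_id = paste0("d", i)))
  res3 <- intersect_category(category_spec("cat", trip, "intersection"),
                             n_sim = 100, seed = 1)
  expect_equal(res3$merged_network$edges$weight, 0.9^3)

  expect_error(
    intersect_category(category_spec("cat", list(d1), "intersection")),
    class = "mircascade_validation_error")
  far <- make_dmin("x", "y", 0.9, disease_id = "far")
  expect_warning(
    res4 <- intersect_category(category_spec("cat", list(d1, far),
                                             "intersection")),
    "no edge")
  expect_equal(nrow(res4$ranking), 0)
})

test_that("intersection weight never exceeds the member minimum", {
  set.seed(31)
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    w <- runif(k)
    nets <- lapply(seq_len(k), function(i)
      make_dmin("a", "b", w[i], disease_id = paste0("d", i)))
    res <- intersect_category(category_spec("c", nets, "intersection"),
                              n_sim = 10, seed = 1)
    expect_equal(res$merged_network$edges$weight, prod(w))
    expect_lte(res$merged_network$edges$weight, min(w))
  }
})

test_that("intersection is independent of member ordering", {
  nets <- lapply(1:3, function(s) generate_random_dmin(
    8, 0.5, weight_distribution = "uniform01", seed = s,
    disease_id = paste0("d", s)))
  a <- intersect_category(category_spec("c", nets, "intersection"),
                          n_sim = 100, seed = 5)
  b <- intersect_category(category_spec("c", rev(nets), "intersection"),
                          n_sim = 100, seed = 5)
  ea <- a$merged_network$edges[order(a$merged_network$edges$source,
                                     a$merged_network$edges$target), ]
  eb <- b$merged_network$edges[order(b$merged_network$edges$source,
                                     b$merged_network$edges$target), ]
  rownames(ea) <- rownames(eb) <- NULL
  expect_equal(ea, eb)
  expect_equal(a$ranking$mirna, b$ranking$mirna)
})

test_that("cumulative union averages per-disease coverage percentages", {
  # deterministic (weight-1) networks with known percentages:
  # d1: hub covers 4 of 5 nodes -> 80%; d2: m1 covers 1 of 2 -> 50%
  d1 <- make_dmin(rep("m1", 4), paste0("x", 1:4), rep(1, 4), disease_id = "d1")
  d2 <- make_dmin("m1", "y", 1, disease_id = "d2")
  res <- cumulative_union(category_spec("cat", list(d1, d2), "cumulative_union"),
                          n_sim = 50, seed = 1)
  m1 <- res$ranking[res$ranking$mirna == "m1", ]
  expect_equal(m1$score, (80 + 50) / 2)
  expect_equal(m1$diseases_present, "d1;d2")
  # a miRNA present in one disease keeps its own percentage
  x1 <- res$ranking[res$ranking$mirna == "x1", ]
  expect_equal(x1$score, 0)

  expect_error(cumulative_union(category_spec("c", list(d1), "cumulative_union"),
                                top_k = 0),
               class = "mircascade_validation_error")
})

test_that("union scores stay within the per-disease percentage range", {
  nets <- lapply(1:3, function(s) generate_random_dmin(
    7, 0.4, seed = s + 40, disease_id = paste0("d", s)))
  res <- cumulative_union(category_spec("c", nets, "cumulative_union"),
                          n_sim = 200, seed = 3, top_k = 100)
  for (i in seq_len(nrow(res$ranking))) {
    m <- res$ranking$mirna[i]
    pcts <- res$per_disease$coverage_percentage[res$per_disease$mirna == m]
    expect_gte(res$ranking$score[i], min(pcts) - 1e-12)
    expect_lte(res$ranking$score[i], max(pcts) + 1e-12)
  }
})

test_that("a singleton union reproduces the per-network ranking", {
  g <- generate_random_dmin(9, 0.3, seed = 17)
  res <- cumulative_union(category_spec("c", list(g), "cumulative_union"),
                          n_sim = 300, seed = 9, top_k = 100)
  ref <- rank_all_nodes(g, n_sim = 300, seed = 9)
  expect_equal(res$ranking$mirna, ref$mirna)
  expect_equal(res$ranking$score, ref$coverage_percentage)
})

test_that("top-k reporting truncates the union ranking", {
  g <- generate_random_dmin(12, 0.3, seed = 23)
  res <- cumulative_union(category_spec("c", list(g), "cumulative_union"),
                          n_sim = 50, seed = 2, top_k = 10)
  expect_equal(nrow(res$ranking), 10)
})

test_that("category building from files validates, runs and is reproducible", {
  dir <- tempfile(); dir.create(dir)
  paths <- vapply(1:2, function(s) {
    g <- generate_random_dmin(8, 0.5, seed = s, disease_id = paste0("d", s))
    p <- file.path(dir, paste0("d", s, ".csv"))
    write_network(g, p)
    p
  }, character(1))

  expect_error(build_category(rep(paths[1], 6), "intersection", dir),
               class = "mircascade_validation_error")
  expect_error(build_category(c(paths, file.path(dir, "nope.csv")),
                              "cumulative_union", dir),
               class = "mircascade_not_found_error")

  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  build_category(paths, "cumulative_union", out1, n_sim = 200, seed = 5)
  build_category(paths, "cumulative_union", out2, n_sim = 200, seed = 5)
  f1 <- file.path(out1, "category_ranking.csv")
  f2 <- file.path(out2, "category_ranking.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(file.path(out1, "category_provenance.json")))
})
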