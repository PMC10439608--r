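test_that("silhouette matches the worked two-cluster example", {
  X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  rownames(X) <- paste0("c", 1:4)
  lab <- setNames(c("A", "A", "B", "B"), rownames(X))
  res <- silhouette_scores(X, lab, standardize = FALSE)
  expect_equal(res$overall_mean, 0.900, tolerance = 1e-3)
  expect_equal(res$n_used, 4)
  # brute-force agreement on the same instance
  expect_equal(res$per_contig$silhouette, brute_silhouette(X, lab),
               tolerance = 1e-12)
})

test_that("silhouette equals the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:60, 1); d <- sample(1:5, 1); k <- sample(2:6, 1)
    X <- matrix(rnorm(n * d), n)
    rownames(X) <- paste0("c", seq_len(n))
    lab <- setNames(sample(paste0("b", 1:k), n, replace = TRUE), rownames(X))
    res <- silhouette_scores(X, lab, standardize = FALSE)
    expect_equal(res$per_contig$silhouette, brute_silhouette(X, lab),
                 tolerance = 1e-9)
  }
})

test_that("silhouette conventions: singletons, identical points, errors", {
  X <- rbind(c(0, 0), c(0, 1), c(5, 5))
  rownames(X) <- c("a", "b", "c")
  res <- silhouette_scores(X, c(a = "A", b = "A", c = "B"), standardize = FALSE)
  expect_equal(res$per_contig$silhouette[res$per_contig$id == "c"], 0)
  # all coordinates identical: a = b so every s = 0
  X2 <- matrix(1, 4, 2, dimnames = list(paste0("c", 1:4), NULL))
  res2 <- silhouette_scores(X2, setNames(c("A", "A", "B", "B"), rownames(X2)),
                            standardize = FALSE)
  expect_equal(res2$per_contig$silhouette, rep(0, 4))
  expect_error(silhouette_scores(X, c(a = "A", b = "A", c = "A")), "2 bins")
  X3 <- X; X3[1, 1] <- NaN
  expect_error(silhouette_scores(X3, c(a = "A", b = "A", c = "B")), "a")
})

test_that("silhouette cross-checks against cluster::silhouette", {
  set.seed(7)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(paste0("c", 1:40), NULL))
  lab <- setNames(sample(c("u", "v", "w"), 40, replace = TRUE), rownames(X))
  res <- silhouette_scores(X, lab, standardize = FALSE)
  ref <- cluster::silhouette(as.integer(factor(lab)), stats::dist(X))
  expect_equal(res$overall_mean, mean(ref[, "sil_width"]), tolerance = 1e-9)
})

test_that("ARI matches the worked example and pair-counting oracle", {
  a <- setNames(c(1, 1, 1, 2, 2, 2), paste0("x", 1:6))
  b <- setNames(c(1, 1, 2, 2, 2, 2), paste0("x", 1:6))
  res <- adjusted_rand(a, b)
  expect_equal(res$ari, 0.3243, tolerance = 1e-4)
  expect_equal(res$ari, brute_ari(unname(a), unname(b)), tolerance = 1e-12)
  expect_equal(res$n_shared, 6)
  # identity and the one-bin vs singleton extremes
  expect_equal(adjusted_rand(a, a)$ari, 1)
  one <- setNames(rep("z", 6), paste0("x", 1:6))
  singl <- setNames(paste0("s", 1:6), paste0("x", 1:6))
  expect_equal(adjusted_rand(one, singl)$ari, 0)
})

test_that("ARI is symmetric, relabel-invariant, and exact on random pairs", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    a <- sample(1:sample(2:6, 1), n, replace = TRUE)
    b <- sample(1:sample(2:6, 1), n, replace = TRUE)
    ids <- paste0("c", seq_len(n))
    ra <- adjusted_rand(setNames(a, ids), setNames(b, ids))
    expect_equal(ra$ari, brute_ari(a, b), tolerance = 1e-12)
    expect_equal(adjusted_rand(setNames(b, ids), setNames(a, ids))$ari, ra$ari)
    relab <- setNames(paste0("bin", a + 10), ids)  # renamed bins
    expect_equal(adjusted_rand(relab, setNames(b, ids))$ari, ra$ari)
    expect_equal(ra$ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-9)
  }
})

test_that("ARI restricts to the plans' shared binned contigs", {
  a <- setNames(c("x", "x", "y", "y"), c("c1", "c2", "c3", "c4"))
  b <- setNames(c("p", "p", "q"), c("c1", "c2", "c3"))
  res <- adjusted_rand(a, b)
  expect_equal(res$n_shared, 3)
  expect_error(adjusted_rand(a, setNames("z", "c9")), "fewer than 2")
})

test_that("completeness/redundancy follow the flat-catalog formulas", {
  g <- feature_group("g", c("g1", "g2", "g3", "g4"))
  tab <- build_contig_table(
    data.frame(id = c("c1", "c2"), hits = c("g1,g2,g2", "g3,other")),
    column_spec("hits", "feature_set")
  )
  cr <- completeness_redundancy(tab, group = g, feature_column = "hits")
  expect_equal(cr$completeness, 75)   # g1, g2, g3 of 4
  expect_equal(cr$redundancy, 25)     # one extra g2 copy
  # nothing found
  none <- build_contig_table(data.frame(id = "c1", hits = "zz"),
                             column_spec("hits", "feature_set"))
  cr0 <- completeness_redundancy(none, group = g, feature_column = "hits")
  expect_equal(c(cr0$completeness, cr0$redundancy), c(0, 0))
  # every member exactly once
  all1 <- build_contig_table(data.frame(id = "c1", hits = "g1,g2,g3,g4"),
                             column_spec("hits", "feature_set"))
  cr1 <- completeness_redundancy(all1, group = g, feature_column = "hits")
  expect_equal(c(cr1$completeness, cr1$redundancy), c(100, 0))
  # masked contigs are excluded
  m <- set_flag(tab, "c2", "mask", TRUE)
  expect_equal(completeness_redundancy(m, group = g, feature_column = "hits")$completeness, 50)
})

test_that("completeness and redundancy grow monotonically with the selection", {
  set.seed(33)
  g <- feature_group("g", paste0("m", 1:10))
  ids <- paste0("c", 1:30)
  cells <- vapply(ids, function(i)
    paste(sample(paste0("m", 1:12), sample(0:4, 1), replace = TRUE), collapse = ","), "")
  tab <- build_contig_table(data.frame(id = ids, hits = cells),
                            column_spec("hits", "feature_set"))
  sel <- character(0); prev <- c(0, 0)
  for (i in sample(ids)) {
    sel <- c(sel, i)
    cr <- completeness_redundancy(tab, sel, g, "hits")
    expect_gte(cr$completeness, prev[1])
    expect_gte(cr$redundancy, prev[2])
    prev <- c(cr$completeness, cr$redundancy)
  }
})

test_that("quality tiers partition the completeness/contamination plane", {
  expect_equal(as.character(classify_quality(95, 3)), "high")
  expect_equal(as.character(classify_quality(55, 8)), "medium")
  expect_equal(as.character(classify_quality(30, 5)), "low")
  expect_equal(as.character(classify_quality(80, 12)), "excluded")
  grid <- expand.grid(comp = c(49.99, 50, 89.99, 90, 100),
                      cont = c(0, 4.99, 5, 9.99, 10))
  tiers <- classify_quality(grid$comp, grid$cont)
  expect_false(anyNA(tiers))  # total: every point maps to exactly one tier
  expected <- with(grid, ifelse(cont >= 10, "excluded",
                    ifelse(comp >= 90 & cont < 5, "high",
                    ifelse(comp >= 50, "medium", "low"))))
  expect_equal(as.character(tiers), expected)
  expect_error(classify_quality(-1, 0), "non-negative")
})

test_that("bin comparison is length-weighted with a count variant", {
  lens <- c(c1 = 100, c2 = 300, c3 = 100)
  res <- compare_bins(c("c1", "c2"), c("c2", "c3"), lens)
  expect_equal(res$jaccard, 0.6)
  expect_equal(res$containment_a_in_b, 0.75)
  expect_equal(res$containment_b_in_a, 0.75)
  same <- compare_bins(c("c1", "c2"), c("c1", "c2"), lens)
  expect_equal(unlist(same[1, 1:3]), c(jaccard = 1, containment_a_in_b = 1,
                                       containment_b_in_a = 1))
  disj <- compare_bins("c1", "c3", lens)
  expect_equal(disj$jaccard, 0)
  cnt <- compare_bins(c("c1", "c2"), c("c2", "c3"), weighted = FALSE)
  expect_equal(cnt$jaccard, 1 / 3)
  expect_error(compare_bins(character(0), character(0)), "empty")
  expect_error(compare_bins("c1", "c9", lens), "c9")
})
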