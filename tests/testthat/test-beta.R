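test_that("phylo_jaccard matches hand-enumerated branch sets", {
  bi <- branch_incidence(fixture_tree(), fixture_pa())
  expect_equal(phylo_jaccard(bi, "c1", "c3"), 2 / 3)
  expect_equal(phylo_jaccard(bi, "c1", "c2"), 1)   # no shared branches
  expect_equal(phylo_jaccard(bi, "c1", "c1"), 0)
  expect_error(phylo_jaccard(bi, "c1", "zz"), "unknown cell")
})

test_that("the pairwise matrix is consistent, symmetric and bounded", {
  bi <- branch_incidence(fixture_tree(), fixture_pa())
  d <- pairwise_phylo_jaccard(bi)
  expect_equal(dim(unclass(d)), c(3L, 3L))
  for (a in rownames(d)) for (b in colnames(d))
    expect_equal(d[a, b], phylo_jaccard(bi, a, b))
  expect_equal(unclass(d), t(unclass(d)))
  expect_equal(unname(diag(unclass(d))), c(0, 0, 0))
  expect_true(all(d >= 0 & d <= 1))

  one_cell <- fixture_pa(list(c1 = c("A", "B")))
  expect_error(pairwise_phylo_jaccard(branch_incidence(fixture_tree(),
                                                       one_cell)),
               "at least 2 cells")
})

test_that("phylo-jaccard on unit star trees equals classical Jaccard", {
  tips <- paste0("t", 1:5)
  star <- read_tree(paste0("(", paste0(tips, ":1", collapse = ","), ");"))
  for (s in 1:10) {
    cells <- random_cells(star, 4, seed = s)
    bi <- branch_incidence(star, fixture_pa(cells))
    d <- pairwise_phylo_jaccard(bi)
    for (a in names(cells)) for (b in names(cells)) {
      inter <- length(intersect(cells[[a]], cells[[b]]))
      uni <- length(union(cells[[a]], cells[[b]]))
      expect_equal(d[a, b], 1 - inter / uni)
    }
  }
})

test_that("phylo-jaccard agrees with the path-enumeration oracle", {
  for (s in 1:5) {
    tree <- simulate_tree(10, seed = s)
    cells <- random_cells(tree, 3, seed = s + 10)
    bi <- branch_incidence(tree, fixture_pa(cells))
    d <- pairwise_phylo_jaccard(bi)
    for (a in names(cells)) for (b in names(cells))
      expect_equal(d[a, b],
                   oracle_phylo_jaccard(tree, cells[[a]], cells[[b]]))
  }
})

test_that("average linkage clustering agglomerates as derived by hand", {
  d <- matrix(c(0, 0.1, 0.8,
                0.1, 0, 0.8,
                0.8, 0.8, 0), 3, 3,
              dimnames = list(c("i1", "i2", "i3"), c("i1", "i2", "i3")))
  hc <- average_linkage_cluster(d)
  expect_equal(hc$height, c(0.1, 0.8))
  cl2 <- cut_clusters(hc, 2)
  expect_equal(cl2$cluster[cl2$item == "i1"], cl2$cluster[cl2$item == "i2"])
  expect_false(cl2$cluster[cl2$item == "i3"] == cl2$cluster[cl2$item == "i1"])

  # all-equal dissimilarities merge at a single height
  de <- matrix(0.4, 4, 4, dimnames = list(paste0("i", 1:4), paste0("i", 1:4)))
  diag(de) <- 0
  expect_equal(average_linkage_cluster(de)$height, rep(0.4, 3))

  # heights nondecreasing on proper dissimilarities; identical inputs give
  # identical merge sequences
  for (s in 1:5) {
    tree <- simulate_tree(12, seed = s)
    pa <- simulate_occurrences(tree, range_model(n_cells_x = 5,
                                                 n_cells_y = 3), seed = s)
    dm <- pairwise_phylo_jaccard(branch_incidence(tree, pa))
    h1 <- average_linkage_cluster(dm)
    expect_true(all(diff(h1$height) >= -1e-12))
    expect_identical(h1$merge, average_linkage_cluster(dm)$merge)
  }

  dn <- d; dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(average_linkage_cluster(dn), "NaN")
})

test_that("cut_clusters covers the degenerate cuts and validates k", {
  bi <- branch_incidence(fixture_tree(), fixture_pa())
  hc <- average_linkage_cluster(pairwise_phylo_jaccard(bi))
  expect_equal(nrow(dplyr::distinct(cut_clusters(hc, 1)["cluster"])), 1)
  allk <- cut_clusters(hc, 3)
  expect_equal(length(unique(allk$cluster)), 3)
  expect_error(cut_clusters(hc, 0), "k")
  expect_error(cut_clusters(hc, 4), "k")
})

test_that("dendrograms round-trip to newick with cophenetic heights", {
  d <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- average_linkage_cluster(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(hc, path)
  tr <- read_tree(path)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  # cophenetic distances equal the merge heights
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd["a", "b"], 0.2)
  expect_equal(cd["a", "c"], 0.6)
})
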