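test_that("simulate_tree produces valid seeded pure-birth trees", {
  t1 <- simulate_tree(1, seed = 3)
  expect_s3_class(t1, "phylo")
  expect_equal(length(t1$tip.label), 1)
  expect_gt(tree_length(t1), 0)

  t64a <- simulate_tree(64, seed = 7)
  t64b <- simulate_tree(64, seed = 7)
  expect_identical(ape::write.tree(t64a), ape::write.tree(t64b))
  expect_equal(length(t64a$tip.label), 64)
  # strictly bifurcating rooted: 2n - 2 edges, n - 1 internal nodes
  expect_equal(nrow(t64a$edge), 126)
  expect_equal(t64a$Nnode, 63)
  expect_true(all(t64a$edge.length > 0))
  expect_false(identical(ape::write.tree(simulate_tree(64, seed = 8)),
                         ape::write.tree(t64a)))
  expect_error(simulate_tree(0), "positive integer")
  expect_error(simulate_tree(2, birth_rate = 0), "positive")
})

test_that("simulate_occurrences respects the range model and seed", {
  tr <- simulate_tree(64, seed = 7)
  pa1 <- simulate_occurrences(tr, range_model(), seed = 3)
  pa2 <- simulate_occurrences(tr, range_model(), seed = 3)
  expect_identical(pa1$incidence, pa2$incidence)
  expect_setequal(pa_taxa(pa1), tr$tip.label)
  expect_true(all(pa1$incidence %in% c(0L, 1L)))
  expect_true(all(pa_ranges(pa1) >= 1))
  expect_false(identical(pa1$incidence,
                         simulate_occurrences(tr, range_model(), seed = 4)$incidence))

  # degenerate radius: every taxon confined to a single cell
  tiny <- range_model(range_radius_log_mean = log(1e-4),
                      range_radius_log_sd = 0)
  pa_tiny <- simulate_occurrences(tr, tiny, seed = 5)
  expect_true(all(pa_ranges(pa_tiny) == 1))
})

test_that("endemism scenarios are injected by construction contract", {
  tr <- simulate_tree(32, seed = 2)
  pa <- simulate_occurrences(tr, range_model(), seed = 2)
  target <- pa_cells(pa)[1]

  base_draw <- mean(tr$edge.length[tr$edge[, 2] <= 32])
  paleo <- inject_endemism_scenario(
    tr, pa, endemism_scenario("paleo", target, branch_scale = 10,
                              range_cells = 1), seed = 9)
  expect_equal(length(paleo$tree$tip.label), 33)
  tipi <- match(paleo$injected, paleo$tree$tip.label)
  inj_len <- paleo$tree$edge.length[match(tipi, paleo$tree$edge[, 2])]
  expect_equal(inj_len, base_draw * 10)
  expect_equal(unname(pa_ranges(paleo$matrix)[paleo$injected]), 1L)
  expect_equal(sum(paleo$matrix$incidence[target, paleo$injected]), 1)
  # untouched base data
  expect_identical(paleo$matrix$incidence[, pa_taxa(pa)], pa$incidence)

  neo <- inject_endemism_scenario(
    tr, pa, endemism_scenario("neo", target, n_taxa = 5), seed = 9)
  expect_equal(length(neo$injected), 5)
  expect_true(all(pa_ranges(neo$matrix)[neo$injected] == 2))
  expect_true(all(neo$matrix$incidence[target, neo$injected] == 1))
  # sisters: injected tips form a clade
  mrca <- ape::getMRCA(neo$tree, neo$injected)
  expect_setequal(ape::extract.clade(neo$tree, mrca)$tip.label, neo$injected)

  expect_error(
    inject_endemism_scenario(tr, pa, endemism_scenario("paleo", "no_such"),
                             seed = 1),
    "invalid scenario")
})

test_that("paleo-injected branches land in the top branch-length decile", {
  for (s in 1:5) {
    tr <- simulate_tree(64, seed = s)
    pa <- simulate_occurrences(tr, range_model(), seed = s)
    inj <- inject_endemism_scenario(
      tr, pa, endemism_scenario("paleo", pa_cells(pa)[1]), seed = s)
    tipi <- match(inj$injected, inj$tree$tip.label)
    len <- inj$tree$edge.length[match(tipi, inj$tree$edge[, 2])]
    expect_gte(len, unname(stats::quantile(inj$tree$edge.length, 0.9)))
  }
})

test_that("simulate_null_dataset hits its margins exactly or errors", {
  # forced unique matrix
  forced <- simulate_null_dataset(c(c1 = 2L), c(A = 1L, B = 1L), seed = 1)
  expect_equal(unname(forced$incidence), matrix(1L, 1, 2))

  # 2x2: both permutation matrices occur across seeds
  firsts <- vapply(1:200, function(s)
    simulate_null_dataset(c(c1 = 1L, c2 = 1L), c(A = 1L, B = 1L),
                          seed = s)$incidence[1, 1], integer(1))
  expect_setequal(unique(firsts), c(0L, 1L))

  # margins always exact
  for (s in 1:5) {
    rich <- c(c1 = 3L, c2 = 1L, c3 = 2L, c4 = 2L)
    rng <- c(A = 2L, B = 1L, C = 3L, D = 1L, E = 1L)
    out <- simulate_null_dataset(rich, rng, seed = s)
    expect_equal(rowSums(out$incidence), rich)
    expect_equal(colSums(out$incidence), rng)
  }

  expect_error(simulate_null_dataset(c(c1 = 1L), c(A = 1L, B = 1L)),
               "infeasible")
  # Gale-Ryser violation with equal totals: one cell cannot hold 2 copies
  expect_error(simulate_null_dataset(c(c1 = 2L), c(A = 2L)), "infeasible")
})
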