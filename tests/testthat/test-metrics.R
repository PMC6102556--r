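test_that("the six metrics reproduce the hand-derived fixture", {
  tr <- fixture_tree()
  pa <- fixture_pa()
  bi <- branch_incidence(tr, pa)

  tr_surf <- taxon_richness(pa)
  expect_equal(stats::setNames(tr_surf$value, tr_surf$cell_id),
               c(c1 = 2, c2 = 1, c3 = 3))
  we <- weighted_endemism(pa)
  expect_equal(stats::setNames(we$value, we$cell_id),
               c(c1 = 1.5, c2 = 0.5, c3 = 2.0))
  pd <- phylogenetic_diversity(bi)
  expect_equal(stats::setNames(pd$value, pd$cell_id),
               c(c1 = 3, c2 = 2, c3 = 5))
  pe <- phylogenetic_endemism(bi)
  expect_equal(stats::setNames(pe$value, pe$cell_id),
               c(c1 = 2, c2 = 1, c3 = 3))

  # cell with all taxa reaches total tree length; single-tip cell = path
  pa_all <- fixture_pa(list(c1 = c("A", "B", "C", "D"), c2 = "A"))
  bi_all <- branch_incidence(tr, pa_all)
  pd_all <- phylogenetic_diversity(bi_all)
  expect_equal(pd_all$value[pd_all$cell_id == "c1"], 6)
  expect_equal(pd_all$value[pd_all$cell_id == "c2"], 2)
})

test_that("RPD follows the stated ratio rule and its symmetries", {
  tr <- read_tree("((A:4,B:1):1,(C:1,D:1):1);")
  pa <- fixture_pa(list(c1 = c("A", "B"), c2 = c("C", "D")))
  bi <- branch_incidence(tr, pa)
  bi_eq <- branch_incidence(equalize_branch_lengths(tr), pa)
  rpd <- relative_metric(phylogenetic_diversity(bi),
                         phylogenetic_diversity(bi_eq))
  # PD actual at {A,B} = 4+1+1 = 6; equalized = 3 branches x 9/6 = 4.5
  expect_equal(rpd$value[rpd$cell_id == "c1"], 6 / 4.5)
  expect_equal(rpd$metric[1], "RPD")

  # equal-branch tree: RPD identically 1
  surf_eq <- diversity_metrics(pa, equalize_branch_lengths(tr))
  expect_equal(surf_eq$value[surf_eq$metric == "RPD"], c(1, 1))

  # invariance to global branch rescaling
  tr10 <- tr; tr10$edge.length <- tr10$edge.length * 10
  r1 <- diversity_metrics(pa, tr)
  r2 <- diversity_metrics(pa, tr10)
  expect_equal(r2$value[r2$metric == "RPD"], r1$value[r1$metric == "RPD"])
  expect_equal(r2$value[r2$metric == "RPE"], r1$value[r1$metric == "RPE"])

  # zero comparison cells are refused
  expect_error(relative_metric(phylogenetic_diversity(bi),
                               dplyr::mutate(phylogenetic_diversity(bi_eq),
                                             value = 0)),
               "comparison value 0")
})

test_that("conservation identities hold on simulated datasets", {
  for (s in 1:5) {
    tree <- simulate_tree(40, seed = s)
    pa <- simulate_occurrences(tree, range_model(), seed = s)
    surf <- diversity_metrics(pa, tree)
    expect_equal(sum(surf$value[surf$metric == "WE"]), 40,
                 tolerance = 1e-9)
    expect_equal(sum(surf$value[surf$metric == "PE"]), tree_length(tree),
                 tolerance = 1e-9)
    expect_equal(sum(surf$value[surf$metric == "TR"]), sum(pa_ranges(pa)))
  }
})

test_that("metrics are monotone in added taxa and properly dominated", {
  tree <- simulate_tree(20, seed = 11)
  pa <- simulate_occurrences(tree, range_model(n_cells_x = 8, n_cells_y = 5),
                             seed = 11)
  surf <- diversity_metrics(pa, tree)
  wide <- tidyr::pivot_wider(surf, names_from = "metric",
                             values_from = "value")
  expect_true(all(wide$PE <= wide$PD + 1e-12))
  expect_true(all(wide$WE <= wide$TR + 1e-12))
  expect_true(all(wide$PE >= 0 & wide$PD >= 0 & wide$WE >= 0))
  expect_true(all(wide$RPD > 0 & wide$RPE > 0))

  # adding a taxon to a cell never decreases that cell's metrics
  inc <- pa$incidence
  absent <- which(inc == 0L, arr.ind = TRUE)
  withr::with_seed(42, picks <- absent[sample(nrow(absent), 5), , drop = FALSE])
  for (r in seq_len(nrow(picks))) {
    inc2 <- inc
    inc2[picks[r, 1], picks[r, 2]] <- 1L
    pa2 <- pa_matrix(inc2, cells = pa$cells)
    cell <- rownames(inc)[picks[r, 1]]
    s1 <- diversity_metrics(pa, tree)
    s2 <- diversity_metrics(pa2, tree)
    for (m in c("TR", "WE", "PD", "PE")) {
      v1 <- s1$value[s1$metric == m & s1$cell_id == cell]
      v2 <- s2$value[s2$metric == m & s2$cell_id == cell]
      expect_gte(v2, v1 - 1e-12)
    }
  }
})

test_that("star trees reduce PD to TR and PE to WE", {
  star <- read_tree("(A:1,B:1,C:1,D:1,E:1);")
  pa <- fixture_pa(list(c1 = c("A", "B"), c2 = c("B", "C", "D"),
                        c3 = c("A", "E")))
  for (conv in c("root", "crown")) {
    bi <- branch_incidence(star, pa)
    pd <- phylogenetic_diversity(bi, convention = conv)
    pe <- phylogenetic_endemism(bi, convention = conv)
    tr_s <- taxon_richness(pa)
    we <- weighted_endemism(pa)
    expect_equal(pd$value, tr_s$value)
    expect_equal(pe$value, we$value)
  }
})

test_that("PD agrees with an independent reference implementation", {
  skip_if_not_installed("picante")
  for (s in 1:3) {
    tree <- simulate_tree(24, seed = s)
    pa <- simulate_occurrences(tree, range_model(n_cells_x = 6,
                                                 n_cells_y = 4), seed = s)
    bi <- branch_incidence(tree, pa)
    mine <- phylogenetic_diversity(bi)
    ref <- picante::pd(pa$incidence[, tree$tip.label, drop = FALSE], tree,
                       include.root = TRUE)
    expect_equal(unname(stats::setNames(mine$value, mine$cell_id)[rownames(ref)]),
                 ref$PD, tolerance = 1e-9)
  }
})
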