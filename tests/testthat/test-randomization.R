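test_that("randomize_matrix preserves both margins exactly", {
  tr <- simulate_tree(30, seed = 4)
  pa <- simulate_occurrences(tr, range_model(n_cells_x = 8, n_cells_y = 6),
                             seed = 4)
  for (s in 1:10) {
    r <- randomize_matrix(pa, seed = s)
    expect_identical(rowSums(r$incidence), rowSums(pa$incidence))
    expect_identical(colSums(r$incidence), colSums(pa$incidence))
    expect_true(all(r$incidence %in% c(0L, 1L)))
  }
})

test_that("randomize_matrix explores the fixed-margin polytope", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("c1", "c2"), c("A", "B")))
  pa <- pa_matrix(m)
  states <- vapply(1:100, function(s)
    randomize_matrix(pa, seed = s)$incidence[1, 1], integer(1))
  expect_setequal(unique(states), c(0L, 1L))  # both permutation matrices

  ones <- pa_matrix(matrix(1L, 3, 4, dimnames = list(paste0("c", 1:3),
                                                     paste0("t", 1:4))))
  expect_identical(randomize_matrix(ones, seed = 1)$incidence,
                   ones$incidence)  # unique feasible state
})

test_that("the null ensemble is seeded, complete and richness-preserving", {
  tree <- simulate_tree(20, seed = 5)
  pa <- simulate_occurrences(tree, range_model(n_cells_x = 6, n_cells_y = 4),
                             seed = 5)
  cfg <- randomization_config(n_reps = 99, seed = 17)
  e1 <- build_null_ensemble(pa, tree, cfg)
  e2 <- build_null_ensemble(pa, tree, cfg)
  expect_identical(e1$nulls, e2$nulls)
  expect_identical(e1$observed, e2$observed)
  for (m in c("PD", "RPD", "PE_actual", "PE_equalized", "RPE")) {
    expect_equal(dim(e1$nulls[[m]]), c(nrow(pa$incidence), 99))
    expect_false(anyNA(e1$nulls[[m]]))
  }
  e3 <- build_null_ensemble(pa, tree, randomization_config(n_reps = 99,
                                                           seed = 18))
  expect_false(identical(e1$nulls$PD, e3$nulls$PD))

  # misaligned inputs are refused
  expect_error(build_null_ensemble(pa, simulate_tree(5, seed = 1), cfg),
               "not aligned")
})

# hand-built ensemble with known rank counts
toy_ensemble <- function(obs, nulls_vec) {
  n <- length(nulls_vec)
  structure(list(
    observed = tibble::tibble(cell_id = "c1", PD = obs, RPD = obs,
                              PE_actual = obs, PE_equalized = obs, RPE = obs),
    nulls = list(PD = matrix(nulls_vec, 1), RPD = matrix(nulls_vec, 1),
                 PE_actual = matrix(nulls_vec, 1),
                 PE_equalized = matrix(nulls_vec, 1),
                 RPE = matrix(nulls_vec, 1)),
    cells = tibble::tibble(cell_id = "c1", x = 0, y = 0),
    config = randomization_config(n_reps = length(nulls_vec), seed = 1)
  ), class = "null_ensemble")
}

test_that("significance ranks follow the (1 + count) / (1 + n) convention", {
  # observed above all 999 nulls: p_high = 1/1000, sig-high two-tailed
  e_hi <- toy_ensemble(1000, seq_len(999))
  s_hi <- significance_ranks(e_hi, "PD", tail = "two", alpha = 0.05)
  expect_equal(s_hi$p_high, 0.001)
  expect_equal(s_hi$flag, "sig-high")

  # observed below all nulls: p_low = 1/1000, sig-low
  e_lo <- toy_ensemble(0, seq_len(999))
  s_lo <- significance_ranks(e_lo, "PD", tail = "two", alpha = 0.05)
  expect_equal(s_lo$p_low, 0.001)
  expect_equal(s_lo$flag, "sig-low")

  # observed at the null median: not significant, rank duality holds
  e_mid <- toy_ensemble(500, seq_len(999))
  s_mid <- significance_ranks(e_mid, "PD", tail = "two", alpha = 0.05)
  expect_equal(s_mid$flag, "ns")
  expect_gte(s_mid$p_high + s_mid$p_low, 1 + 1 / 1000)

  # one-tailed uses the whole alpha
  s_one <- significance_ranks(toy_ensemble(961, seq_len(999)), "PE_actual",
                              tail = "high", alpha = 0.05)
  expect_equal(s_one$p_high, 40 / 1000)
  expect_equal(s_one$flag, "sig-high")

  expect_error(significance_ranks(e_hi, "XX"), "unknown metric")
})

sig_row <- function(p_high, p_low, alpha = 0.05, tail = "two") {
  thr <- if (tail == "two") alpha / 2 else alpha
  flag <- if (p_high <= thr) "sig-high"
          else if (tail == "two" && p_low <= thr) "sig-low" else "ns"
  out <- tibble::tibble(cell_id = "c1", x = 0, y = 0, metric = "PE_actual",
                        observed = 1, p_high = p_high, p_low = p_low,
                        flag = flag)
  class(out) <- c("sig_surface", class(out))
  out
}

test_that("canape_classify implements the two-step categorical test", {
  classify1 <- function(p1, rpe_high, rpe_low, ...) {
    cm <- canape_classify(sig_row(p1, 1 - p1),
                          sig_row(0.5, 0.5),
                          sig_row(rpe_high, rpe_low), ...)
    as.character(cm$category)
  }
  # step-one pass + RPE significantly high -> paleo
  expect_equal(classify1(0.03, 0.01, 0.99), "paleo")
  # step-one pass + RPE significantly low -> neo
  expect_equal(classify1(0.03, 0.99, 0.01), "neo")
  # step-one p below the stricter level + RPE ns -> super
  expect_equal(classify1(0.004, 0.5, 0.5), "super")
  # step-one pass (not strict) + RPE ns -> mixed
  expect_equal(classify1(0.03, 0.5, 0.5), "mixed")
  # step-one failure -> not significant regardless of RPE
  expect_equal(classify1(0.30, 0.01, 0.99), "not-significant")

  # either-tree variant passes step one through the comparison tree
  cm_either <- canape_classify(sig_row(0.5, 0.5), sig_row(0.02, 0.98),
                               sig_row(0.99, 0.01), step_one = "either")
  expect_equal(as.character(cm_either$category), "neo")
  cm_actual <- canape_classify(sig_row(0.5, 0.5), sig_row(0.02, 0.98),
                               sig_row(0.99, 0.01), step_one = "actual")
  expect_equal(as.character(cm_actual$category), "not-significant")
})

test_that("tidy and glance summarise a null ensemble", {
  tree <- simulate_tree(12, seed = 2)
  pa <- simulate_occurrences(tree, range_model(n_cells_x = 5, n_cells_y = 3),
                             seed = 2)
  ens <- build_null_ensemble(pa, tree, randomization_config(n_reps = 49,
                                                            seed = 3))
  td <- generics::tidy(ens)
  expect_equal(nrow(td), nrow(pa$incidence) * 5)
  expect_true(all(td$p_high > 0 & td$p_high <= 1))
  gl <- generics::glance(ens)
  expect_equal(gl$n_reps, 49L)
  expect_equal(gl$n_cells, nrow(pa$incidence))
})
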