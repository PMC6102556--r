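#' Type-I-error calibration of the randomization tests
#'
#' Monte-Carlo check that the rank-based tests hold their nominal levels
#' when the data really are draws from the fixed-margin null process. One
#' pure-birth tree and one disc-model matrix are simulated, then for each
#' outer replicate the matrix is replaced by a fresh fixed-margin draw (so
#' the null is true by construction) and the full randomization test is
#' run. Reported per outer replicate: the fraction of cells significant in
#' the two-tailed PD test at `alpha`, the fraction passing the one-tailed
#' PE test at `alpha` (CANAPE step one), and the fraction with one-tailed
#' PE p-value at or below `alpha_super`.
#'
#' @param seed integer seed driving every stage
#' @param n_outer number of outer replicates (default 20)
#' @param n_taxa tree size (default 64)
#' @param model a [range_model()] (default: 20 x 10 grid of 25-km cells)
#' @param n_reps randomizations per test (default 999)
#' @param alpha nominal level (default 0.05)
#' @param alpha_super stricter step-one level (default 0.01)
#' @return tibble with one row per outer replicate: `outer`, `n_cells`,
#'   `pd_two_rate`, `pe_high_rate`, `pe_super_rate`
#' @export
calibrate_null_rates <- function(seed = 1, n_outer = 20, n_taxa = 64,
                                 model = range_model(), n_reps = 999,
                                 alpha = 0.05, alpha_super = 0.01) {
  tree <- simulate_tree(n_taxa, seed = derive_seed(seed, 1))
  purrr::map_dfr(seq_len(n_outer), function(i) {
    pa0 <- simulate_occurrences(tree, model, seed = derive_seed(seed, 600 + i))
    pa_null <- randomize_matrix(pa0, seed = derive_seed(seed, 100 + i))
    ens <- build_null_ensemble(
      pa_null, tree,
      randomization_config(n_reps = n_reps,
                           alpha_two_tailed = alpha,
                           alpha_super = alpha_super,
                           seed = derive_seed(seed, 200 + i)))
    sig_pd <- significance_ranks(ens, "PD", tail = "two", alpha = alpha)
    pe <- significance_ranks(ens, "PE_actual", tail = "high", alpha = alpha)
    tibble(outer = i, n_cells = nrow(sig_pd),
           pd_two_rate = mean(sig_pd$flag != "ns"),
           pe_high_rate = mean(pe$p_high <= alpha),
           pe_super_rate = mean(pe$p_high <= alpha_super))
  })
}

#' Recovery of injected endemism scenarios by CANAPE
#'
#' Power check of the endemism classification: injects a neo or paleo
#' scenario at the richest cell of a simulated dataset and records the
#' CANAPE category assigned to the target cell, over several seeds. A
#' paleo injection counts as recovered when the target is classified paleo
#' or super; a neo injection when it is classified neo. Step one defaults
#' to the either-tree rule, under which rare-branch concentrations are
#' detectable regardless of their branch lengths.
#'
#' @param kind `"neo"` or `"paleo"`
#' @param seed integer seed
#' @param n_seeds number of independent datasets (default 20)
#' @param n_taxa tree size (default 64)
#' @param model a [range_model()]
#' @param n_reps randomizations per test (default 999)
#' @param step_one CANAPE step-one variant (default `"either"`)
#' @return tibble with one row per seed: `replicate`, `target_cell`,
#'   `category`, `recovered`
#' @export
scenario_recovery <- function(kind = c("neo", "paleo"), seed = 1,
                              n_seeds = 20, n_taxa = 64,
                              model = range_model(), n_reps = 999,
                              step_one = c("either", "actual")) {
  kind <- match.arg(kind)
  step_one <- match.arg(step_one)
  tree <- simulate_tree(n_taxa, seed = derive_seed(seed, 1))
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    pa <- simulate_occurrences(tree, model, seed = derive_seed(seed, 300 + i))
    # inject at a cell of median richness: the scenario is a cell whose
    # endemism signal is dominated by the injected rare taxa, not the
    # extreme tail of the base richness distribution
    rich <- pa_richness(pa)
    target <- pa_cells(pa)[order(rich)][ceiling(length(rich) / 2)]
    inj <- inject_endemism_scenario(tree, pa,
                                    endemism_scenario(kind, target),
                                    seed = derive_seed(seed, 400 + i))
    ens <- build_null_ensemble(
      inj$matrix, inj$tree,
      randomization_config(n_reps = n_reps,
                           seed = derive_seed(seed, 500 + i)))
    cat_i <- canape(ens, step_one = step_one)
    got <- as.character(cat_i$category[cat_i$cell_id == target])
    tibble(replicate = i, target_cell = target, category = got,
           recovered = if (kind == "paleo") got %in% c("paleo", "super")
                       else got == "neo")
  })
}
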