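#' Randomization configuration
#'
#' Settings of the constrained null model: number of randomizations
#' (default 999), the two-tailed significance level (default 0.05), the
#' stricter one-tailed level that upgrades mixed- to super-endemism
#' (default 0.01), the seed, and the curveball chain settings expressed as
#' multiples of the number of matrix presences (burn-in before the first
#' emitted matrix, thinning between consecutive matrices).
#'
#' @param n_reps number of null matrices (default 999)
#' @param alpha_two_tailed two-tailed alpha in (0,1), default 0.05
#' @param alpha_super stricter step-one alpha for super-endemism, default
#'   0.01; must be below `alpha_two_tailed`
#' @param seed integer seed
#' @param burn_in_swaps_factor burn-in trades per presence (default 5)
#' @param thin_swaps_factor trades per presence between emitted matrices
#'   (default 1)
#' @return object of class `randomization_config`
#' @export
randomization_config <- function(n_reps = 999, alpha_two_tailed = 0.05,
                                 alpha_super = 0.01, seed = 1,
                                 burn_in_swaps_factor = 5,
                                 thin_swaps_factor = 1) {
  stopifnot(n_reps >= 1, alpha_two_tailed > 0, alpha_two_tailed < 1,
            alpha_super > 0, burn_in_swaps_factor > 0,
            thin_swaps_factor > 0)
  if (alpha_super >= alpha_two_tailed)
    abort("`alpha_super` must be below `alpha_two_tailed`")
  structure(list(n_reps = as.integer(n_reps),
                 alpha_two_tailed = alpha_two_tailed,
                 alpha_super = alpha_super, seed = as.integer(seed),
                 burn_in_swaps_factor = burn_in_swaps_factor,
                 thin_swaps_factor = thin_swaps_factor),
            class = "randomization_config")
}

# internal: draw n_reps fixed-margin matrices (cells x taxa x n_reps array)
# from a sequential curveball chain
curveball_draws <- function(inc, n_reps, seed, burn_in_swaps_factor = 5,
                            thin_swaps_factor = 1) {
  if (nrow(inc) < 2 || ncol(inc) < 2) {
    # margins pin the matrix down completely: the input is the unique state
    return(array(inc, dim = c(nrow(inc), ncol(inc), n_reps),
                 dimnames = list(rownames(inc), colnames(inc), NULL)))
  }
  presences <- sum(inc)
  burnin <- max(1L, ceiling(burn_in_swaps_factor * presences))
  thin <- max(1L, ceiling(thin_swaps_factor * presences))
  nm <- vegan::nullmodel(inc, "curveball")
  sims <- stats::simulate(nm, nsim = n_reps, seed = seed, burnin = burnin,
                          thin = thin)
  dimnames(sims) <- list(rownames(inc), colnames(inc), NULL)
  sims
}

#' Draw one fixed-margin randomization of a matrix
#'
#' Returns a binary matrix with exactly the input's per-cell richness (row
#' sums) and per-taxon ranges (column sums), drawn by curveball trading:
#' repeated random pair-of-cells trades of their exchangeable taxa, which
#' preserve both margins by construction. This is the null model of the
#' significance tests: it amounts to handing each cell a random selection
#' of the same number of terminals on the tree.
#'
#' @param pa a [pa_matrix()]
#' @param seed integer seed
#' @param burn_in_swaps_factor burn-in trades per presence (default 5)
#' @return a [pa_matrix()] with identical margins and cell metadata
#' @export
randomize_matrix <- function(pa, seed = 1, burn_in_swaps_factor = 5) {
  stopifnot(inherits(pa, "pa_matrix"), nrow(pa$incidence) > 0)
  sims <- curveball_draws(pa$incidence, 1, seed, burn_in_swaps_factor, 1)
  out <- sims[, , 1, drop = TRUE]
  if (is.null(dim(out)))
    out <- matrix(out, nrow(pa$incidence), ncol(pa$incidence),
                  dimnames = dimnames(pa$incidence))
  mode(out) <- "integer"
  pa_matrix(out, cells = pa$cells, drop_empty = FALSE)
}

# internal: per-branch descendant indicator (taxa x branches) and lengths
branch_system <- function(tree, taxa) {
  # recover the taxa x branches indicator from a one-taxon-per-cell probe
  probe <- pa_matrix(diag_matrix(taxa), drop_empty = FALSE)
  bi <- branch_incidence(tree, probe)
  list(D = bi$counts[taxa, , drop = FALSE], lengths = bi$lengths,
       branch_id = bi$branch_id)
}

diag_matrix <- function(taxa) {
  m <- diag(length(taxa))
  mode(m) <- "integer"
  dimnames(m) <- list(taxa, taxa)
  m
}

# internal: PD/PE on actual and equalized lengths for one incidence matrix.
# D: taxa x branches indicator; L, Leq: branch lengths. Branch ranges are
# recomputed per matrix; path convention = tips-to-root.
pd_pe_values <- function(inc, D, L, Leq) {
  counts <- inc %*% D
  pres <- counts > 0
  rb <- colSums(pres)
  wpe <- ifelse(rb > 0, L / rb, 0)
  wpe_eq <- ifelse(rb > 0, Leq / rb, 0)
  list(pd = as.numeric(pres %*% L),
       pd_eq = as.numeric(pres %*% Leq),
       pe = as.numeric(pres %*% wpe),
       pe_eq = as.numeric(pres %*% wpe_eq))
}

#' Build the null ensemble for the significance tests
#'
#' Runs the constrained randomization: for each of `n_reps` fixed-margin
#' null matrices, recomputes PD and PE per cell on both the actual tree
#' and the equal-branch-length comparison tree (branch ranges recomputed
#' from the randomized cell sets, branch lengths fixed), plus the ratios
#' RPD and RPE. Observed values are attached. The whole ensemble is a pure
#' function of (matrix, tree, config seed).
#'
#' @param pa a [pa_matrix()] aligned to `tree`
#' @param tree a rooted `phylo` tree
#' @param config a [randomization_config()]
#' @return object of class `null_ensemble` with per-metric observed vectors
#'   and cells x n_reps null matrices for metrics PD, RPD, PE_actual,
#'   PE_equalized, RPE
#' @export
build_null_ensemble <- function(pa, tree, config = randomization_config()) {
  stopifnot(inherits(pa, "pa_matrix"), inherits(config, "randomization_config"))
  if (!setequal(pa_taxa(pa), tree$tip.label))
    abort("matrix and tree are not aligned; see align_matrix_to_tree()")
  taxa <- pa_taxa(pa)
  tree_eq <- equalize_branch_lengths(tree)
  bs <- branch_system(tree, taxa)
  Leq <- rep(sum(bs$lengths) / length(bs$lengths), length(bs$lengths))
  inc <- pa$incidence
  obs <- pd_pe_values(inc, bs$D, bs$lengths, Leq)
  n_cells <- nrow(inc)
  metrics <- c("PD", "RPD", "PE_actual", "PE_equalized", "RPE")
  nulls <- lapply(metrics, function(m)
    matrix(NA_real_, n_cells, config$n_reps,
           dimnames = list(rownames(inc), NULL)))
  names(nulls) <- metrics
  sims <- curveball_draws(inc, config$n_reps, config$seed,
                          config$burn_in_swaps_factor,
                          config$thin_swaps_factor)
  for (r in seq_len(config$n_reps)) {
    v <- pd_pe_values(sims[, , r], bs$D, bs$lengths, Leq)
    nulls$PD[, r] <- v$pd
    nulls$RPD[, r] <- v$pd / v$pd_eq
    nulls$PE_actual[, r] <- v$pe
    nulls$PE_equalized[, r] <- v$pe_eq
    nulls$RPE[, r] <- v$pe / v$pe_eq
  }
  observed <- tibble(
    cell_id = rownames(inc),
    PD = obs$pd, RPD = obs$pd / obs$pd_eq,
    PE_actual = obs$pe, PE_equalized = obs$pe_eq,
    RPE = obs$pe / obs$pe_eq
  )
  structure(list(observed = observed, nulls = nulls, cells = pa$cells,
                 config = config, tree = tree, tree_equalized = tree_eq),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d cells, %d null reps, metrics: %s\n",
              nrow(x$observed), x$config$n_reps,
              paste(names(x$nulls), collapse = ", ")))
  invisible(x)
}

#' Rank-based significance surface for one metric
#'
#' Permutation p-values from the null ensemble, never zero by construction:
#' `p_high = (1 + #\{null >= observed\}) / (1 + n_reps)` and `p_low`
#' analogously with `<=`; ties count toward significance in both tails.
#' Two-tailed tests split alpha evenly: a cell is `sig-high` iff
#' `p_high <= alpha / 2` (one-tailed: `p_high <= alpha`), `sig-low`
#' symmetrically, else `ns`.
#'
#' @param ensemble a [build_null_ensemble()] result
#' @param metric one of `"PD"`, `"RPD"`, `"PE_actual"`, `"PE_equalized"`,
#'   `"RPE"`
#' @param tail `"two"` (default) or `"high"`
#' @param alpha significance level (default from the ensemble's config)
#' @return tibble (`sig_surface`) with columns cell_id, x, y, metric,
#'   observed, p_high, p_low, flag
#' @export
significance_ranks <- function(ensemble, metric, tail = c("two", "high"),
                               alpha = NULL) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  tail <- match.arg(tail)
  if (!metric %in% names(ensemble$nulls))
    abort(paste0("unknown metric: ", metric, "; available: ",
                 paste(names(ensemble$nulls), collapse = ", ")))
  alpha <- alpha %||% ensemble$config$alpha_two_tailed
  obs <- ensemble$observed[[metric]]
  nulls <- ensemble$nulls[[metric]]
  n_reps <- ncol(nulls)
  ge <- rowSums(nulls >= obs)
  le <- rowSums(nulls <= obs)
  p_high <- (1 + ge) / (1 + n_reps)
  p_low <- (1 + le) / (1 + n_reps)
  thr <- if (tail == "two") alpha / 2 else alpha
  flag <- rep("ns", length(obs))
  flag[p_high <= thr] <- "sig-high"
  if (tail == "two") flag[p_low <= thr] <- "sig-low"
  out <- tibble(cell_id = ensemble$observed$cell_id,
                x = ensemble$cells$x, y = ensemble$cells$y,
                metric = metric, observed = obs,
                p_high = p_high, p_low = p_low, flag = flag)
  attr(out, "tail") <- tail
  attr(out, "alpha") <- alpha
  class(out) <- c("sig_surface", class(out))
  out
}

#' CANAPE: categorical analysis of neo- and paleo-endemism
#'
#' Two-step classification of the cells. Step one: the cell must show
#' significantly high PE (one-tailed) at `alpha`; by default PE on the
#' actual tree, or, with `step_one = "either"`, on either the actual or
#' the comparison tree. Step two, for passing cells, reads the RPE
#' two-tailed test: significantly high RPE means rare long branches
#' (paleo-endemism), significantly low RPE rare short branches
#' (neo-endemism); otherwise the cell holds a mixture (mixed-endemism),
#' upgraded to super-endemism when its step-one p-value is at or below
#' `alpha_super`. Cells failing step one are not significant. Categories
#' are mutually exclusive and exhaustive.
#'
#' @param pe_sig_actual one-tailed `"high"` significance surface of
#'   `PE_actual`
#' @param pe_sig_equalized one-tailed `"high"` significance surface of
#'   `PE_equalized`
#' @param rpe_sig two-tailed significance surface of `RPE`
#' @param alpha step-one / step-two level (default 0.05)
#' @param alpha_super stricter step-one level for super-endemism (default
#'   0.01)
#' @param step_one `"actual"` (default) or `"either"`
#' @return tibble (`canape_map`) with columns cell_id, x, y, p_step_one,
#'   category (factor: not-significant, neo, paleo, mixed, super)
#' @export
canape_classify <- function(pe_sig_actual, pe_sig_equalized, rpe_sig,
                            alpha = 0.05, alpha_super = 0.01,
                            step_one = c("actual", "either")) {
  step_one <- match.arg(step_one)
  if (!setequal(pe_sig_actual$cell_id, rpe_sig$cell_id) ||
      !setequal(pe_sig_actual$cell_id, pe_sig_equalized$cell_id))
    abort("significance surfaces cover different cell sets")
  eq <- pe_sig_equalized[match(pe_sig_actual$cell_id,
                               pe_sig_equalized$cell_id), ]
  rpe <- rpe_sig[match(pe_sig_actual$cell_id, rpe_sig$cell_id), ]
  p1 <- if (step_one == "actual") pe_sig_actual$p_high
        else pmin(pe_sig_actual$p_high, eq$p_high)
  pass <- p1 <= alpha
  cat <- rep("not-significant", length(pass))
  rpe_high <- rpe$p_high <= alpha / 2
  rpe_low <- rpe$p_low <= alpha / 2
  cat[pass & rpe_high] <- "paleo"
  cat[pass & !rpe_high & rpe_low] <- "neo"
  mixed <- pass & !rpe_high & !rpe_low
  cat[mixed] <- ifelse(p1[mixed] <= alpha_super, "super", "mixed")
  out <- tibble(cell_id = pe_sig_actual$cell_id,
                x = pe_sig_actual$x, y = pe_sig_actual$y,
                p_step_one = p1,
                category = factor(cat, levels = c("not-significant", "neo",
                                                  "paleo", "mixed", "super")))
  class(out) <- c("canape_map", class(out))
  out
}

#' One-call CANAPE from a null ensemble
#'
#' Convenience wrapper running the three significance tests CANAPE needs
#' and classifying the cells.
#'
#' @param ensemble a [build_null_ensemble()] result
#' @param step_one `"actual"` (default) or `"either"`
#' @return a `canape_map` tibble (see [canape_classify()])
#' @export
canape <- function(ensemble, step_one = c("actual", "either")) {
  step_one <- match.arg(step_one)
  cfg <- ensemble$config
  a <- cfg$alpha_two_tailed
  canape_classify(
    significance_ranks(ensemble, "PE_actual", tail = "high", alpha = a),
    significance_ranks(ensemble, "PE_equalized", tail = "high", alpha = a),
    significance_ranks(ensemble, "RPE", tail = "two", alpha = a),
    alpha = a, alpha_super = cfg$alpha_super, step_one = step_one
  )
}
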