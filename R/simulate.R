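#' Simulate a pure-birth (Yule) phylogeny
#'
#' Generates a rooted, strictly bifurcating tree with `n_taxa` uniquely
#' labeled tips and strictly positive branch lengths, via a pure-birth
#' process with exponential waiting times. A Yule tree gives the
#' branch-length heterogeneity the relative metrics need without the extra
#' machinery of extinction. Fully reproducible per seed.
#'
#' @param n_taxa number of tips (>= 1)
#' @param birth_rate speciation rate (> 0), default 1
#' @param seed integer seed
#' @return a `phylo` tree with tips `t1 ... tn`
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1 || n_taxa < 1 ||
      n_taxa != round(n_taxa))
    abort("`n_taxa` must be a positive integer")
  if (birth_rate <= 0) abort("`birth_rate` must be positive")
  withr::with_seed(seed, {
    if (n_taxa == 1) {
      tr <- ape::read.tree(text = sprintf("(t1:%.12g);", rexp(1, birth_rate)))
    } else {
      tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
    }
    tr
  })
}

#' Species range model
#'
#' Parameters of the disc-range generator on a rectangular grid of 25-km
#' cells: each taxon occupies every cell whose centroid falls within a
#' lognormally distributed radius (in cell units) of a drawn range center,
#' clipped to the grid; the nearest cell is always included so each taxon
#' occupies at least one cell. With `center_clustering > 0` centers are
#' drawn from a Gaussian mixture (3 components placed uniformly, component
#' spread shrinking as clustering grows), emulating the spatially clustered
#' ranges of real occurrence data; at 0 centers are uniform.
#'
#' @param n_cells_x,n_cells_y grid dimensions in cells (>= 1)
#' @param range_radius_log_mean,range_radius_log_sd lognormal parameters of
#'   the range radius in cell units (defaults: meanlog log(2), sdlog 0.6,
#'   i.e. a median radius of two 25-km cells)
#' @param center_clustering non-negative clustering strength (default 1)
#' @param cell_size cell side in meters (default 25000)
#' @return object of class `range_model`
#' @export
range_model <- function(n_cells_x = 20, n_cells_y = 10,
                        range_radius_log_mean = log(2),
                        range_radius_log_sd = 0.6,
                        center_clustering = 1,
                        cell_size = 25000) {
  stopifnot(n_cells_x >= 1, n_cells_y >= 1, range_radius_log_sd >= 0,
            center_clustering >= 0, cell_size > 0)
  structure(list(n_cells_x = as.integer(n_cells_x),
                 n_cells_y = as.integer(n_cells_y),
                 range_radius_log_mean = range_radius_log_mean,
                 range_radius_log_sd = range_radius_log_sd,
                 center_clustering = center_clustering,
                 cell_size = cell_size), class = "range_model")
}

# full cell table for a range model (origin 0,0), centroids in meters
model_cells <- function(model) {
  ix <- rep(seq_len(model$n_cells_x) - 1L, times = model$n_cells_y)
  iy <- rep(seq_len(model$n_cells_y) - 1L, each = model$n_cells_x)
  tibble(cell_id = paste0(ix, "_", iy),
         cx = ix + 0.5, cy = iy + 0.5,
         x = (ix + 0.5) * model$cell_size,
         y = (iy + 0.5) * model$cell_size)
}

#' Simulate spatially clustered species ranges
#'
#' Draws one disc range per tree tip under a [range_model()] and returns
#' the resulting presence-absence matrix. Every tip occupies at least one
#' cell; matrix taxa equal tree tips exactly.
#'
#' @param tree a `phylo` tree
#' @param model a [range_model()]
#' @param seed integer seed
#' @return a [pa_matrix()]
#' @export
simulate_occurrences <- function(tree, model = range_model(), seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "range_model"))
  taxa <- tree$tip.label
  cells <- model_cells(model)
  withr::with_seed(seed, {
    if (model$center_clustering > 0) {
      k <- 3
      mx <- runif(k, 0, model$n_cells_x)
      my <- runif(k, 0, model$n_cells_y)
      sd_c <- max(model$n_cells_x, model$n_cells_y) /
        (2 * (1 + model$center_clustering))
      comp <- sample.int(k, length(taxa), replace = TRUE)
      cx <- rnorm(length(taxa), mx[comp], sd_c)
      cy <- rnorm(length(taxa), my[comp], sd_c)
      cx <- pmin(pmax(cx, 0), model$n_cells_x)
      cy <- pmin(pmax(cy, 0), model$n_cells_y)
    } else {
      cx <- runif(length(taxa), 0, model$n_cells_x)
      cy <- runif(length(taxa), 0, model$n_cells_y)
    }
    radius <- rlnorm(length(taxa), model$range_radius_log_mean,
                     model$range_radius_log_sd)
    m <- matrix(0L, nrow(cells), length(taxa),
                dimnames = list(cells$cell_id, taxa))
    for (i in seq_along(taxa)) {
      d2 <- (cells$cx - cx[i])^2 + (cells$cy - cy[i])^2
      inside <- d2 <= radius[i]^2
      if (!any(inside)) inside[which.min(d2)] <- TRUE
      m[inside, i] <- 1L
    }
  })
  pa_matrix(m, cells = cells[, c("cell_id", "x", "y")])
}

#' Endemism scenario description
#'
#' Describes an injected concentration of rare taxa: `"neo"` scenarios add
#' rare short-branch tips (subtending branch shrunk by `branch_scale` < 1),
#' `"paleo"` scenarios rare long-branch tips (`branch_scale` > 1), confined
#' to `range_cells` cells around the target cell(s).
#'
#' @param kind `"neo"` or `"paleo"`
#' @param target_cells character vector of cell ids to concentrate on
#' @param n_taxa number of tips to inject (default: 5 for neo, 1 for paleo)
#' @param branch_scale branch-length multiplier (default: 0.1 for neo, 10
#'   for paleo)
#' @param range_cells range size of each injected tip, in cells (default:
#'   2 for neo, 1 for paleo)
#' @return object of class `endemism_scenario`
#' @export
endemism_scenario <- function(kind = c("neo", "paleo"), target_cells,
                              n_taxa = NULL, branch_scale = NULL,
                              range_cells = NULL) {
  kind <- match.arg(kind)
  n_taxa <- n_taxa %||% if (kind == "neo") 5L else 1L
  branch_scale <- branch_scale %||% if (kind == "neo") 0.1 else 10
  range_cells <- range_cells %||% if (kind == "neo") 2L else 1L
  stopifnot(length(target_cells) >= 1, n_taxa >= 1, branch_scale > 0,
            range_cells >= 1)
  if (kind == "neo" && branch_scale >= 1)
    abort("neo scenarios need branch_scale < 1")
  if (kind == "paleo" && branch_scale <= 1)
    abort("paleo scenarios need branch_scale > 1")
  structure(list(kind = kind, target_cells = as.character(target_cells),
                 n_taxa = as.integer(n_taxa), branch_scale = branch_scale,
                 range_cells = as.integer(range_cells)),
            class = "endemism_scenario")
}

#' Inject an endemism scenario into a dataset
#'
#' Grafts `n_taxa` new tips onto the tree and gives each a range of exactly
#' `range_cells` cells containing its target cell, leaving all existing
#' taxa and cells untouched (the base dataset stays usable as a control).
#' Each injected tip's subtending branch is a draw (the mean tip branch
#' length of the base tree) multiplied by `branch_scale`. Neo tips are
#' grafted as a cluster of sisters on one random edge; paleo tips each on
#' their own random edge.
#'
#' @param tree a `phylo` tree
#' @param pa a [pa_matrix()] over the same taxa
#' @param scenario an [endemism_scenario()]
#' @param seed integer seed
#' @return list with elements `tree` and `matrix` (the augmented pair) and
#'   `injected` (the new tip labels)
#' @export
inject_endemism_scenario <- function(tree, pa, scenario, seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(pa, "pa_matrix"),
            inherits(scenario, "endemism_scenario"))
  missing_cells <- setdiff(scenario$target_cells, pa_cells(pa))
  if (length(missing_cells) > 0)
    abort(paste0("invalid scenario: target cell(s) absent from grid: ",
                 paste(missing_cells, collapse = ", ")))
  base_draw <- mean(tree$edge.length[tree$edge[, 2] <=
                                       length(tree$tip.label)])
  new_len <- base_draw * scenario$branch_scale
  labels <- paste0(scenario$kind, "_inj", seq_len(scenario$n_taxa))
  withr::with_seed(seed, {
    tr <- tree
    if (scenario$kind == "neo") {
      # a cladelet of sisters on one random edge
      if (scenario$n_taxa == 1) {
        sub <- ape::read.tree(text = sprintf("(%s:%.12g);", labels, new_len))
      } else {
        sub <- ape::stree(scenario$n_taxa, type = "star",
                          tip.label = labels)
        sub$edge.length <- rep(new_len, nrow(sub$edge))
        sub$root.edge <- base_draw
      }
      e <- sample.int(nrow(tr$edge), 1)
      pos <- runif(1, 0.25, 0.75) * tr$edge.length[e]
      tr <- ape::bind.tree(tr, sub, where = tr$edge[e, 2], position = pos)
    } else {
      for (i in seq_len(scenario$n_taxa)) {
        sub <- ape::read.tree(text = sprintf("(%s:%.12g);", labels[i],
                                             new_len))
        e <- sample.int(nrow(tr$edge), 1)
        pos <- runif(1, 0.25, 0.75) * tr$edge.length[e]
        tr <- ape::bind.tree(tr, sub, where = tr$edge[e, 2], position = pos)
      }
    }
    # ranges: target cell plus nearest cells by centroid distance
    cells <- pa$cells
    inc <- pa$incidence
    for (i in seq_len(scenario$n_taxa)) {
      target <- scenario$target_cells[
        ((i - 1) %% length(scenario$target_cells)) + 1]
      ti <- match(target, cells$cell_id)
      if (all(is.finite(cells$x))) {
        d2 <- (cells$x - cells$x[ti])^2 + (cells$y - cells$y[ti])^2
        ord <- order(d2, cells$cell_id)
      } else {
        ord <- c(ti, setdiff(seq_len(nrow(cells)), ti))
      }
      occ_cells <- ord[seq_len(min(scenario$range_cells, nrow(cells)))]
      col <- integer(nrow(inc))
      col[occ_cells] <- 1L
      inc <- cbind(inc, col)
      colnames(inc)[ncol(inc)] <- labels[i]
    }
  })
  list(tree = tr, matrix = pa_matrix(inc, cells = pa$cells),
       injected = labels)
}

# Gale-Ryser feasibility for binary matrices with given margins
margins_feasible <- function(row_sums, col_sums) {
  if (sum(row_sums) != sum(col_sums)) return(FALSE)
  if (any(row_sums < 0) || any(col_sums < 0)) return(FALSE)
  if (any(row_sums > length(col_sums)) || any(col_sums > length(row_sums)))
    return(FALSE)
  r <- sort(as.integer(row_sums), decreasing = TRUE)
  cs <- as.integer(col_sums)
  for (k in seq_along(r)) {
    if (sum(r[seq_len(k)]) > sum(pmin(cs, k))) return(FALSE)
  }
  TRUE
}

#' Draw a presence-absence matrix with fixed margins
#'
#' Samples a binary matrix whose row sums equal the given per-cell richness
#' and whose column sums equal the given per-taxon ranges, using the same
#' curveball sampler as [randomize_matrix()]: a feasible matrix is first
#' constructed greedily (largest ranges into the richest remaining cells)
#' and then randomized. Errors if the margins are infeasible
#' (Gale-Ryser condition).
#'
#' @param richness named integer vector: target richness per cell
#' @param ranges named integer vector: target range per taxon
#' @param seed integer seed
#' @param burn_in_swaps_factor curveball burn-in, as a multiple of the
#'   number of presences (default 5)
#' @return a [pa_matrix()] with the requested margins
#' @export
simulate_null_dataset <- function(richness, ranges, seed = 1,
                                  burn_in_swaps_factor = 5) {
  if (is.null(names(richness))) names(richness) <- paste0("c", seq_along(richness))
  if (is.null(names(ranges))) names(ranges) <- paste0("t", seq_along(ranges))
  if (!margins_feasible(richness, ranges))
    abort("infeasible margins: no binary matrix has these row/column sums")
  m <- matrix(0L, length(richness), length(ranges),
              dimnames = list(names(richness), names(ranges)))
  cap <- as.integer(richness)
  for (j in order(ranges, decreasing = TRUE)) {
    pick <- order(cap, decreasing = TRUE)[seq_len(ranges[j])]
    m[pick, j] <- 1L
    cap[pick] <- cap[pick] - 1L
  }
  stopifnot(all(rowSums(m) == richness), all(colSums(m) == ranges))
  pa <- pa_matrix(m, drop_empty = FALSE)
  randomize_matrix(pa, seed = seed,
                   burn_in_swaps_factor = burn_in_swaps_factor)
}
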