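# internal: tidy surface constructor
new_surface <- function(cells, value, metric, group = NA_character_) {
  out <- tibble(cell_id = cells$cell_id, x = cells$x, y = cells$y,
                metric = metric, group = group, value = unname(value))
  class(out) <- c("div_surface", class(out))
  out
}

# internal: per-cell branch sums with the chosen path convention.
# weights: per-branch weight (L_b for PD, L_b / R_b for PE).
# root: sum over every branch whose cell set contains the cell
# (tip-to-root paths); crown: additionally exclude branches ancestral to
# *all* of the cell's taxa (the root-to-MRCA path), so a single-taxon cell
# scores 0.
branch_cell_sums <- function(bi, weights, convention = c("root", "crown")) {
  convention <- match.arg(convention)
  v <- as.numeric(bi$presence %*% weights)
  if (convention == "crown") {
    anc <- (bi$counts == bi$richness) & (bi$presence > 0)
    v <- v - as.numeric(anc %*% weights)
  }
  setNames(v, rownames(bi$presence))
}

#' Taxon richness surface (TR)
#'
#' Number of taxa present per grid cell.
#' @param pa a [pa_matrix()]
#' @param group optional group label carried into the surface
#' @return tibble (`div_surface`) with columns cell_id, x, y, metric,
#'   group, value
#' @export
taxon_richness <- function(pa, group = NA_character_) {
  stopifnot(inherits(pa, "pa_matrix"), nrow(pa$incidence) > 0)
  new_surface(pa$cells, rowSums(pa$incidence), "TR", group)
}

#' Weighted endemism surface (WE)
#'
#' Per cell, the sum over taxa present of the inverse of each taxon's range
#' size in cells: range-restricted taxa weigh more. Summed over all cells,
#' WE equals the number of taxa.
#' @inheritParams taxon_richness
#' @export
weighted_endemism <- function(pa, group = NA_character_) {
  stopifnot(inherits(pa, "pa_matrix"), nrow(pa$incidence) > 0)
  w <- 1 / colSums(pa$incidence)
  new_surface(pa$cells, as.numeric(pa$incidence %*% w), "WE", group)
}

#' Phylogenetic diversity surface (PD)
#'
#' Faith's PD per cell: the total branch length of the tree subgraph
#' spanned by the cell's taxa. Under the default `"root"` convention the
#' subgraph is the union of tip-to-root paths; under `"crown"` the
#' root-to-MRCA path is excluded.
#' @param bi a [branch_incidence()]
#' @param convention `"root"` (default) or `"crown"`
#' @param group optional group label
#' @export
phylogenetic_diversity <- function(bi, convention = c("root", "crown"),
                                   group = NA_character_) {
  stopifnot(inherits(bi, "branch_incidence"))
  new_surface(bi$cells, branch_cell_sums(bi, bi$lengths, convention),
              "PD", group)
}

#' Phylogenetic endemism surface (PE)
#'
#' PD with every branch length L_b down-weighted by its range R_b (the
#' number of cells holding any of its descendant tips): PE(c) = sum over
#' branches on c's paths of L_b / R_b. Spatially concentrated branches
#' weigh more; summed over all cells PE equals the total counted tree
#' length.
#' @inheritParams phylogenetic_diversity
#' @export
phylogenetic_endemism <- function(bi, convention = c("root", "crown"),
                                  group = NA_character_) {
  stopifnot(inherits(bi, "branch_incidence"))
  rb <- colSums(bi$presence)
  w <- ifelse(rb > 0, bi$lengths / rb, 0)
  new_surface(bi$cells, branch_cell_sums(bi, w, convention), "PE", group)
}

#' Relative metric surface (RPD / RPE)
#'
#' Ratio of an observed surface to the same metric on the
#' equal-branch-length comparison tree, cell by cell. Values above 1 flag
#' concentrations of unusually long branches, below 1 of unusually short
#' branches.
#' @param observed,comparison `div_surface` tibbles over identical cell sets
#' @param metric label for the output (default prefixes "R" to the
#'   observed metric)
#' @export
relative_metric <- function(observed, comparison, metric = NULL) {
  stopifnot(is.data.frame(observed), is.data.frame(comparison))
  if (!setequal(observed$cell_id, comparison$cell_id))
    abort("observed and comparison surfaces cover different cells")
  comparison <- comparison[match(observed$cell_id, comparison$cell_id), ]
  zero <- comparison$value == 0
  if (any(zero))
    abort(paste0("comparison value 0 in cell(s): ",
                 paste(observed$cell_id[zero], collapse = ", ")))
  metric <- metric %||% paste0("R", observed$metric[1])
  out <- observed
  out$value <- observed$value / comparison$value
  out$metric <- metric
  out
}

#' All six diversity and endemism surfaces for one group
#'
#' Convenience wrapper computing TR, WE, PD, PE, RPD and RPE on an aligned
#' matrix/tree pair, returned as one long tibble. RPD and RPE divide by PD
#' and PE on the equal-branch-length comparison tree ([equalize_branch_lengths()]);
#' the comparison tree shares the topology, so branch cell sets and ranges
#' are identical and only the lengths differ.
#'
#' @param pa a [pa_matrix()] aligned to `tree`
#' @param tree a rooted `phylo` tree
#' @param convention path convention for PD/PE, `"root"` (default) or
#'   `"crown"`
#' @param group optional group label
#' @return long `div_surface` tibble over all cells and the six metrics
#' @export
diversity_metrics <- function(pa, tree, convention = c("root", "crown"),
                              group = NA_character_) {
  convention <- match.arg(convention)
  bi <- branch_incidence(tree, pa)
  bi_eq <- branch_incidence(equalize_branch_lengths(tree), pa)
  pd <- phylogenetic_diversity(bi, convention, group)
  pe <- phylogenetic_endemism(bi, convention, group)
  pd_eq <- phylogenetic_diversity(bi_eq, convention, group)
  pe_eq <- phylogenetic_endemism(bi_eq, convention, group)
  bind_rows(
    taxon_richness(pa, group),
    weighted_endemism(pa, group),
    pd, pe,
    relative_metric(pd, pd_eq, "RPD"),
    relative_metric(pe, pe_eq, "RPE")
  )
}

#' Write a surface tibble to CSV
#' @param surface a `div_surface` tibble
#' @param path file path
#' @export
write_surface <- function(surface, path) {
  readr::write_csv(surface, path)
  invisible(path)
}

#' Read a surface tibble from CSV
#' @param path file path
#' @export
read_surface <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           cell_id = readr::col_character(),
                           metric = readr::col_character(),
                           group = readr::col_character()))
  class(out) <- c("div_surface", class(out))
  out
}
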