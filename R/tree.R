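#' Read and validate a rooted newick tree
#'
#' Thin wrapper over ape's newick parser adding the validation the metrics
#' require: unique tip labels, finite non-negative branch lengths. Branches
#' without lengths default to 0 with a warning. A root stem (`root.edge`),
#' if present, is retained on the object but never counted by any metric,
#' by equalization, or in total tree length.
#'
#' @param newick a newick string, or the path of a file containing one
#' @return a rooted `phylo` object
#' @export
read_tree <- function(newick) {
  stopifnot(is.character(newick), length(newick) == 1)
  tree <- if (grepl("\\(", newick) || grepl(";", newick)) {
    tr <- try(ape::read.tree(text = newick), silent = TRUE)
    if (inherits(tr, "try-error") || is.null(tr))
      abort("newick parse failure")
    tr
  } else {
    if (!file.exists(newick)) abort(paste0("no such file: ", newick))
    ape::read.tree(newick)
  }
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylo tree")
  if (anyDuplicated(tree$tip.label))
    abort(paste0("duplicate tip label(s): ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(is.na(tree$edge.length)) || any(!is.finite(tree$edge.length)))
    abort("non-finite branch length")
  if (any(tree$edge.length < 0)) abort("negative branch length")
  tree
}

#' Total counted branch length of a tree
#'
#' Sum of all branch lengths excluding the root stem.
#' @param tree a `phylo` tree
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sum(tree$edge.length)
}

#' Build the equal-branch-length comparison tree
#'
#' Returns a tree with identical topology in which every counted branch is
#' set to (total original length) / (number of counted branches), so the
#' total length is preserved. This is the denominator tree for the relative
#' metrics RPD and RPE: dividing by diversity on this tree isolates the
#' contribution of branch-length heterogeneity from that of topology and
#' occupancy.
#'
#' @param tree a `phylo` tree with positive total length
#' @return a `phylo` tree
#' @export
equalize_branch_lengths <- function(tree) {
  tree <- validate_tree(tree)
  total <- sum(tree$edge.length)
  if (total <= 0) abort("degenerate tree: total branch length is 0")
  tree$edge.length <- rep(total / nrow(tree$edge), nrow(tree$edge))
  tree
}

#' Branch-by-cell incidence structure
#'
#' The workhorse structure shared by PD, PE, phylo-jaccard and the
#' randomization null: for every counted branch `b`, its length `L_b` and
#' the set of grid cells in which at least one descendant tip is present.
#' `R_b`, the branch range, is the size of that set; for a tip branch it
#' equals the taxon's range, and every internal branch's cell set is the
#' union of its children's. Computed in one post-order pass.
#'
#' @param tree a rooted `phylo` tree
#' @param pa a [pa_matrix()] whose taxa are all tips of `tree` (tips absent
#'   from the matrix get empty cell sets)
#' @return object of class `branch_incidence` with fields `lengths`
#'   (per-branch), `presence` (cells x branches 0/1), `counts` (cells x
#'   branches number of present descendant tips), `branch_id`, `is_tip`,
#'   `cells`, `richness`, `tree`
#' @export
branch_incidence <- function(tree, pa) {
  tree <- validate_tree(tree)
  stopifnot(inherits(pa, "pa_matrix"))
  missing_taxa <- setdiff(pa_taxa(pa), tree$tip.label)
  if (length(missing_taxa) > 0)
    abort(paste0("matrix taxa missing from tree: ",
                 paste(missing_taxa, collapse = ", ")))
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  # descendant-tip indicator per edge, built tip-upward in postorder
  desc <- matrix(FALSE, nedge, ntip, dimnames = list(NULL, tree$tip.label))
  po <- ape::postorder(tree)
  child_edges <- split(seq_len(nedge), tree$edge[, 1])  # edges below each node
  for (e in po) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) {
      desc[e, ch] <- TRUE
    } else {
      below <- child_edges[[as.character(ch)]]
      desc[e, ] <- colSums(desc[below, , drop = FALSE]) > 0
    }
  }
  # cells x branches counts of present descendant tips
  inc <- pa$incidence
  dmat <- matrix(0L, ntip, nedge, dimnames = list(tree$tip.label, NULL))
  dmat[t(desc)] <- 1L
  counts <- inc %*% dmat[pa_taxa(pa), , drop = FALSE]
  presence <- (counts > 0) * 1L
  structure(list(
    lengths = tree$edge.length,
    presence = presence,
    counts = counts,
    branch_id = branch_ids(tree),
    is_tip = tree$edge[, 2] <= ntip,
    cells = pa$cells,
    richness = rowSums(inc),
    tree = tree
  ), class = "branch_incidence")
}

# stable branch labels: tip label for tip branches, sorted descendant-tip
# signature for internal branches
branch_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) tree$tip.label[ch]
    else paste(sort(ape::extract.clade(tree, ch)$tip.label), collapse = "|")
  }, character(1))
}

#' Branch ranges R_b
#' @param bi a [branch_incidence()]
#' @return named integer vector: number of cells per counted branch
#' @export
branch_ranges <- function(bi) {
  stopifnot(inherits(bi, "branch_incidence"))
  setNames(colSums(bi$presence), bi$branch_id)
}

#' @export
print.branch_incidence <- function(x, ...) {
  cat(sprintf("<branch_incidence> %d branches x %d cells, total length %g\n",
              length(x$lengths), nrow(x$presence), sum(x$lengths)))
  invisible(x)
}

#' @export
as_tibble.branch_incidence <- function(x, ...) {
  tibble(
    branch_id = x$branch_id,
    length = x$lengths,
    is_tip = x$is_tip,
    range = unname(colSums(x$presence)),
    cells = purrr::map(seq_along(x$lengths), function(e)
      rownames(x$presence)[x$presence[, e] > 0])
  )
}
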