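#' Phylo-jaccard dissimilarity between two cells
#'
#' One minus the fraction of shared phylogenetic branch length: with A the
#' total length of branches present in both cells, and B and C the lengths
#' unique to each, returns (B + C) / (A + B + C). Branch presence in a cell
#' uses the same path convention as PD (default: tips-to-root).
#'
#' @param bi a [branch_incidence()]
#' @param cell_a,cell_b cell ids
#' @param convention `"root"` (default) or `"crown"`
#' @return a dissimilarity in \[0, 1\]
#' @export
phylo_jaccard <- function(bi, cell_a, cell_b,
                          convention = c("root", "crown")) {
  convention <- match.arg(convention)
  pres <- cell_branch_sets(bi, convention)
  for (cc in c(cell_a, cell_b)) {
    if (!cc %in% rownames(pres)) abort(paste0("unknown cell: ", cc))
  }
  a <- pres[cell_a, ] > 0
  b <- pres[cell_b, ] > 0
  union_len <- sum(bi$lengths[a | b])
  if (union_len == 0) return(0)
  1 - sum(bi$lengths[a & b]) / union_len
}

# per-cell branch sets under the chosen convention, as 0/1 matrix
cell_branch_sets <- function(bi, convention = c("root", "crown")) {
  convention <- match.arg(convention)
  pres <- bi$presence
  if (convention == "crown")
    pres <- pres * !((bi$counts == bi$richness) & (bi$presence > 0))
  pres
}

#' Pairwise phylo-jaccard dissimilarity matrix
#'
#' Full symmetric matrix of [phylo_jaccard()] over all cell pairs, computed
#' by shared-branch-length matrix algebra.
#'
#' @inheritParams phylo_jaccard
#' @return symmetric numeric matrix (class `dissim_matrix`) with zero
#'   diagonal and values in \[0, 1\], cell ids as dimnames
#' @export
pairwise_phylo_jaccard <- function(bi, convention = c("root", "crown")) {
  stopifnot(inherits(bi, "branch_incidence"))
  convention <- match.arg(convention)
  pres <- cell_branch_sets(bi, convention)
  if (nrow(pres) < 2) abort("need at least 2 cells")
  w <- pres * rep(bi$lengths, each = nrow(pres))
  shared <- w %*% t(pres)               # A_ij = sum of lengths in both
  tot <- rowSums(w)                     # per-cell branch length
  union <- outer(tot, tot, "+") - shared
  d <- ifelse(union > 0, 1 - shared / union, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(pres), rownames(pres))
  class(d) <- c("dissim_matrix", class(d))
  d
}

#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' Unweighted average-linkage agglomeration via [stats::hclust()]. Items
#' are sorted lexicographically first so tied merges resolve
#' deterministically by item id.
#'
#' @param dissim symmetric dissimilarity matrix with dimnames (e.g. from
#'   [pairwise_phylo_jaccard()])
#' @return an `hclust` dendrogram
#' @export
average_linkage_cluster <- function(dissim) {
  d <- unclass(dissim)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  if (any(is.na(d)) || any(!is.finite(d))) abort("NaN/NA in dissimilarity matrix")
  if (max(abs(d - t(d))) > 1e-12) abort("dissimilarity matrix is not symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hclust(as.dist(d), method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges; labels are stable across runs (numbered
#' in order of first appearance over the leaf ordering).
#'
#' @param dendrogram an `hclust` object
#' @param k number of clusters, between 1 and the number of leaves
#' @return tibble with columns `item`, `cluster`
#' @export
cut_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != round(k))
    abort(sprintf("`k` must be an integer in [1, %d]", n))
  cl <- cutree(dendrogram, k = k)
  tibble(item = names(cl), cluster = unname(cl))
}

#' Write a dendrogram as newick
#'
#' Branch lengths in the newick encode an ultrametric tree whose
#' tip-to-node depths are half the merge heights (cophenetic distances are
#' preserved).
#' @param dendrogram an `hclust` object
#' @param path file path
#' @export
write_dendrogram <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram)
  # round-off in hclust heights can leave infinitesimal negative edges
  phy$edge.length[phy$edge.length < 0 & phy$edge.length > -1e-8] <- 0
  ape::write.tree(phy, path)
  invisible(path)
}

#' Write a dissimilarity matrix as CSV (long format)
#' @param dissim a dissimilarity matrix with dimnames
#' @param path file path
#' @export
write_dissim <- function(dissim, path) {
  d <- unclass(dissim)
  long <- tibble(
    item_a = rep(rownames(d), times = ncol(d)),
    item_b = rep(colnames(d), each = nrow(d)),
    dissimilarity = as.numeric(d)
  )
  readr::write_csv(long, path)
  invisible(path)
}
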