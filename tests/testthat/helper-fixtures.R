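# Shared fixtures: the 4-tip balanced tree and 3-cell assemblage used
# throughout, plus independent brute-force oracles that enumerate
# tip-to-root paths explicitly (ape::nodepath), never touching the
# package's postorder incidence code.

fixture_tree <- function() read_tree("((A:1,B:1):1,(C:1,D:1):1);")

fixture_cells <- function() {
  list(c1 = c("A", "B"), c2 = c("C"), c3 = c("A", "C", "D"))
}

fixture_pa <- function(cells = fixture_cells()) {
  pa_from_long(tibble::tibble(
    cell_id = rep(names(cells), lengths(cells)),
    taxon = unlist(cells, use.names = FALSE)
  ))
}

# grid-shaped pa with centroids, from a list cell -> taxa; cells on a line
fixture_pa_xy <- function(cells = fixture_cells(), cell_size = 25000) {
  n <- length(cells)
  tibble::tibble(
    cell_id = rep(names(cells), lengths(cells)),
    x = rep((seq_len(n) - 0.5) * cell_size, lengths(cells)),
    y = rep(0.5 * cell_size, lengths(cells)),
    taxon = unlist(cells, use.names = FALSE)
  ) |> pa_from_long()
}

# ---- independent oracles -------------------------------------------------

# edge indices on the union of tip-to-root paths of `taxa`
oracle_cell_edges <- function(tree, taxa) {
  root <- length(tree$tip.label) + 1L
  edges <- integer(0)
  for (tx in taxa) {
    tip <- match(tx, tree$tip.label)
    np <- ape::nodepath(tree, from = root, to = tip)
    for (i in seq_len(length(np) - 1)) {
      e <- which(tree$edge[, 1] == np[i] & tree$edge[, 2] == np[i + 1])
      edges <- union(edges, e)
    }
  }
  sort(edges)
}

oracle_pd <- function(tree, taxa) {
  sum(tree$edge.length[oracle_cell_edges(tree, taxa)])
}

# cells: named list cell -> character vector of taxa
oracle_metrics <- function(tree, cells) {
  edge_sets <- lapply(cells, oracle_cell_edges, tree = tree)
  ranges <- table(unlist(lapply(cells, unique)))
  branch_range <- function(e) sum(vapply(edge_sets, function(s) e %in% s,
                                         logical(1)))
  pe <- vapply(edge_sets, function(es)
    sum(tree$edge.length[es] / vapply(es, branch_range, numeric(1))),
    numeric(1))
  eq_len <- sum(tree$edge.length) / nrow(tree$edge)
  pd_eq <- vapply(edge_sets, function(es) length(es) * eq_len, numeric(1))
  pe_eq <- vapply(edge_sets, function(es)
    sum(eq_len / vapply(es, branch_range, numeric(1))), numeric(1))
  list(
    tr = lengths(cells),
    we = vapply(cells, function(tx) sum(1 / ranges[tx]), numeric(1)),
    pd = vapply(edge_sets, function(es) sum(tree$edge.length[es]),
                numeric(1)),
    pe = pe,
    rpd = vapply(edge_sets, function(es) sum(tree$edge.length[es]),
                 numeric(1)) / pd_eq,
    rpe = pe / pe_eq
  )
}

oracle_phylo_jaccard <- function(tree, taxa_a, taxa_b) {
  ea <- oracle_cell_edges(tree, taxa_a)
  eb <- oracle_cell_edges(tree, taxa_b)
  u <- sum(tree$edge.length[union(ea, eb)])
  if (u == 0) return(0)
  1 - sum(tree$edge.length[intersect(ea, eb)]) / u
}

# random cell -> taxa assignment over a tree's tips (every cell nonempty)
random_cells <- function(tree, n_cells, seed) {
  withr::with_seed(seed, {
    tips <- tree$tip.label
    repeat {
      cells <- lapply(seq_len(n_cells), function(i)
        sort(sample(tips, sample(seq_along(tips), 1))))
      names(cells) <- paste0("c", seq_len(n_cells))
      if (all(lengths(cells) > 0)) break
    }
    cells
  })
}
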