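#' Read point occurrence records
#'
#' Reads a delimited table of occurrence records (one row per record) and
#' returns a tidy occurrence table with columns `taxon`, `x`, `y`.
#' Coordinates are planar meters in an equal-area projection; no
#' reprojection is performed. Rows with missing/unparseable coordinates or
#' empty taxon names are dropped and their count reported via a message.
#'
#' @param path file path to a CSV/TSV table
#' @param columns named character vector mapping `taxon`, `x`, `y` to the
#'   file's column names, e.g. `c(taxon = "species", x = "x", y = "y")`.
#' @param delim field delimiter (default `","`)
#' @return tibble with columns `taxon`, `x`, `y`
#' @export
read_occurrences <- function(path,
                             columns = c(taxon = "taxon", x = "x", y = "y"),
                             delim = ",") {
  stopifnot(file.exists(path))
  if (!all(c("taxon", "x", "y") %in% names(columns)))
    abort("`columns` must map taxon, x and y")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(unname(columns[c("taxon", "x", "y")]), names(raw))
  if (length(missing_cols) > 0)
    abort(paste0("mapped column(s) not in file: ",
                 paste(missing_cols, collapse = ", ")))
  occ <- tibble(
    taxon = as.character(raw[[columns[["taxon"]]]]),
    x = suppressWarnings(as.numeric(raw[[columns[["x"]]]])),
    y = suppressWarnings(as.numeric(raw[[columns[["y"]]]]))
  )
  ok <- !is.na(occ$taxon) & nzchar(occ$taxon) &
    is.finite(occ$x) & is.finite(occ$y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    inform(sprintf("read_occurrences: dropped %d invalid record(s)", n_dropped))
  out <- occ[ok, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Grid specification
#'
#' Defines the equal-area analysis grid: square cells of side `cell_size`
#' meters (default 25 km), anchored at `(origin_x, origin_y)`. Cells are
#' half-open intervals `[low, high)` in both axes, and a point maps to cell
#' index `floor((coord - origin) / cell_size)`. If origins are `NULL` they
#' default, at aggregation time, to the data's min x/y floored to the
#' nearest `cell_size` multiple. An optional polygon `mask` (data frame with
#' columns `x`, `y`) restricts records to its interior, boundary-inclusive.
#'
#' @param cell_size cell side in meters (> 0); default 25000
#' @param origin_x,origin_y grid origin in meters, or `NULL`
#' @param mask optional polygon (data frame with `x`, `y` vertex columns)
#' @return object of class `grid_spec`
#' @export
grid_spec <- function(cell_size = 25000, origin_x = NULL, origin_y = NULL,
                      mask = NULL) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    abort("`cell_size` must be a single positive number")
  if (!is.null(mask)) {
    mask <- as.data.frame(mask)
    stopifnot(all(c("x", "y") %in% names(mask)), nrow(mask) >= 3)
  }
  structure(list(cell_size = cell_size, origin_x = origin_x,
                 origin_y = origin_y, mask = mask), class = "grid_spec")
}

# even-odd point-in-polygon, boundary-inclusive
point_in_polygon <- function(px, py, poly) {
  vx <- poly$x; vy <- poly$y
  nv <- length(vx)
  j <- c(nv, seq_len(nv - 1))
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    for (i in seq_len(nv)) {
      x1 <- vx[j[i]]; y1 <- vy[j[i]]; x2 <- vx[i]; y2 <- vy[i]
      # on-edge test (boundary-inclusive)
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-12 * max(1, abs(x2 - x1), abs(y2 - y1)) &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) return(TRUE)
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Aggregate occurrence records to a grid
#'
#' Bins records into half-open square cells and collapses duplicates to a
#' single presence, producing the cell-by-taxon presence-absence matrix all
#' downstream metrics consume. Cells with no records are not materialized.
#'
#' @param occ occurrence tibble with columns `taxon`, `x`, `y` (as returned
#'   by [read_occurrences()])
#' @param grid a [grid_spec()]
#' @return a [pa_matrix()] whose cell ids are `"ix_iy"` integer cell indices
#'   and whose `cells` tibble carries cell centroid coordinates
#' @export
aggregate_to_grid <- function(occ, grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"))
  occ <- as_tibble(occ)
  stopifnot(all(c("taxon", "x", "y") %in% names(occ)))
  if (nrow(occ) == 0) {
    return(pa_matrix(matrix(integer(), 0, 0,
                            dimnames = list(character(), character()))))
  }
  if (!is.null(grid$mask)) {
    keep <- point_in_polygon(occ$x, occ$y, grid$mask)
    occ <- occ[keep, , drop = FALSE]
    if (nrow(occ) == 0) {
      return(pa_matrix(matrix(integer(), 0, 0,
                              dimnames = list(character(), character()))))
    }
  }
  cs <- grid$cell_size
  ox <- grid$origin_x %||% (floor(min(occ$x) / cs) * cs)
  oy <- grid$origin_y %||% (floor(min(occ$y) / cs) * cs)
  ix <- floor((occ$x - ox) / cs)
  iy <- floor((occ$y - oy) / cs)
  long <- tibble(
    cell_id = paste0(ix, "_", iy),
    x = ox + (ix + 0.5) * cs,
    y = oy + (iy + 0.5) * cs,
    taxon = occ$taxon,
    presence = 1L
  )
  pa_from_long(distinct(long))
}

#' Align a presence-absence matrix with a phylogenetic tree
#'
#' Reconciles the matrix's taxa with the tree's tip labels. Under
#' `"strict"`, any mismatch is an error listing the offending names; under
#' `"prune-both"` the name sets are intersected, the tree is pruned to the
#' shared tips and cells left empty are dropped.
#'
#' @param pa a [pa_matrix()]
#' @param tree a rooted `phylo` tree
#' @param policy `"prune-both"` (default) or `"strict"`
#' @return list with elements `matrix` (pa_matrix) and `tree` (phylo)
#' @export
align_matrix_to_tree <- function(pa, tree, policy = c("prune-both", "strict")) {
  policy <- match.arg(policy)
  stopifnot(inherits(pa, "pa_matrix"), inherits(tree, "phylo"))
  mt <- pa_taxa(pa)
  tt <- tree$tip.label
  if (policy == "strict") {
    extra_m <- setdiff(mt, tt)
    extra_t <- setdiff(tt, mt)
    if (length(extra_m) || length(extra_t))
      abort(paste0(
        "matrix/tree name mismatch; matrix-only: {",
        paste(extra_m, collapse = ", "), "}, tree-only: {",
        paste(extra_t, collapse = ", "), "}"))
    return(list(matrix = pa, tree = tree))
  }
  shared <- intersect(mt, tt)
  if (length(shared) == 0) abort("empty intersection of matrix taxa and tree tips")
  inc <- pa$incidence[, shared, drop = FALSE]
  pa2 <- pa_matrix(inc, cells = pa$cells)
  tree2 <- if (length(shared) < length(tt)) {
    ape::keep.tip(tree, shared)
  } else tree
  list(matrix = pa2, tree = tree2)
}
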