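#' Cell-by-taxon presence-absence matrix
#'
#' The central container of the package: a binary incidence matrix with grid
#' cells as rows and taxa as columns, plus a tibble of cell centroids. Row
#' sums are per-cell taxon richness; column sums are per-taxon range sizes
#' (in cells), the quantity held fixed by the randomization null model and
#' used as the inverse weight in weighted endemism.
#'
#' Only materialized cells (richness >= 1) and taxa with range >= 1 are
#' retained; absence of a cell from the matrix means "no record there", not
#' "richness zero".
#'
#' @param incidence integer or logical matrix (cells x taxa) with rownames
#'   (cell ids) and colnames (taxon names); entries coerced to 0/1.
#' @param cells optional tibble with columns `cell_id`, `x`, `y` (centroid
#'   coordinates in meters). Defaults to `NA` coordinates.
#' @param drop_empty drop all-zero rows/columns (default `TRUE`).
#' @return An object of class `pa_matrix`.
#' @export
pa_matrix <- function(incidence, cells = NULL, drop_empty = TRUE) {
  if (!is.matrix(incidence)) abort("`incidence` must be a matrix")
  if (nrow(incidence) == 0 || ncol(incidence) == 0) {
    incidence <- matrix(integer(), nrow(incidence), ncol(incidence),
                        dimnames = list(rownames(incidence) %||% character(),
                                        colnames(incidence) %||% character()))
  } else if (is.null(rownames(incidence)) || is.null(colnames(incidence))) {
    abort("`incidence` must have cell rownames and taxon colnames")
  }
  mode(incidence) <- "integer"
  if (any(is.na(incidence)) || any(incidence < 0L | incidence > 1L))
    abort("`incidence` entries must be 0 or 1")
  if (anyDuplicated(rownames(incidence))) abort("duplicate cell ids")
  if (anyDuplicated(colnames(incidence))) abort("duplicate taxon names")
  if (drop_empty) {
    incidence <- incidence[rowSums(incidence) > 0L, colSums(incidence) > 0L,
                           drop = FALSE]
  }
  if (is.null(cells)) {
    cells <- tibble(cell_id = rownames(incidence), x = NA_real_, y = NA_real_)
  } else {
    cells <- as_tibble(cells)
    stopifnot(all(c("cell_id", "x", "y") %in% names(cells)))
    cells <- cells[match(rownames(incidence), cells$cell_id), , drop = FALSE]
    if (any(is.na(cells$cell_id))) abort("`cells` is missing some cell ids")
  }
  structure(list(incidence = incidence, cells = cells), class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("<pa_matrix> %d cells x %d taxa, %d presences\n",
              nrow(x$incidence), ncol(x$incidence), sum(x$incidence)))
  invisible(x)
}

#' @export
dim.pa_matrix <- function(x) dim(x$incidence)

#' Per-cell taxon richness (row sums)
#' @param pa a [pa_matrix()]
#' @return named integer vector over cells
#' @export
pa_richness <- function(pa) {
  stopifnot(inherits(pa, "pa_matrix"))
  rowSums(pa$incidence)
}

#' Per-taxon range size in cells (column sums)
#' @param pa a [pa_matrix()]
#' @return named integer vector over taxa
#' @export
pa_ranges <- function(pa) {
  stopifnot(inherits(pa, "pa_matrix"))
  colSums(pa$incidence)
}

#' Taxon names of a presence-absence matrix
#' @param pa a [pa_matrix()]
#' @export
pa_taxa <- function(pa) colnames(pa$incidence)

#' Cell ids of a presence-absence matrix
#' @param pa a [pa_matrix()]
#' @export
pa_cells <- function(pa) rownames(pa$incidence)

#' @export
as_tibble.pa_matrix <- function(x, ...) {
  long <- tibble(
    cell_id = rep(rownames(x$incidence), times = ncol(x$incidence)),
    taxon = rep(colnames(x$incidence), each = nrow(x$incidence)),
    presence = as.integer(x$incidence)
  )
  long <- long[long$presence == 1L, , drop = FALSE]
  left_join(long, x$cells, by = "cell_id")[, c("cell_id", "x", "y",
                                               "taxon", "presence")]
}

#' Build a presence-absence matrix from a long table
#'
#' @param df data frame with columns `cell_id`, `taxon` and optionally
#'   `presence` (rows with presence 0 are ignored) and `x`, `y` centroids.
#' @return a [pa_matrix()]
#' @export
pa_from_long <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("cell_id", "taxon") %in% names(df)))
  if ("presence" %in% names(df)) df <- df[df$presence > 0, , drop = FALSE]
  if (nrow(df) == 0) {
    return(pa_matrix(matrix(integer(), 0, 0,
                            dimnames = list(character(), character()))))
  }
  cells <- sort(unique(df$cell_id))
  taxa <- sort(unique(df$taxon))
  m <- matrix(0L, length(cells), length(taxa), dimnames = list(cells, taxa))
  m[cbind(match(df$cell_id, cells), match(df$taxon, taxa))] <- 1L
  cell_tb <- NULL
  if (all(c("x", "y") %in% names(df))) {
    cell_tb <- distinct(df[, c("cell_id", "x", "y")])
    if (anyDuplicated(cell_tb$cell_id))
      abort("inconsistent centroid coordinates for a cell_id")
  }
  pa_matrix(m, cells = cell_tb)
}

#' Write / read a presence-absence matrix as long-format CSV
#'
#' Long format has columns cell_id, x, y, taxon, presence (one row per
#' presence); `write_pa_wide()` writes the full 0/1 matrix with a leading
#' cell_id column.
#'
#' @param pa a [pa_matrix()]
#' @param path file path
#' @export
write_pa_long <- function(pa, path) {
  readr::write_csv(as_tibble(pa), path)
  invisible(path)
}

#' @rdname write_pa_long
#' @export
read_pa_long <- function(path) {
  pa_from_long(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname write_pa_long
#' @export
write_pa_wide <- function(pa, path) {
  wide <- as_tibble(cbind(tibble(cell_id = rownames(pa$incidence)),
                          as.data.frame(pa$incidence)))
  readr::write_csv(wide, path)
  invisible(path)
}
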