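#' 0-1 standardization of a diversity surface
#'
#' Rescales a surface to \[0, 1\] by subtracting its minimum and dividing
#' by its range, over its own materialized cells. A constant surface maps
#' to all zeros with a warning.
#'
#' @param surface a `div_surface` tibble (columns cell_id, value, ...)
#' @return the surface with `value` rescaled
#' @export
minmax_standardize <- function(surface) {
  stopifnot(is.data.frame(surface), nrow(surface) > 0)
  rng <- range(surface$value)
  out <- surface
  if (diff(rng) == 0) {
    warn("constant surface: standardized to all 0")
    out$value <- rep(0, nrow(surface))
  } else {
    out$value <- (surface$value - rng[1]) / diff(rng)
  }
  out
}

#' Standardize a multi-group surface table
#'
#' Applies [minmax_standardize()] to each group of a long surface table.
#' With `mode = "per-group"` (default) each group uses its own min/max;
#' with `mode = "pooled"` one min/max is taken over all groups together.
#'
#' @param surfaces long tibble with columns `group`, `cell_id`, `value`
#'   (one metric at a time)
#' @param mode `"per-group"` (default) or `"pooled"`
#' @return the table with `value` rescaled to \[0, 1\]
#' @export
standardize_groups <- function(surfaces, mode = c("per-group", "pooled")) {
  mode <- match.arg(mode)
  check_one_metric(surfaces)
  if (mode == "pooled") return(minmax_standardize(surfaces))
  surfaces |>
    group_by(.data$group) |>
    dplyr::group_modify(~ minmax_standardize(.x)) |>
    ungroup()
}

check_one_metric <- function(surfaces) {
  stopifnot(is.data.frame(surfaces),
            all(c("group", "cell_id", "value") %in% names(surfaces)))
  if ("metric" %in% names(surfaces) &&
      length(unique(surfaces$metric)) > 1)
    abort("surfaces mix metrics; compare one metric at a time")
  if (length(unique(surfaces$group)) < 2)
    abort("need at least 2 groups")
  invisible(surfaces)
}

#' Mean-all summary surface across groups
#'
#' For each cell materialized in at least one group, the mean of the
#' standardized values of the groups materialized there. Groups absent
#' from a cell are excluded from that cell's mean (absence means
#' "unsampled", not zero diversity).
#'
#' @param surfaces long standardized tibble with columns `group`,
#'   `cell_id`, `value` and optionally `x`, `y`
#' @return tibble with one row per cell: cell_id, x, y, value, n_groups
#' @export
mean_all_cells <- function(surfaces) {
  check_one_metric(surfaces)
  has_xy <- all(c("x", "y") %in% names(surfaces))
  out <- surfaces |>
    group_by(.data$cell_id) |>
    summarise(x = if (has_xy) .data$x[1] else NA_real_,
              y = if (has_xy) .data$y[1] else NA_real_,
              value = mean(.data$value), n_groups = n(), .groups = "drop")
  out
}

#' Mean-concordant summary across groups
#'
#' Restricts to the concordant cells -- those where every group is
#' materialized with a nonzero standardized value -- and averages over all
#' groups there. If no cell is concordant, an empty summary is returned
#' with a warning.
#'
#' @inheritParams mean_all_cells
#' @return object of class `concordance_summary`: list with `mean_all`,
#'   `mean_concordant` (tibbles), `concordant_cells`, `n_concordant`,
#'   `groups`
#' @export
mean_concordant_cells <- function(surfaces) {
  check_one_metric(surfaces)
  groups <- sort(unique(surfaces$group))
  nz <- surfaces[surfaces$value != 0, , drop = FALSE]
  counts <- nz |>
    group_by(.data$cell_id) |>
    summarise(k = dplyr::n_distinct(.data$group), .groups = "drop")
  conc <- counts$cell_id[counts$k == length(groups)]
  if (length(conc) == 0) {
    warn("no concordant cells (no cell has nonzero values for all groups)")
    mean_conc <- tibble(cell_id = character(), x = numeric(),
                        y = numeric(), value = numeric(),
                        n_groups = integer())
  } else {
    mean_conc <- mean_all_cells(
      surfaces[surfaces$cell_id %in% conc, , drop = FALSE])
  }
  structure(list(
    mean_all = mean_all_cells(surfaces),
    mean_concordant = mean_conc,
    concordant_cells = sort(conc),
    n_concordant = length(conc),
    groups = groups
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> %d groups (%s); %d concordant cells of %d\n",
              length(x$groups), paste(x$groups, collapse = ", "),
              x$n_concordant, nrow(x$mean_all)))
  invisible(x)
}

#' Leave-one-group-out sensitivity of the concordance summary
#'
#' Recomputes the mean-all and mean-concordant summaries without the named
#' group — the sensitivity analysis for a group of restricted spatial
#' coverage (e.g. fish, absent from dry cells). Dropping a group can only
#' grow the concordant cell set.
#'
#' @inheritParams mean_all_cells
#' @param group group name to exclude
#' @return a `concordance_summary` over the remaining groups, with an
#'   extra field `delta_concordant` = change in concordant cell count
#' @export
leave_group_out <- function(surfaces, group) {
  check_one_metric(surfaces)
  if (!group %in% surfaces$group)
    abort(paste0("no such group: ", group))
  if (length(unique(surfaces$group)) < 3)
    abort("fewer than 2 groups would remain")
  full <- mean_concordant_cells(surfaces)
  rest <- mean_concordant_cells(
    surfaces[surfaces$group != group, , drop = FALSE])
  rest$excluded_group <- group
  rest$delta_concordant <- rest$n_concordant - full$n_concordant
  rest
}
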