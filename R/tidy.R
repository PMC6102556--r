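#' Tidy a null ensemble into per-cell p-values
#'
#' One row per cell and metric: observed value, rank p-values in both
#' tails, and the null mean.
#'
#' @param x a `null_ensemble`
#' @param ... unused
#' @return a tibble
#' @export
tidy.null_ensemble <- function(x, ...) {
  n_reps <- x$config$n_reps
  purrr::map_dfr(names(x$nulls), function(m) {
    obs <- x$observed[[m]]
    nulls <- x$nulls[[m]]
    tibble(
      cell_id = x$observed$cell_id,
      metric = m,
      observed = obs,
      null_mean = rowMeans(nulls),
      p_high = (1 + rowSums(nulls >= obs)) / (1 + n_reps),
      p_low = (1 + rowSums(nulls <= obs)) / (1 + n_reps)
    )
  })
}

#' One-row summary of a null ensemble
#' @param x a `null_ensemble`
#' @param ... unused
#' @return a tibble with one row
#' @export
glance.null_ensemble <- function(x, ...) {
  a <- x$config$alpha_two_tailed
  td <- tidy(x)
  pd <- td[td$metric == "PD", ]
  tibble(
    n_cells = nrow(x$observed),
    n_reps = x$config$n_reps,
    seed = x$config$seed,
    alpha_two_tailed = a,
    alpha_super = x$config$alpha_super,
    prop_pd_sig_two_tailed = mean(pd$p_high <= a / 2 | pd$p_low <= a / 2)
  )
}

#' Tidy a group-similarity result (per-cell similarities)
#' @param x a `group_similarity`
#' @param ... unused
#' @export
tidy.group_similarity <- function(x, ...) x$cells

#' One-row summary of a group-similarity result
#' @param x a `group_similarity`
#' @param ... unused
#' @export
glance.group_similarity <- function(x, ...) {
  tibble(n_cells = nrow(x$cells), similarity = x$similarity,
         dissimilarity = x$dissimilarity, radius = x$spec$radius,
         decay = x$spec$decay)
}

#' Tidy a concordance summary (mean-concordant surface)
#' @param x a `concordance_summary`
#' @param ... unused
#' @export
tidy.concordance_summary <- function(x, ...) x$mean_concordant

#' One-row summary of a concordance summary
#' @param x a `concordance_summary`
#' @param ... unused
#' @export
glance.concordance_summary <- function(x, ...) {
  tibble(n_groups = length(x$groups), n_cells_all = nrow(x$mean_all),
         n_concordant = x$n_concordant,
         excluded_group = x$excluded_group %||% NA_character_)
}
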