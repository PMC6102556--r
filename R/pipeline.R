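#' Analysis configuration
#'
#' Declarative description of a full multi-group run: per-group input
#' paths, grid, randomization settings, CANAPE variant, standardization
#' mode, fuzzy neighborhood and output directory. One global seed
#' deterministically derives per-group and per-stage seeds.
#'
#' @param groups named list; each element a list with `tree` (newick path)
#'   and `occurrences` (CSV path), optionally `columns` for
#'   [read_occurrences()]
#' @param grid a [grid_spec()]
#' @param randomization a [randomization_config()]
#' @param canape_step_one `"actual"` (default) or `"either"`
#' @param standardization `"per-group"` (default) or `"pooled"`
#' @param neighborhood a [neighborhood_spec()]
#' @param compare_metrics metrics for the cross-group layer (default TR,
#'   WE, PD, PE)
#' @param beta_clusters number of phylo-jaccard clusters to cut per group
#'   (default 3)
#' @param out_dir output directory
#' @param seed global seed
#' @return object of class `analysis_config`
#' @export
analysis_config <- function(groups, grid = grid_spec(),
                            randomization = randomization_config(),
                            canape_step_one = c("actual", "either"),
                            standardization = c("per-group", "pooled"),
                            neighborhood = neighborhood_spec(),
                            compare_metrics = c("TR", "WE", "PD", "PE"),
                            beta_clusters = 3,
                            out_dir = tempfile("phylospat_run_"),
                            seed = 1) {
  canape_step_one <- match.arg(canape_step_one)
  standardization <- match.arg(standardization)
  if (!is.list(groups) || length(groups) < 1 || is.null(names(groups)) ||
      any(!nzchar(names(groups))))
    abort("`groups` must be a named list with at least one group")
  for (g in names(groups)) {
    spec <- groups[[g]]
    for (field in c("tree", "occurrences")) {
      if (is.null(spec[[field]]))
        abort(sprintf("group '%s': missing %s path", g, field))
      if (!file.exists(spec[[field]]))
        abort(sprintf("group '%s': %s path does not exist: %s", g, field,
                      spec[[field]]))
    }
  }
  structure(list(groups = groups, grid = grid,
                 randomization = randomization,
                 canape_step_one = canape_step_one,
                 standardization = standardization,
                 neighborhood = neighborhood,
                 compare_metrics = compare_metrics,
                 beta_clusters = as.integer(beta_clusters),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Paths in the file are interpreted relative to the file's directory.
#' @param path YAML file
#' @return an `analysis_config`
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  groups <- lapply(y$groups, function(g) {
    g$tree <- rel(g$tree); g$occurrences <- rel(g$occurrences); g
  })
  analysis_config(
    groups = groups,
    grid = do.call(grid_spec, y$grid %||% list()),
    randomization = do.call(randomization_config, y$randomization %||% list()),
    canape_step_one = y$canape_step_one %||% "actual",
    standardization = y$standardization %||% "per-group",
    neighborhood = do.call(neighborhood_spec, y$neighborhood %||% list()),
    compare_metrics = y$compare_metrics %||% c("TR", "WE", "PD", "PE"),
    beta_clusters = y$beta_clusters %||% 3,
    out_dir = y$out_dir %||% tempfile("phylospat_run_"),
    seed = y$seed %||% 1
  )
}

stage_log <- function(manifest, stage, ...) {
  msg <- sprintf(...)
  inform(sprintf("[%s] %s", stage, msg))
  manifest$log <- c(manifest$log, sprintf("[%s] %s", stage, msg))
  manifest
}

#' Run the per-group analysis
#'
#' Executes the whole single-group pipeline: read tree and occurrences,
#' aggregate to the grid, align, compute the six observed surfaces, run
#' the randomization null, the PD/RPD significance tests and CANAPE, and
#' the phylo-jaccard beta-diversity clustering. All outputs are written
#' under `out_dir/<group>/` as CSV/newick and a JSON manifest; reruns with
#' the same config are byte-identical.
#'
#' @param config an [analysis_config()]
#' @param group group name (must be in `config$groups`)
#' @return (invisibly) named character vector of output files
#' @export
run_group_analysis <- function(config, group) {
  stopifnot(inherits(config, "analysis_config"))
  if (!group %in% names(config$groups))
    abort(paste0("unknown group: ", group))
  gi <- match(group, names(config$groups))
  gspec <- config$groups[[group]]
  dir.create(file.path(config$out_dir, group), recursive = TRUE,
             showWarnings = FALSE)
  outfile <- function(name) file.path(config$out_dir, group, name)
  manifest <- list(group = group, seed = config$seed, log = character(),
                   package_version = as.character(utils::packageVersion("phylospat")))
  t0 <- Sys.time()

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' (group '%s'): %s", stage, group,
                    conditionMessage(e))))
  }
  tree <- run_stage("read_tree", read_tree(gspec$tree))
  occ <- run_stage("read_occurrences", read_occurrences(
    gspec$occurrences,
    columns = unlist(gspec$columns %||%
                       c(taxon = "taxon", x = "x", y = "y"))))
  pa <- run_stage("aggregate", aggregate_to_grid(occ, config$grid))
  aligned <- run_stage("align", align_matrix_to_tree(pa, tree, "prune-both"))
  pa <- aligned$matrix; tree <- aligned$tree
  manifest <- stage_log(manifest, "align", "%d cells x %d taxa", nrow(pa$incidence),
                        ncol(pa$incidence))

  surfaces <- run_stage("metrics", diversity_metrics(pa, tree, group = group))
  write_surface(surfaces, outfile("surfaces.csv"))

  rc <- config$randomization
  rc$seed <- derive_seed(config$seed, gi)
  ens <- run_stage("randomize", build_null_ensemble(pa, tree, rc))
  manifest <- stage_log(manifest, "randomize", "%d null reps, seed %d",
                        rc$n_reps, rc$seed)
  sig_pd <- significance_ranks(ens, "PD", tail = "two")
  sig_rpd <- significance_ranks(ens, "RPD", tail = "two")
  readr::write_csv(bind_rows(sig_pd, sig_rpd), outfile("significance.csv"))
  cmap <- run_stage("canape", canape(ens, step_one = config$canape_step_one))
  readr::write_csv(cmap, outfile("canape.csv"))

  files <- c(surfaces = outfile("surfaces.csv"),
             significance = outfile("significance.csv"),
             canape = outfile("canape.csv"))
  if (nrow(pa$incidence) >= 2) {
    bi <- branch_incidence(tree, pa)
    dmat <- run_stage("beta", pairwise_phylo_jaccard(bi))
    dend <- average_linkage_cluster(dmat)
    k <- min(config$beta_clusters, nrow(pa$incidence))
    clusters <- cut_clusters(dend, k)
    write_dissim(dmat, outfile("phylo_jaccard.csv"))
    write_dendrogram(dend, outfile("beta_dendrogram.nwk"))
    readr::write_csv(clusters, outfile("beta_clusters.csv"))
    files <- c(files, dissim = outfile("phylo_jaccard.csv"),
               dendrogram = outfile("beta_dendrogram.nwk"),
               clusters = outfile("beta_clusters.csv"))
  }
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$files <- as.list(files)
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(files)
}

#' Run the cross-group analysis
#'
#' Consumes the per-group surface files written by [run_group_analysis()]
#' (running any missing group first): per metric, standardizes the groups,
#' computes the mean-all and mean-concordant summary surfaces,
#' leave-one-group-out sensitivity, and the fuzzy pairwise group
#' dissimilarity with its average-linkage dendrogram.
#'
#' @param config an [analysis_config()] with at least 2 groups
#' @return (invisibly) named character vector of output files
#' @export
run_cross_group_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (length(config$groups) < 2)
    abort("cross-group analysis needs at least 2 groups")
  cross_dir <- file.path(config$out_dir, "cross_group")
  dir.create(cross_dir, recursive = TRUE, showWarnings = FALSE)
  all_surf <- purrr::map_dfr(names(config$groups), function(g) {
    f <- file.path(config$out_dir, g, "surfaces.csv")
    if (!file.exists(f)) run_group_analysis(config, g)
    read_surface(f)
  })
  files <- character()
  manifest <- list(groups = names(config$groups),
                   standardization = config$standardization,
                   metrics = config$compare_metrics,
                   concordant = list(), log = character())
  for (m in config$compare_metrics) {
    surf_m <- all_surf[all_surf$metric == m, , drop = FALSE]
    std <- standardize_groups(surf_m, mode = config$standardization)
    readr::write_csv(std, file.path(cross_dir,
                                    sprintf("standardized_%s.csv", m)))
    summ <- mean_concordant_cells(std)
    readr::write_csv(summ$mean_all,
                     file.path(cross_dir, sprintf("mean_all_%s.csv", m)))
    readr::write_csv(summ$mean_concordant,
                     file.path(cross_dir, sprintf("mean_concordant_%s.csv", m)))
    manifest$concordant[[m]] <- summ$n_concordant
    if (length(config$groups) >= 3) {
      loo <- purrr::map_dfr(names(config$groups), function(g) {
        s <- leave_group_out(std, g)
        tibble(metric = m, excluded_group = g,
               n_concordant = s$n_concordant,
               delta_concordant = s$delta_concordant)
      })
      readr::write_csv(loo, file.path(cross_dir,
                                      sprintf("leave_one_out_%s.csv", m)))
    }
    dmat <- pairwise_group_dissimilarity(std, config$neighborhood)
    write_dissim(dmat, file.path(cross_dir,
                                 sprintf("group_dissimilarity_%s.csv", m)))
    write_dendrogram(cluster_groups(dmat),
                     file.path(cross_dir,
                               sprintf("group_dendrogram_%s.nwk", m)))
    stems <- c("standardized_%s.csv", "mean_all_%s.csv",
               "mean_concordant_%s.csv", "group_dissimilarity_%s.csv",
               "group_dendrogram_%s.nwk")
    if (length(config$groups) >= 3)
      stems <- append(stems, "leave_one_out_%s.csv", after = 3)
    new_files <- file.path(cross_dir, sprintf(stems, m))
    files <- c(files, setNames(new_files, basename(new_files)))
  }
  jsonlite::write_json(manifest, file.path(cross_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
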