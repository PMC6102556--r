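#' Neighborhood specification for fuzzy map comparison
#'
#' Defines the tolerance neighborhood: cells within `radius` meters
#' (centroid-to-centroid Euclidean distance) can stand in for one another,
#' with membership either decaying linearly from 1 at distance 0 to 0 at
#' the radius, or constant 1 inside the radius. The default radius of
#' 100 km corresponds to a circle of 200 km diameter.
#'
#' @param radius neighborhood radius in meters (>= 0), default 1e5
#' @param decay `"linear"` (default) or `"constant"`
#' @return object of class `neighborhood_spec`
#' @export
neighborhood_spec <- function(radius = 100000, decay = c("linear", "constant")) {
  decay <- match.arg(decay)
  stopifnot(is.numeric(radius), length(radius) == 1, radius >= 0)
  structure(list(radius = radius, decay = decay),
            class = "neighborhood_spec")
}

# local similarity of two values: 1 - |u - v| / max(|u|, |v|); 1 at 0,0
local_similarity <- function(u, v) {
  m <- pmax(abs(u), abs(v))
  ifelse(m == 0, 1, 1 - abs(u - v) / m)
}

# membership by distance
membership <- function(d, spec) {
  if (spec$radius == 0) return(as.numeric(d == 0))
  if (spec$decay == "linear") pmax(0, 1 - d / spec$radius)
  else as.numeric(d <= spec$radius)
}

#' Fuzzy numerical similarity of two diversity surfaces
#'
#' Neighborhood-tolerant comparison of two surfaces on a shared grid. For
#' each cell materialized in both surfaces, the directional score from a
#' to b is the best distance-discounted local match,
#' `max_j m(d_ij) * s(a_i, b_j)` over cells j of b within the radius, with
#' `s(u, v) = 1 - |u - v| / max(|u|, |v|)`; the cell's similarity is the
#' minimum of the two directions, and the scalar similarity is the mean
#' over the mutually materialized cells. This transparent formula is a
#' stand-in for proprietary fuzzy map-comparison tools, not a replica of
#' any of them.
#'
#' @param a,b `div_surface` tibbles (columns cell_id, x, y, value) sharing
#'   a grid geometry (shared cell ids must carry identical centroids)
#' @param spec a [neighborhood_spec()]
#' @return object of class `group_similarity`: list with `cells` (per-cell
#'   tibble), `similarity`, `dissimilarity`
#' @export
fuzzy_numerical_similarity <- function(a, b, spec = neighborhood_spec()) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            inherits(spec, "neighborhood_spec"))
  shared <- intersect(a$cell_id, b$cell_id)
  if (length(shared) == 0) abort("surfaces share no cells")
  ai <- a[match(shared, a$cell_id), ]
  bi <- b[match(shared, b$cell_id), ]
  if (max(abs(ai$x - bi$x), abs(ai$y - bi$y), na.rm = TRUE) > 1e-6)
    abort("grid mismatch: shared cells have different centroids")
  dir_score <- function(from, to) {
    # from, to: tibbles with x, y, value; score per `from` cell
    dx <- outer(from$x, to$x, "-")
    dy <- outer(from$y, to$y, "-")
    d <- sqrt(dx^2 + dy^2)
    m <- membership(d, spec)
    s <- outer(from$value, to$value, local_similarity)
    apply(m * s, 1, max)
  }
  sim_ab <- dir_score(ai, b)
  sim_ba <- dir_score(bi, a)
  cell_sim <- pmin(sim_ab, sim_ba)
  cells <- tibble(cell_id = shared, x = ai$x, y = ai$y,
                  similarity = cell_sim)
  scalar <- mean(cell_sim)
  structure(list(cells = cells, similarity = scalar,
                 dissimilarity = 1 - scalar, spec = spec),
            class = "group_similarity")
}

#' @export
print.group_similarity <- function(x, ...) {
  cat(sprintf("<group_similarity> %d shared cells; similarity %.4f\n",
              nrow(x$cells), x$similarity))
  invisible(x)
}

#' Pairwise fuzzy dissimilarity between taxonomic groups
#'
#' Applies [fuzzy_numerical_similarity()] to every pair of groups for one
#' metric and assembles the symmetric matrix of scalar dissimilarities
#' (heights near 0 mean very similar spatial patterns; near 1, highly
#' dissimilar).
#'
#' @param surfaces long tibble with columns `group`, `cell_id`, `x`, `y`,
#'   `value` for a single metric
#' @param spec a [neighborhood_spec()]
#' @return symmetric `dissim_matrix` over groups
#' @export
pairwise_group_dissimilarity <- function(surfaces,
                                         spec = neighborhood_spec()) {
  stopifnot(is.data.frame(surfaces),
            all(c("group", "cell_id", "x", "y", "value") %in% names(surfaces)))
  groups <- sort(unique(surfaces$group))
  if (length(groups) < 2) abort("need at least 2 groups")
  split_surf <- split(surfaces, surfaces$group)
  d <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
    res <- fuzzy_numerical_similarity(split_surf[[groups[i]]],
                                      split_surf[[groups[j]]], spec)
    d[i, j] <- d[j, i] <- res$dissimilarity
  }
  class(d) <- c("dissim_matrix", class(d))
  d
}

#' Cluster taxonomic groups by map similarity
#'
#' Average-linkage dendrogram over the pairwise fuzzy dissimilarities
#' (reuses [average_linkage_cluster()]); heights live in \[0, 1\].
#'
#' @param dissim a group dissimilarity matrix
#' @return an `hclust` dendrogram
#' @export
cluster_groups <- function(dissim) {
  average_linkage_cluster(dissim)
}
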