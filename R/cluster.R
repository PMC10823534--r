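#' Project an embedding to 2-D with UMAP
#'
#' Deterministic given `seed` (single-threaded layout optimization).
#'
#' @param emb a `csa_embedding` (e.g. from [ae_embed()]).
#' @param n_neighbors UMAP neighborhood size (default 30); must be at
#'   most n_cells - 1.
#' @param min_dist UMAP minimum embedding distance (default 0.3).
#' @param seed integer seed.
#' @return a `csa_embedding` with 2 columns.
#' @export
umap_2d <- function(emb, n_neighbors = 30, min_dist = 0.3, seed = 1L) {
  stopifnot(inherits(emb, "csa_embedding"))
  n <- nrow(emb$coords)
  if (n < n_neighbors + 1) {
    stop(sprintf("need at least n_neighbors + 1 = %d cells, have %d",
                 n_neighbors + 1, n))
  }
  set.seed(seed)
  xy <- uwot::umap(emb$coords, n_neighbors = n_neighbors,
                   min_dist = min_dist, n_components = 2, n_threads = 1,
                   n_sgd_threads = 0, verbose = FALSE)
  colnames(xy) <- c("UMAP1", "UMAP2")
  as_embedding(xy, emb$cell_ids)
}

# eps heuristic: 95th percentile of the distance to the min_samples-th
# nearest neighbor, so that roughly 95% of points are core points.
.default_eps <- function(d, min_samples) {
  k <- min(min_samples, nrow(d) - 1)
  knn <- apply(d, 1, function(r) sort(r)[k + 1])  # +1 skips self
  as.numeric(stats::quantile(knn, 0.95))
}

#' Density-based (DBSCAN) clustering of 2-D coordinates
#'
#' Classic DBSCAN: a point is a core point when at least `min_samples`
#' points (itself included) lie within distance `eps`; clusters are the
#' density-reachable expansions of core points; points reachable from no
#' core point are noise (label -1). Cluster labels are renumbered by
#' descending size so label 0 is always the largest cluster.
#'
#' @param coords2d a `csa_embedding` or numeric matrix of coordinates.
#' @param eps neighborhood radius; if NULL (default), the 95th percentile
#'   of `min_samples`-nearest-neighbor distances.
#' @param min_samples core-point threshold (default 10).
#' @return object of class `csa_clusters`: list(coords2d, labels,
#'   n_clusters, cell_ids, params).
#' @export
density_cluster <- function(coords2d, eps = NULL, min_samples = 10) {
  cell_ids <- NULL
  if (inherits(coords2d, "csa_embedding")) {
    cell_ids <- coords2d$cell_ids
    coords2d <- coords2d$coords
  }
  x <- as.matrix(coords2d)
  stopifnot(min_samples >= 1, is.null(eps) || eps > 0)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  if (is.null(eps)) eps <- .default_eps(d, min_samples)
  within <- d <= eps
  core <- rowSums(within) >= min_samples
  labels <- rep.int(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    # breadth-first expansion from core point i
    labels[i] <- cl
    frontier <- i
    while (length(frontier) > 0) {
      nbr <- which(colSums(within[frontier, , drop = FALSE]) > 0)
      nbr <- nbr[labels[nbr] == -1L]
      if (length(nbr) == 0) break
      labels[nbr] <- cl
      frontier <- nbr[core[nbr]]    # only core points expand further
    }
    cl <- cl + 1L
  }
  labels <- .relabel_by_size(labels)
  n_clusters <- length(unique(labels[labels >= 0]))
  if (n_clusters == 0) message("density_cluster: all points are noise")
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(n))
  structure(list(coords2d = x, labels = labels, n_clusters = n_clusters,
                 cell_ids = cell_ids,
                 params = list(eps = eps, min_samples = min_samples)),
            class = "csa_clusters")
}

# Renumber non-noise labels by descending cluster size (ties: first seen).
.relabel_by_size <- function(labels) {
  pos <- labels[labels >= 0]
  if (length(pos) == 0) return(labels)
  sizes <- sort(table(pos), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- labels
  out[labels >= 0] <- map[as.character(pos)]
  as.integer(out)
}

#' @export
print.csa_clusters <- function(x, ...) {
  cat(sprintf("csa_clusters: %d cells, %d clusters, %d noise (eps %.4g, minPts %d)\n",
              length(x$labels), x$n_clusters, sum(x$labels == -1L),
              x$params$eps, x$params$min_samples))
  invisible(x)
}

#' Per-(group, timepoint) cluster proportion table
#'
#' For each stratum of the metadata, the fraction of its cells in each
#' cluster (noise, when present, appears as cluster -1 so proportions
#' always sum to 1 within a stratum). Empty strata are omitted.
#'
#' @param labels integer cluster labels (or a `csa_clusters` object).
#' @param metadata data.frame with `group` and `timepoint`, one row per
#'   cell, aligned with `labels`.
#' @return data.frame(group, timepoint, cluster, n_cells, proportion).
#' @export
cluster_proportions <- function(labels, metadata) {
  if (inherits(labels, "csa_clusters")) labels <- labels$labels
  stopifnot(length(labels) == nrow(metadata))
  strata <- interaction(metadata$group, metadata$timepoint, drop = TRUE,
                        sep = "\r")
  out <- do.call(rbind, lapply(levels(strata), function(s) {
    idx <- strata == s
    parts <- strsplit(s, "\r", fixed = TRUE)[[1]]
    tab <- table(labels[idx])
    data.frame(group = parts[1], timepoint = parts[2],
               cluster = as.integer(names(tab)),
               n_cells = as.integer(tab),
               proportion = as.numeric(tab) / sum(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare two samples of per-replicate proportions (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test: exact when both sides have at most 10
#' replicates and there are no ties, otherwise the normal approximation
#' with continuity and tie correction.
#'
#' @param a,b numeric vectors of per-replicate proportions (non-empty).
#' @return two-sided p-value.
#' @export
compare_proportions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  exact <- length(a) <= 10 && length(b) <= 10 &&
    !anyDuplicated(c(a, b))
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
  if (is.nan(p)) p <- 1.0   # fully tied degenerate case
  p
}
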