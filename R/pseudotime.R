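#' Build a landmark minimum-spanning-tree backbone over an embedding
#'
#' Landmarks are k-means centers computed per cluster (the `k_landmarks`
#' budget is split across clusters proportionally to their size, at least
#' one each); the backbone is the minimum spanning tree of the complete
#' Euclidean-distance graph over the landmarks. This is an explicit
#' simplification of principal-graph trajectory methods: the acceptance
#' surface (marker ordering along the path, branch detection) is the
#' same, the graph-learning machinery is not.
#'
#' @param emb a `csa_embedding`.
#' @param labels integer cluster labels (or a `csa_clusters` object);
#'   noise cells (-1) are ignored when placing landmarks.
#' @param k_landmarks total number of landmarks (default 10, at least 2).
#' @param seed seed for k-means.
#' @return object of class `csa_backbone`: list(landmarks, edges, graph,
#'   landmark_cluster).
#' @export
build_backbone <- function(emb, labels = NULL, k_landmarks = 10,
                           seed = 1L) {
  stopifnot(inherits(emb, "csa_embedding"))
  X <- emb$coords
  if (inherits(labels, "csa_clusters")) labels <- labels$labels
  if (is.null(labels)) labels <- rep.int(0L, nrow(X))
  keep <- labels >= 0
  Xk <- X[keep, , drop = FALSE]
  lab <- labels[keep]
  if (nrow(unique(Xk)) == 1) {
    # degenerate: all cells identical -> single-node backbone
    lm <- Xk[1, , drop = FALSE]
    g <- igraph::make_empty_graph(1, directed = FALSE)
    return(structure(list(landmarks = lm,
                          edges = data.frame(from = integer(0),
                                             to = integer(0),
                                             length = numeric(0)),
                          graph = g, landmark_cluster = lab[1]),
                     class = "csa_backbone"))
  }
  cl_sizes <- table(lab)
  cls <- as.integer(names(cl_sizes))
  k_landmarks <- max(2L, as.integer(k_landmarks))
  # proportional allocation, >= 1 per cluster
  alloc <- pmax(1L, round(k_landmarks * as.numeric(cl_sizes) / sum(cl_sizes)))
  set.seed(seed)
  lms <- list(); lm_cl <- integer(0)
  for (i in seq_along(cls)) {
    pts <- Xk[lab == cls[i], , drop = FALSE]
    k <- min(alloc[i], nrow(unique(pts)))
    ctr <- if (k == 1) matrix(colMeans(pts), 1) else
      stats::kmeans(pts, centers = k, nstart = 5, iter.max = 50)$centers
    lms[[i]] <- ctr
    lm_cl <- c(lm_cl, rep.int(cls[i], nrow(ctr)))
  }
  lm <- do.call(rbind, lms)
  rownames(lm) <- NULL
  if (nrow(lm) < 2) stop("need at least 2 landmarks")
  d <- as.matrix(stats::dist(lm))
  g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                weighted = TRUE)
  g <- igraph::mst(g_full)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      length = igraph::E(g)$weight)
  structure(list(landmarks = lm, edges = edges, graph = g,
                 landmark_cluster = lm_cl),
            class = "csa_backbone")
}

#' Degrees of the backbone nodes (branch points have degree >= 3)
#' @param backbone a [build_backbone()] result.
#' @return integer vector of node degrees.
#' @export
backbone_degrees <- function(backbone) {
  as.integer(igraph::degree(backbone$graph))
}

#' Assign a root-anchored pseudotime along the backbone
#'
#' Each cell is projected orthogonally onto its nearest backbone edge;
#' its pseudotime is the along-tree distance from the root to the
#' projection, divided by the maximum such distance (so values lie in
#' \[0, 1\] and the root maps to 0). The root is a landmark id, or —
#' mirroring the use of proliferation markers to orient a trajectory —
#' the landmark whose assigned cells have the lowest mean expression of
#' `root_gene` (default MKI67), so pseudotime runs from quiescent toward
#' cycling cells.
#'
#' @param emb the `csa_embedding` the backbone was built on.
#' @param backbone a [build_backbone()] result.
#' @param root landmark id (1-based), or NULL to select by `root_gene`.
#' @param norm `csa_norm` with the cells of `emb` (required when
#'   selecting the root by gene).
#' @param root_gene gene symbol used for root selection.
#' @return object of class `csa_pseudotime`: list(order, cell_ids, root,
#'   backbone).
#' @export
assign_pseudotime <- function(emb, backbone, root = NULL, norm = NULL,
                              root_gene = "MKI67") {
  stopifnot(inherits(emb, "csa_embedding"),
            inherits(backbone, "csa_backbone"))
  X <- emb$coords
  lm <- backbone$landmarks
  n_lm <- nrow(lm)
  if (n_lm == 1) {
    return(structure(list(order = rep(0, nrow(X)), cell_ids = emb$cell_ids,
                          root = 1L, backbone = backbone),
                     class = "csa_pseudotime"))
  }
  # nearest landmark per cell (used for gene-based root selection)
  d_lm <- .cross_dist(X, lm)
  nearest <- max.col(-d_lm)
  if (is.null(root)) {
    if (is.null(norm)) stop("gene-based root selection requires 'norm'")
    root_gene <- toupper(root_gene)
    j <- match(root_gene, norm$gene_symbols)
    if (is.na(j)) stop("root gene not in matrix: ", root_gene)
    v <- norm$values[, j]
    means <- vapply(seq_len(n_lm), function(l) {
      cells <- nearest == l
      if (!any(cells)) Inf else mean(v[cells])
    }, numeric(1))
    root <- which.min(means)
  }
  stopifnot(root >= 1, root <= n_lm)
  droot <- igraph::distances(backbone$graph, v = root)[1, ]

  # project each cell on each edge, keep the closest edge
  e <- backbone$edges
  best_d <- rep(Inf, nrow(X)); best_pt <- rep(NA_real_, nrow(X))
  for (k in seq_len(nrow(e))) {
    a <- lm[e$from[k], ]; b <- lm[e$to[k], ]
    ab <- b - a; L2 <- sum(ab^2)
    t <- if (L2 == 0) rep(0, nrow(X)) else
      as.numeric(pmin(pmax((sweep(X, 2, a, "-") %*% ab) / L2, 0), 1))
    proj <- outer(t, ab) + matrix(a, nrow(X), length(a), byrow = TRUE)
    dd <- rowSums((X - proj)^2)
    # along-tree distance root -> projection point on edge (from, to)
    Ld <- sqrt(L2)
    pt <- pmin(droot[e$from[k]] + t * Ld, droot[e$to[k]] + (1 - t) * Ld)
    upd <- dd < best_d
    best_d[upd] <- dd[upd]
    best_pt[upd] <- pt[upd]
  }
  mx <- max(best_pt)
  order <- if (mx > 0) best_pt / mx else best_pt
  structure(list(order = order, cell_ids = emb$cell_ids,
                 root = as.integer(root), backbone = backbone),
            class = "csa_pseudotime")
}

.cross_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Check marker ordering along pseudotime
#'
#' Computes each marker's expression-weighted mean pseudotime
#' (`sum(expr * t) / sum(expr)`) and the Kendall tau between those means
#' and the supplied sequence order: 1 means the markers peak in exactly
#' the supplied order (e.g. CCND1 -> CCNE2 -> CCNB2 -> MKI67 for the
#' G1/S -> S -> M -> proliferation progression), -1 a full reversal.
#' Markers expressed in no cell are skipped with a warning.
#'
#' @param pt a [assign_pseudotime()] result.
#' @param norm `csa_norm` aligned with the pseudotime cells.
#' @param marker_sequence character vector of gene symbols in expected
#'   temporal order.
#' @return list(tau, means) where `means` is the named vector of
#'   expression-weighted mean pseudotimes.
#' @export
marker_ordering_check <- function(pt, norm, marker_sequence) {
  stopifnot(inherits(pt, "csa_pseudotime"))
  marker_sequence <- toupper(marker_sequence)
  j <- match(marker_sequence, norm$gene_symbols)
  if (anyNA(j)) {
    stop("marker(s) not in matrix: ",
         paste(marker_sequence[is.na(j)], collapse = ", "))
  }
  means <- vapply(j, function(col) {
    w <- norm$values[, col]
    s <- sum(w)
    if (s == 0) NA_real_ else sum(w * pt$order) / s
  }, numeric(1))
  names(means) <- marker_sequence
  if (anyNA(means)) {
    warning("skipping marker(s) expressed in no cell: ",
            paste(marker_sequence[is.na(means)], collapse = ", "))
  }
  ok <- !is.na(means)
  tau <- suppressWarnings(
    stats::cor(seq_along(means)[ok], means[ok], method = "kendall")
  )
  list(tau = tau, means = means)
}
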