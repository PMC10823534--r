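#' Specification for the synthetic snRNA-seq count generator
#'
#' Describes a stratified population of cell clusters with planted marker
#' genes. Background counts are negative-binomial with per-gene
#' dispersion and lognormal library sizes. A planted marker is governed
#' by two independent dials: its expressing-cell fractions (`prop_in`
#' inside the cluster, `prop_out` outside; drawn exactly as Bernoulli
#' indicators) and its `fold_change`, defined as the ratio of mean
#' expression among expressing in-cluster cells to that among expressing
#' out-cluster cells (positive counts come from a zero-truncated NB with
#' the mean solved to hit that ratio). See [simulate_counts()].
#'
#' @param genes character vector of gene symbols.
#' @param cell_cycle_genes subset of `genes` flagged as cell-cycle.
#' @param clusters data.frame(name, class, proliferating) with class in
#'   "VEC"/"LEC".
#' @param strata data.frame(group, timepoint, n_cells).
#' @param proportions matrix, clusters x strata; every column sums to 1.
#' @param markers data.frame(cluster, gene, fold_change, prop_in,
#'   prop_out); fold_change >= 1.
#' @param baseline_mu per-gene NB mean (scalar recycled).
#' @param dispersion per-gene NB dispersion theta > 0 (scalar recycled).
#' @param lib_meanlog,lib_sdlog lognormal library-size parameters.
#' @return validated list of class `csa_sim_spec`.
#' @export
sim_spec <- function(genes, cell_cycle_genes, clusters, strata,
                     proportions, markers = NULL, baseline_mu = 0.3,
                     dispersion = 2, lib_meanlog = log(1500),
                     lib_sdlog = 0.3) {
  genes <- toupper(genes)
  cell_cycle_genes <- toupper(cell_cycle_genes)
  if (anyDuplicated(genes)) stop("duplicate gene symbols in spec")
  if (!all(cell_cycle_genes %in% genes)) {
    stop("cell_cycle_genes must be a subset of genes")
  }
  clusters <- as.data.frame(clusters, stringsAsFactors = FALSE)
  strata <- as.data.frame(strata, stringsAsFactors = FALSE)
  if (is.null(markers)) {
    markers <- data.frame(cluster = character(0), gene = character(0),
                          fold_change = numeric(0), prop_in = numeric(0),
                          prop_out = numeric(0))
  }
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  proportions <- as.matrix(proportions)
  stopifnot(nrow(proportions) == nrow(clusters),
            ncol(proportions) == nrow(strata),
            all(clusters$class %in% c("VEC", "LEC")),
            all(strata$n_cells >= 1))
  if (any(abs(colSums(proportions) - 1) > 1e-9)) {
    stop("per-stratum cluster proportions must sum to 1")
  }
  markers$gene <- toupper(markers$gene)
  if (!all(markers$gene %in% genes)) stop("marker gene not in gene list")
  if (!all(markers$cluster %in% clusters$name)) {
    stop("marker cluster not in cluster table")
  }
  if (any(markers$fold_change < 1)) stop("planted fold_change must be >= 1")
  if (any(markers$prop_in <= 0 & markers$fold_change > 1)) {
    stop("infeasible marker: prop_in = 0 with fold_change > 1")
  }
  baseline_mu <- rep_len(baseline_mu, length(genes))
  dispersion <- rep_len(dispersion, length(genes))
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  if (any(baseline_mu <= 0)) stop("baseline_mu must be positive")
  structure(list(genes = genes, cell_cycle_genes = cell_cycle_genes,
                 clusters = clusters, strata = strata,
                 proportions = proportions, markers = markers,
                 baseline_mu = baseline_mu, dispersion = dispersion,
                 lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog),
            class = "csa_sim_spec")
}

#' Simulate a stratified snRNA-seq count matrix with planted structure
#'
#' For each stratum, cluster labels are multinomial with the stratum's
#' proportions. Background genes: each cell draws a lognormal library
#' size `L` and counts `NB(mean = L * mu_g / sum(mu), theta_g)`. Planted
#' marker genes are generated by an exact two-part model: a cell
#' expresses the gene with probability `prop_in` (its cluster) or
#' `prop_out` (elsewhere), and expressing cells draw from a
#' zero-truncated NB whose mean is solved so that the expected
#' expression level among expressing in-cluster cells is exactly
#' `fold_change` times the level among expressing out-cluster cells.
#' Planted expressing fractions and fold-changes are therefore exact in
#' expectation and independently controllable. Fully deterministic given
#' `seed`.
#'
#' @param spec a [sim_spec()].
#' @param seed integer seed.
#' @return list(counts, truth): a [count_matrix()] with metadata, and a
#'   ground-truth list with per-cell `cluster`, the cluster table, the
#'   marker table and the cell-cycle gene set.
#' @export
simulate_counts <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "csa_sim_spec"))
  set.seed(seed)
  G <- length(spec$genes)
  K <- nrow(spec$clusters)
  cl_names <- spec$clusters$name

  # per-cluster fold and expressing-probability matrices (K x G),
  # NA = not a marker gene for any cluster
  marker_cols <- match(unique(spec$markers$gene), spec$genes)
  Fold <- matrix(1, K, G)
  Prob <- matrix(NA_real_, K, G)
  for (g in unique(spec$markers$gene)) {
    rows <- spec$markers[spec$markers$gene == g, ]
    j <- match(g, spec$genes)
    Prob[, j] <- rows$prop_out[nrow(rows)]
    for (r in seq_len(nrow(rows))) {
      k <- match(rows$cluster[r], cl_names)
      Fold[k, j] <- rows$fold_change[r]
      Prob[k, j] <- rows$prop_in[r]
    }
  }

  counts <- NULL; meta_rows <- list(); lab_all <- character(0)
  for (s in seq_len(nrow(spec$strata))) {
    n <- spec$strata$n_cells[s]
    lab <- sample(cl_names, n, replace = TRUE,
                  prob = spec$proportions[, s])
    L <- stats::rlnorm(n, spec$lib_meanlog, spec$lib_sdlog)
    block <- matrix(0, n, G)
    p <- spec$baseline_mu / sum(spec$baseline_mu)
    for (k in seq_len(K)) {
      idx <- which(lab == cl_names[k])
      if (length(idx) == 0) next
      mu_mat <- outer(L[idx], p)
      draws <- stats::rnbinom(length(idx) * G, mu = as.vector(mu_mat),
                              size = rep(spec$dispersion,
                                         each = length(idx)))
      m <- matrix(draws, length(idx), G)
      for (j in marker_cols) {
        theta <- spec$dispersion[j]
        nu_base <- .ztnb_mean(spec$baseline_mu[j], theta)
        target <- Fold[k, j] * nu_base
        mm <- .ztnb_solve(target, theta)
        p0 <- (theta / (theta + mm))^theta
        expr <- stats::rbinom(length(idx), 1, Prob[k, j])
        u <- stats::runif(length(idx), p0, 1)
        m[, j] <- expr * stats::qnbinom(u, mu = mm, size = theta)
      }
      block[idx, ] <- m
    }
    counts <- rbind(counts, block)
    meta_rows[[s]] <- data.frame(group = spec$strata$group[s],
                                 timepoint = spec$strata$timepoint[s],
                                 n = n, stringsAsFactors = FALSE)
    lab_all <- c(lab_all, lab)
  }
  n_tot <- nrow(counts)
  ids <- sprintf("cell%05d", seq_len(n_tot))
  meta <- data.frame(cell_id = ids,
                     group = rep(vapply(meta_rows, `[[`, "", "group"),
                                 vapply(meta_rows, `[[`, 0, "n")),
                     timepoint = rep(vapply(meta_rows, `[[`, "",
                                            "timepoint"),
                                     vapply(meta_rows, `[[`, 0, "n")),
                     stringsAsFactors = FALSE)
  cm <- count_matrix(counts, spec$genes, ids, meta)
  truth <- list(cluster = lab_all, clusters = spec$clusters,
                markers = spec$markers,
                cell_cycle_genes = spec$cell_cycle_genes)
  list(counts = cm, truth = truth)
}

# mean of a zero-truncated NB with untruncated mean m, dispersion theta
.ztnb_mean <- function(m, theta) {
  p0 <- (theta / (theta + m))^theta
  m / (1 - p0)
}

# solve for the untruncated NB mean whose zero-truncated mean is `target`
# (monotone in m; target >= ztnb_mean as m -> 0, which tends to 1+)
.ztnb_solve <- function(target, theta) {
  if (target <= 1) return(1e-8)   # degenerate: essentially all-ones
  f <- function(m) .ztnb_mean(m, theta) - target
  stats::uniroot(f, c(1e-8, target), tol = 1e-10)$root
}

#' Default study-like simulation spec
#'
#' Emulates the structure of the cardiac endothelial dataset the pipeline
#' targets: 2,000 cells over four (group, timepoint) strata, 1,000 genes
#' of which 300 are cell-cycle-flagged, and five planted clusters — three
#' vascular-like (one proliferating, one quiescent majority reservoir,
#' one EndMT-like) and two lymphatic-like (one proliferating). Each
#' cluster carries 30 cluster-specific cell-cycle genes (fold 6,
#' expressing fraction 0.8 inside vs 0.05 outside) defining its cycle
#' state; the proliferating clusters plant the five mitosis markers
#' (AURKB, MKI67, INCENP, BIRC5, CDCA8); VEC clusters plant CD34/PLVAP
#' and LEC clusters CCL21/PROX1/LYVE1; the EndMT-like cluster plants
#' PKP2/CDH11/CDH18/PDGFRA. Pan-EC genes (PECAM1, KDR, CDH5) are
#' high-abundance baseline genes in every cluster. Stratum proportions
#' follow the fetal-versus-postnatal pattern of the study system (LECs
#' rare in fetal hearts, roughly a third of ECs postnatally; the
#' EndMT-like cluster prominent in fetal and regenerating hearts).
#'
#' @return a [sim_spec()].
#' @export
default_study_spec <- function() {
  prolif <- c("AURKB", "MKI67", "INCENP", "BIRC5", "CDCA8")
  cycle_extra <- c("CCND1", "CCNE2", "CCNB2")
  cc_filler <- sprintf("CC%03d", seq_len(300 - length(prolif) -
                                           length(cycle_extra)))
  cc_genes <- c(prolif, cycle_extra, cc_filler)
  panels <- c("PECAM1", "KDR", "CDH5", "CD34", "PLVAP", "CCL21", "PROX1",
              "LYVE1")
  endmt <- c("PKP2", "CDH11", "CDH18", "PDGFRA")
  other_filler <- sprintf("GF%03d", seq_len(1000 - 300 - length(panels) -
                                              length(endmt)))
  genes <- c(cc_genes, panels, endmt, other_filler)

  clusters <- data.frame(
    name = c("VEC1", "VEC2", "VEC3", "LEC1", "LEC2"),
    class = c("VEC", "VEC", "VEC", "LEC", "LEC"),
    proliferating = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  strata <- data.frame(
    group = c("fetal", "CTL", "MI_P28", "AR_P1_MI_P28"),
    timepoint = c("E80", "P28", "P30", "P30"),
    n_cells = c(300L, 500L, 600L, 600L), stringsAsFactors = FALSE)
  proportions <- cbind(
    fetal = c(0.087, 0.55, 0.30, 0.013, 0.05),
    CTL = c(0.010, 0.55, 0.03, 0.010, 0.40),
    MI = c(0.040, 0.56, 0.016, 0.024, 0.36),
    AR = c(0.042, 0.52, 0.063, 0.025, 0.35))

  mk <- function(cluster, gene, fold, p_in, p_out) {
    data.frame(cluster = cluster, gene = gene, fold_change = fold,
               prop_in = p_in, prop_out = p_out, stringsAsFactors = FALSE)
  }
  # cluster-identity cell-cycle programs: 30 genes each (the two
  # proliferating clusters use the five mitosis markers + 25 fillers)
  id_blocks <- list(VEC1 = c(prolif, cc_filler[1:25]),
                    VEC2 = cc_filler[26:55],
                    VEC3 = cc_filler[56:85],
                    LEC1 = c(prolif, cc_filler[86:110]),
                    LEC2 = cc_filler[111:140])
  markers <- do.call(rbind, lapply(names(id_blocks), function(k) {
    mk(k, id_blocks[[k]], 6, 0.8, ifelse(id_blocks[[k]] %in% prolif,
                                         0.02, 0.05))
  }))
  # class panels: the large quiescent VEC cluster expresses the VEC
  # panel at a slightly lower fraction than the specialized ones, so the
  # panel stays detectable against the pooled out-group (see vignette)
  markers <- rbind(markers,
                   mk("VEC1", c("CD34", "PLVAP"), 4, 0.90, 0.02),
                   mk("VEC2", c("CD34", "PLVAP"), 4, 0.75, 0.02),
                   mk("VEC3", c("CD34", "PLVAP"), 4, 0.90, 0.02),
                   mk("LEC1", c("CCL21", "PROX1", "LYVE1"), 4, 0.90, 0.02),
                   mk("LEC2", c("CCL21", "PROX1", "LYVE1"), 4, 0.90, 0.02),
                   mk("VEC3", endmt, 8, 0.70, 0.03))
  baseline_mu <- rep(0.3, length(genes))
  baseline_mu[match(c("PECAM1", "KDR", "CDH5"), genes)] <- 3
  sim_spec(genes, cc_genes, clusters, strata, proportions, markers,
           baseline_mu = baseline_mu, dispersion = 2)
}

#' Simulate a linear expression gradient with staged markers
#'
#' Cells carry a latent progression coordinate `t ~ Uniform(0, 1)`. Each
#' staged marker's NB mean is multiplied by a Gaussian bump centered at
#' its stage (so markers activate in sequence), and a set of monotone
#' "ramp" genes increases or decreases linearly with `t` (the smooth
#' component a progression needs for its geometry to be recoverable);
#' the first ramp-up gene, `GRAD_UP01`, is a convenient root selector.
#'
#' @param n_cells number of cells.
#' @param markers character vector of staged marker symbols (in stage
#'   order).
#' @param stages strictly increasing values in (0, 1), one per marker.
#' @param seed integer seed.
#' @param n_ramp number of ramp-up and ramp-down genes (default 10 each).
#' @param n_background extra constant-mean genes (default 40).
#' @param bump_amp,bump_width bump multiplier amplitude and s.d.
#' @return list(counts, truth) with `truth$t` the latent coordinate.
#' @export
simulate_gradient <- function(n_cells = 600, markers = c("CCND1", "CCNE2",
                                                         "CCNB2", "MKI67"),
                              stages = c(0.2, 0.4, 0.6, 0.8), seed = 1L,
                              n_ramp = 10, n_background = 40,
                              bump_amp = 8, bump_width = 0.12) {
  if (length(stages) != length(markers)) {
    stop("one stage per marker required")
  }
  if (length(stages) > 0 &&
      (any(diff(stages) <= 0) || any(stages <= 0) || any(stages >= 1))) {
    stop("stages must be strictly increasing within (0, 1)")
  }
  set.seed(seed)
  markers <- toupper(markers)
  up <- sprintf("GRAD_UP%02d", seq_len(n_ramp))
  dn <- sprintf("GRAD_DN%02d", seq_len(n_ramp))
  bg <- sprintf("BG%03d", seq_len(n_background))
  genes <- c(markers, up, dn, bg)
  G <- length(genes)
  t <- stats::runif(n_cells)
  mu <- matrix(0.5, n_cells, G)
  for (i in seq_along(markers)) {
    mu[, i] <- 0.5 * (1 + bump_amp *
                        exp(-(t - stages[i])^2 / (2 * bump_width^2)))
  }
  if (n_ramp > 0) {
    iu <- length(markers) + seq_len(n_ramp)
    mu[, iu] <- 0.5 * (0.2 + 3 * t)
    mu[, iu + n_ramp] <- 0.5 * (3.2 - 3 * t)
  }
  L <- stats::rlnorm(n_cells, log(800), 0.25)
  P <- mu / rowSums(mu)
  counts <- matrix(stats::rnbinom(n_cells * G, mu = as.vector(P * L),
                                  size = 2), n_cells, G)
  ids <- sprintf("cell%05d", seq_len(n_cells))
  meta <- data.frame(cell_id = ids, group = "CTL", timepoint = "P28",
                     stringsAsFactors = FALSE)
  cm <- count_matrix(counts, genes, ids, meta)
  list(counts = cm, truth = list(t = t, markers = markers,
                                 stages = stages))
}

#' Simulate a branched (Y-shaped) latent structure
#'
#' A reservoir state and two divergent arms: each cell sits on one of
#' three arms at depth `t ~ Uniform(0, 1)`; an arm-specific gene module
#' ramps up with depth while a shared reservoir module ramps down, so the
#' expression manifold is a Y whose three tips are the mature states.
#'
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param n_module genes per arm module (default 15).
#' @param arm_probs arm assignment probabilities (reservoir-heavy default).
#' @return list(counts, truth); `truth$arm` in 1..3, `truth$t` depth.
#' @export
simulate_branched <- function(n_cells = 600, seed = 1L, n_module = 15,
                              arm_probs = c(0.4, 0.3, 0.3)) {
  set.seed(seed)
  arm <- sample.int(3, n_cells, replace = TRUE, prob = arm_probs)
  t <- stats::runif(n_cells)
  mods <- lapply(1:3, function(a) sprintf("ARM%d_%02d", a,
                                          seq_len(n_module)))
  shared <- sprintf("CORE%02d", seq_len(n_module))
  bg <- sprintf("BG%03d", seq_len(30))
  genes <- c(unlist(mods), shared, bg)
  G <- length(genes)
  mu <- matrix(0.4, n_cells, G)
  for (a in 1:3) {
    cols <- (a - 1) * n_module + seq_len(n_module)
    mu[arm == a, cols] <- 0.4 * (1 + 6 * t[arm == a])
  }
  shared_cols <- 3 * n_module + seq_len(n_module)
  mu[, shared_cols] <- 0.4 * (3 - 2.5 * t)
  L <- stats::rlnorm(n_cells, log(700), 0.25)
  P <- mu / rowSums(mu)
  counts <- matrix(stats::rnbinom(n_cells * G, mu = as.vector(P * L),
                                  size = 2), n_cells, G)
  ids <- sprintf("cell%05d", seq_len(n_cells))
  meta <- data.frame(cell_id = ids, group = "CTL", timepoint = "P28",
                     stringsAsFactors = FALSE)
  cm <- count_matrix(counts, genes, ids, meta)
  list(counts = cm, truth = list(arm = arm, t = t))
}
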