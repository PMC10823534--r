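#' Run the full cell-cycle-specific embedding and annotation pipeline
#'
#' Chains the stages on a raw count matrix: gene QC by total UMI,
#' log-normalization, restriction to the cell-cycle gene set, sparse
#' autoencoder training and embedding, 2-D UMAP, DBSCAN clustering,
#' marker calling on the full normalized matrix, panel-based cluster
#' classification, and per-stratum cluster proportions.
#'
#' @param counts a [count_matrix()] with metadata.
#' @param cell_cycle a [gene_set()] of cell-cycle genes.
#' @param min_total_umi gene QC threshold (default 0: the simulator's
#'   gene set is already curated; use 1000 for full-transcriptome data).
#' @param ae_cfg an [ae_config()] for the embedding network.
#' @param n_runs number of independently initialized autoencoder
#'   trainings whose embeddings are concatenated before UMAP (default 3).
#'   A single 10-unit bottleneck can intermittently fold a small
#'   subpopulation onto a neighboring one; concatenating a few seeded
#'   runs makes the pooled geometry keep any separation that at least
#'   one run finds. Run r uses seed `ae_cfg$seed + 1000 * (r - 1)`.
#' @param umap_n_neighbors,umap_min_dist UMAP parameters.
#' @param eps,min_samples DBSCAN parameters (eps NULL = k-NN heuristic).
#' @param panels marker panels for [classify_clusters()].
#' @param seed seed for UMAP (the autoencoder has its own in `ae_cfg`).
#' @return list with elements norm, norm_cc, model, trace (model and
#'   trace are from the first run), embedding (the concatenated
#'   coordinates), umap, clusters, markers, annotation, proportions.
#' @export
run_csa_pipeline <- function(counts, cell_cycle,
                             min_total_umi = 0,
                             ae_cfg = ae_config(), n_runs = 3,
                             umap_n_neighbors = 30, umap_min_dist = 0.3,
                             eps = NULL, min_samples = 10,
                             panels = default_marker_panels(),
                             seed = 1L) {
  stopifnot(inherits(counts, "csa_counts"))
  if (min_total_umi > 0) {
    counts <- filter_genes_by_umi(counts, min_total_umi)
  }
  norm <- log_normalize(counts)
  norm_cc <- subset_to_gene_set(norm, cell_cycle)
  fits <- lapply(seq_len(max(1, n_runs)), function(r) {
    cfg_r <- ae_cfg
    cfg_r$seed <- ae_cfg$seed + 1000L * (r - 1L)
    ae_train(norm_cc, cfg_r)
  })
  fit <- fits[[1]]
  emb <- as_embedding(do.call(cbind, lapply(fits, function(f) {
    ae_embed(f$model, norm_cc)$coords
  })), norm_cc$cell_ids)
  um <- umap_2d(emb, n_neighbors = umap_n_neighbors,
                min_dist = umap_min_dist, seed = seed)
  cl <- density_cluster(um, eps = eps, min_samples = min_samples)
  markers <- call_markers(norm, cl$labels)
  ann <- classify_clusters(markers, panels)
  prop <- if (!is.null(norm$metadata)) {
    cluster_proportions(cl$labels, norm$metadata)
  } else NULL
  list(norm = norm, norm_cc = norm_cc, model = fit$model,
       trace = fit$trace, embedding = emb, umap = um, clusters = cl,
       markers = markers, annotation = ann, proportions = prop)
}
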