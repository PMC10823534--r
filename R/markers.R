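#' Expressing-cell contingency counts for one (cluster, gene) pair
#'
#' A cell "expresses" a gene when its raw count is positive, equivalently
#' when its log-normalized value is positive. The out-group is every cell
#' assigned to another cluster; noise cells (label -1) are excluded from
#' both sides.
#'
#' @param norm a `csa_norm` object.
#' @param labels integer cluster labels aligned with the cells.
#' @param cluster cluster id (non-negative integer).
#' @param gene gene symbol.
#' @return named vector (n_expr_in, n_in, n_expr_out, n_out).
#' @export
expression_contingency <- function(norm, labels, cluster, gene) {
  gene <- toupper(gene)
  j <- match(gene, norm$gene_symbols)
  if (is.na(j)) stop("gene not in matrix: ", gene)
  if (!cluster %in% labels) stop("no cells with cluster label ", cluster)
  expr <- norm$values[, j] > 0
  inn <- labels == cluster
  out <- labels != cluster & labels >= 0
  c(n_expr_in = sum(expr & inn), n_in = sum(inn),
    n_expr_out = sum(expr & out), n_out = sum(out))
}

#' One-sided Fisher exact enrichment p-value
#'
#' Upper hypergeometric tail probability that at least `n_expr_in` of the
#' `n_in` in-cluster cells express the gene, given the overall number of
#' expressing cells: `P[X >= n_expr_in]` with
#' `X ~ Hypergeom(n_in + n_out, n_expr_in + n_expr_out, n_in)`. Computed
#' via the log-space hypergeometric tail, so tables with totals up to 1e6
#' do not underflow. A two-sided variant (the usual Fisher exact
#' two-sided rule) is available via `alternative = "two.sided"`.
#'
#' @param n_expr_in,n_in,n_expr_out,n_out contingency entries.
#' @param alternative "greater" (default, enrichment) or "two.sided".
#' @return p-value in \[0, 1\].
#' @export
fisher_exact_enrichment <- function(n_expr_in, n_in, n_expr_out, n_out,
                                    alternative = c("greater",
                                                    "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_in <= 0 || n_out < 0) stop("n_in must be positive")
  if (n_expr_in > n_in || n_expr_out > n_out) {
    stop("impossible contingency table (more expressing than total)")
  }
  if (alternative == "two.sided") {
    tab <- matrix(c(n_expr_in, n_in - n_expr_in, n_expr_out,
                    n_out - n_expr_out), 2, 2)
    return(stats::fisher.test(tab, alternative = "two.sided")$p.value)
  }
  m <- n_expr_in + n_expr_out          # white balls (expressing cells)
  k <- n_in                            # draws (the cluster)
  min(1, stats::phyper(n_expr_in - 1, m, n_in + n_out - m, k,
                       lower.tail = FALSE))
}

#' Mean-expression fold-change of a gene in a cluster versus the rest
#'
#' Ratio of mean normalized expression in the cluster to the mean over
#' all other clustered cells, zeros included on both sides; a small
#' pseudocount keeps the ratio finite when the out-group mean is zero.
#'
#' @inheritParams expression_contingency
#' @param pseudocount added to both means (default 1e-9).
#' @return non-negative fold-change.
#' @export
fold_change <- function(norm, labels, cluster, gene, pseudocount = 1e-9) {
  gene <- toupper(gene)
  j <- match(gene, norm$gene_symbols)
  if (is.na(j)) stop("gene not in matrix: ", gene)
  v <- norm$values[, j]
  inn <- labels == cluster
  out <- labels != cluster & labels >= 0
  (mean(v[inn]) + pseudocount) / (mean(v[out]) + pseudocount)
}

#' Marker-calling thresholds
#'
#' The upregulated-gene criteria: Fisher p below `p_max`, expressing
#' fraction in the cluster above `prop_min`, and fold-change at least
#' `fc_min`. Defaults are the gene rule (p < 1e-6, > 25%, >= 2-fold); the
#' transcription-factor rule relaxes the expressing fraction to > 10%.
#'
#' @param p_max,prop_min,fc_min numeric thresholds.
#' @return named list.
#' @export
marker_thresholds <- function(p_max = 1e-6, prop_min = 0.25, fc_min = 2) {
  list(p_max = p_max, prop_min = prop_min, fc_min = fc_min)
}

#' Call cluster-specific upregulated genes or transcription factors
#'
#' Evaluates every (cluster, gene) pair — restricted to a transcription
#' factor list in `mode = "tf"` — computing expressing proportions in and
#' out of the cluster, the fold-change on normalized expression, and the
#' one-sided Fisher exact enrichment p-value, then flags markers by the
#' three-part rule (see [marker_thresholds()]). Noise cells are excluded
#' throughout. Rows are sorted by cluster, then descending fold-change.
#'
#' @param norm a `csa_norm` object.
#' @param labels integer cluster labels (or a `csa_clusters` object);
#'   at least 2 clusters required.
#' @param mode "gene" (all genes, > 25% rule) or "tf" (TF list, > 10%).
#' @param tf_list a [gene_set()] of transcription factors (required for
#'   `mode = "tf"`).
#' @param thresholds a [marker_thresholds()] list; default depends on
#'   `mode`.
#' @param pseudocount see [fold_change()].
#' @return data.frame of class `csa_marker_table` with columns cluster,
#'   gene, n_expr_in, n_in, n_expr_out, n_out, prop_in, prop_out,
#'   fold_change, p, is_marker, is_tf_marker.
#' @export
call_markers <- function(norm, labels, mode = c("gene", "tf"),
                         tf_list = NULL, thresholds = NULL,
                         pseudocount = 1e-9) {
  mode <- match.arg(mode)
  if (inherits(labels, "csa_clusters")) labels <- labels$labels
  stopifnot(length(labels) == nrow(norm$values))
  if (mode == "tf" && is.null(tf_list)) {
    stop("mode = 'tf' requires a tf_list gene set")
  }
  if (is.null(thresholds)) {
    thresholds <- if (mode == "tf") marker_thresholds(prop_min = 0.10)
                  else marker_thresholds()
  }
  clusters <- sort(unique(labels[labels >= 0]))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  genes <- norm$gene_symbols
  gidx <- seq_along(genes)
  if (mode == "tf") {
    gidx <- which(genes %in% tf_list$symbols)
    if (length(gidx) == 0) stop("no TF-list gene present in the matrix")
  }
  V <- norm$values[labels >= 0, gidx, drop = FALSE]
  lab <- labels[labels >= 0]
  E <- V > 0
  tot_expr <- colSums(E)
  tot_sum <- colSums(V)
  n_tot <- nrow(V)

  res <- lapply(clusters, function(cl) {
    inn <- lab == cl
    n_in <- sum(inn); n_out <- n_tot - n_in
    n_expr_in <- colSums(E[inn, , drop = FALSE])
    n_expr_out <- tot_expr - n_expr_in
    mean_in <- colSums(V[inn, , drop = FALSE]) / n_in
    mean_out <- (tot_sum - mean_in * n_in) / n_out
    fc <- (mean_in + pseudocount) / (mean_out + pseudocount)
    m <- n_expr_in + n_expr_out
    p <- pmin(1, stats::phyper(n_expr_in - 1, m, n_tot - m, n_in,
                               lower.tail = FALSE))
    data.frame(cluster = cl, gene = genes[gidx],
               n_expr_in = as.integer(n_expr_in), n_in = n_in,
               n_expr_out = as.integer(n_expr_out), n_out = n_out,
               prop_in = n_expr_in / n_in, prop_out = n_expr_out / n_out,
               fold_change = fc, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  pass <- tab$p < thresholds$p_max & tab$prop_in > thresholds$prop_min &
    tab$fold_change >= thresholds$fc_min
  tab$is_marker <- if (mode == "gene") pass else FALSE
  tab$is_tf_marker <- if (mode == "tf") pass else FALSE
  tab <- tab[order(tab$cluster, -tab$fold_change), ]
  rownames(tab) <- NULL
  class(tab) <- c("csa_marker_table", "data.frame")
  tab
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min_{j >= i} p(j) * m / j` on the sorted p-values, clipped at
#' 1 and mapped back to the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values in the input order.
#' @export
benjamini_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}
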