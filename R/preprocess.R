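#' Log-normalize UMI counts (library-size scaling then ln(1+x))
#'
#' The standard single-cell "LogNormalize" scheme: each cell's counts are
#' scaled to a common library size (`scale_factor`, default 10,000) and
#' then transformed as `ln(1 + count * scale_factor / total)`. Zero counts
#' map to exactly zero. Cells with zero total count are dropped with a
#' warning.
#'
#' @param counts a [count_matrix()] object.
#' @param scale_factor positive scalar, target library size.
#' @return object of class `csa_norm`: list(values, gene_symbols, cell_ids,
#'   metadata, scale_factor), values a cells x genes numeric matrix.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "csa_counts"), scale_factor > 0)
  m <- counts$counts
  if (any(m != round(m))) stop("counts must be integral")
  tot <- rowSums(m)
  keep <- tot > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d cell(s) with zero total count", sum(!keep)))
    m <- m[keep, , drop = FALSE]
    tot <- tot[keep]
  }
  vals <- log1p(m * (scale_factor / tot))
  meta <- counts$metadata
  if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
  structure(list(values = vals, gene_symbols = counts$gene_symbols,
                 cell_ids = counts$cell_ids[keep], metadata = meta,
                 scale_factor = scale_factor),
            class = "csa_norm")
}

#' @export
print.csa_norm <- function(x, ...) {
  cat(sprintf("csa_norm: %d cells x %d genes (scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Filter genes by total UMI count across all cells
#'
#' Keeps genes whose column sum over all cells is at least `min_total_umi`
#' (the boundary is inclusive). The cell set and gene order are unchanged.
#' The filter is intended to run on the full dataset before any cell
#' subsetting, mirroring a whole-dataset gene QC step.
#'
#' @param counts a [count_matrix()] object.
#' @param min_total_umi non-negative integer threshold (default 1000).
#' @return filtered [count_matrix()] object.
#' @export
filter_genes_by_umi <- function(counts, min_total_umi = 1000) {
  stopifnot(inherits(counts, "csa_counts"), min_total_umi >= 0)
  keep <- colSums(counts$counts) >= min_total_umi
  if (!any(keep)) stop("gene filter removed all genes (threshold ",
                       min_total_umi, ")")
  count_matrix(counts$counts[, keep, drop = FALSE],
               counts$gene_symbols[keep], counts$cell_ids, counts$metadata)
}

#' Restrict a matrix to the genes of a gene set
#'
#' Keeps the columns whose symbol is in the set, preserving the original
#' column order. Set symbols absent from the matrix are reported via a
#' message (count only). Works on both raw counts and normalized matrices.
#'
#' @param x a `csa_counts` or `csa_norm` object.
#' @param set a [gene_set()] object.
#' @return object of the same class restricted to the intersection.
#' @export
subset_to_gene_set <- function(x, set) {
  stopifnot(inherits(set, "csa_gene_set"))
  genes <- x$gene_symbols
  keep <- genes %in% set$symbols
  if (!any(keep)) stop("no gene of set '", set$name, "' is in the matrix")
  missing_n <- length(setdiff(set$symbols, genes))
  if (missing_n > 0) {
    message(sprintf("subset_to_gene_set: %d symbol(s) of '%s' absent from matrix",
                    missing_n, set$name))
  }
  if (inherits(x, "csa_counts")) {
    count_matrix(x$counts[, keep, drop = FALSE], genes[keep], x$cell_ids,
                 x$metadata)
  } else if (inherits(x, "csa_norm")) {
    out <- x
    out$values <- x$values[, keep, drop = FALSE]
    out$gene_symbols <- genes[keep]
    out
  } else stop("unsupported object class")
}
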