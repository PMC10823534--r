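#' @importFrom Matrix readMM writeMM
#' @importFrom utils read.delim write.table
NULL

# Tokens accepted in per-cell metadata. The study design has five injury
# groups and seven sampling timepoints (embryonic day 80 through P56).
.valid_groups <- c("fetal", "CTL", "AR_P1", "MI_P28", "AR_P1_MI_P28")
.valid_timepoints <- c("E80", "P1", "P28", "P30", "P35", "P42", "P56")

#' Construct a validated cell-by-gene UMI count matrix
#'
#' `count_matrix` is the container every pipeline stage consumes: a dense
#' non-negative integer matrix of UMI counts (cells in rows, genes in
#' columns) plus per-cell metadata with the injury group and timepoint of
#' each cell.
#'
#' @param counts numeric matrix, cells x genes, non-negative integers.
#' @param gene_symbols character vector of unique gene symbols (case-folded
#'   to uppercase).
#' @param cell_ids character vector of unique cell identifiers.
#' @param metadata data.frame with columns `cell_id`, `group`, `timepoint`,
#'   keyed 1:1 to `cell_ids`. Cells without metadata are dropped with a
#'   warning; unknown group/timepoint tokens are an error.
#' @return an object of class `csa_counts` with elements `counts`,
#'   `gene_symbols`, `cell_ids`, `metadata`.
#' @export
count_matrix <- function(counts, gene_symbols, cell_ids, metadata = NULL) {
  counts <- as.matrix(counts)
  gene_symbols <- toupper(as.character(gene_symbols))
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(cell_ids)) {
    stop(sprintf("count matrix has %d rows but %d cell ids",
                 nrow(counts), length(cell_ids)))
  }
  if (ncol(counts) != length(gene_symbols)) {
    stop(sprintf("count matrix has %d columns but %d gene symbols",
                 ncol(counts), length(gene_symbols)))
  }
  dup <- unique(gene_symbols[duplicated(gene_symbols)])
  if (length(dup) > 0) {
    stop("duplicate gene symbols: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) stop("cell ids are not unique")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(cell_ids, gene_symbols)

  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
    need <- c("cell_id", "group", "timepoint")
    if (!all(need %in% names(metadata))) {
      stop("metadata must have columns: ", paste(need, collapse = ", "))
    }
    bad_g <- setdiff(unique(metadata$group), .valid_groups)
    if (length(bad_g) > 0) stop("unknown group token(s): ",
                                paste(bad_g, collapse = ", "))
    bad_t <- setdiff(unique(metadata$timepoint), .valid_timepoints)
    if (length(bad_t) > 0) stop("unknown timepoint token(s): ",
                                paste(bad_t, collapse = ", "))
    keep <- cell_ids %in% metadata$cell_id
    if (!all(keep)) {
      warning(sprintf("dropping %d cell(s) without metadata", sum(!keep)))
      counts <- counts[keep, , drop = FALSE]
      cell_ids <- cell_ids[keep]
    }
    metadata <- metadata[match(cell_ids, metadata$cell_id), need,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }

  structure(list(counts = counts, gene_symbols = gene_symbols,
                 cell_ids = cell_ids, metadata = metadata),
            class = "csa_counts")
}

#' @export
print.csa_counts <- function(x, ...) {
  cat(sprintf("csa_counts: %d cells x %d genes (%.0f total UMIs)\n",
              length(x$cell_ids), length(x$gene_symbols), sum(x$counts)))
  if (!is.null(x$metadata)) {
    tab <- table(x$metadata$group, x$metadata$timepoint)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    print(tab)
  }
  invisible(x)
}

#' Read a Matrix Market count matrix with gene/barcode/metadata sidecars
#'
#' Reads coordinate-format Matrix Market counts plus one-entry-per-line
#' gene and barcode files. On-disk orientation (genes x cells or
#' cells x genes) is auto-detected from the matrix dimensions against the
#' lengths of the two lists, and output is always cells x genes.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param genes_path,barcodes_path one symbol / one barcode per line.
#' @param metadata_path optional TSV/CSV with header columns
#'   `cell_id`, `group`, `timepoint` (separator auto-detected).
#' @return a [count_matrix()] object.
#' @export
read_counts_mtx <- function(matrix_path, genes_path, barcodes_path,
                            metadata_path = NULL) {
  m <- as.matrix(Matrix::readMM(matrix_path))
  genes <- .read_lines_clean(genes_path)
  barcodes <- .read_lines_clean(barcodes_path)
  ng <- length(genes); nb <- length(barcodes)
  if (nrow(m) == nb && ncol(m) == ng) {
    # already cells x genes
  } else if (nrow(m) == ng && ncol(m) == nb) {
    m <- t(m)
  } else {
    stop(sprintf(paste0("matrix is %d x %d but there are %d barcodes and ",
                        "%d genes; neither orientation matches"),
                 nrow(m), ncol(m), nb, ng))
  }
  meta <- NULL
  if (!is.null(metadata_path)) meta <- .read_metadata(metadata_path)
  count_matrix(m, genes, barcodes, meta)
}

.read_lines_clean <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

.read_metadata <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' Write a count matrix as Matrix Market plus sidecar files
#'
#' Inverse of [read_counts_mtx()]; writes `matrix.mtx`, `genes.txt`,
#' `barcodes.txt` and (when metadata is present) `metadata.tsv` under
#' `dir`. Counts round-trip bit-identically.
#'
#' @param x a [count_matrix()] object.
#' @param dir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "csa_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.txt"),
             barcodes = file.path(dir, "barcodes.txt"))
  sp <- methods::as(Matrix::Matrix(x$counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, paths[["matrix"]])
  writeLines(x$gene_symbols, paths[["genes"]])
  writeLines(x$cell_ids, paths[["barcodes"]])
  if (!is.null(x$metadata)) {
    paths <- c(paths, metadata = file.path(dir, "metadata.tsv"))
    utils::write.table(x$metadata, paths[["metadata"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a plain-text gene list into a gene set
#'
#' One symbol per line; lines starting with `#` and blank lines are
#' skipped; symbols are uppercased and de-duplicated (the set is
#' order-free). Errors if nothing remains.
#'
#' @param path text file, one gene symbol per line.
#' @param name name for the set (default: file base name).
#' @return object of class `csa_gene_set`: list(name, symbols).
#' @export
read_gene_list <- function(path, name = NULL) {
  syms <- .read_lines_clean(path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_set(unique(toupper(syms)), name = name)
}

#' Construct a gene set from symbols
#' @param symbols character vector of gene symbols.
#' @param name set name.
#' @return object of class `csa_gene_set`.
#' @export
gene_set <- function(symbols, name = "gene_set") {
  symbols <- unique(toupper(as.character(symbols)))
  symbols <- symbols[nzchar(symbols)]
  if (length(symbols) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = name, symbols = symbols), class = "csa_gene_set")
}

#' Write a result table to TSV/CSV
#'
#' Writes any result table (marker table, proportion table, image metrics)
#' with a header row. Numeric columns keep 15 significant digits so that a
#' write/read round trip preserves values to better than 1e-9 relative;
#' p-value columns (named `p` or ending in `_p`/`p_value`/`q`) are written
#' in scientific notation.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param format "tsv" or "csv".
#' @return invisibly, `path`.
#' @export
write_table <- function(table, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (!is.numeric(out[[j]])) next
    nm <- names(out)[j]
    sci <- nm == "p" || nm == "q" || grepl("(_p|p_value|_q)$", nm)
    out[[j]] <- vapply(out[[j]], function(v) {
      if (is.na(v)) return("NA")
      format(v, digits = 15, scientific = sci, trim = TRUE)
    }, character(1))
  }
  ok <- try(utils::write.table(out, path, sep = if (format == "tsv") "\t"
                               else ",", quote = FALSE, row.names = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write table to ", path)
  invisible(path)
}
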