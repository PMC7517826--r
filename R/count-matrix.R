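#' Construct a CountMatrix
#'
#' The package's container for gene-by-cell UMI counts. Per-cell QC metadata
#' (`nUMI`, `nGene`, `mito_frac`) is always derived from the counts so it can
#' never drift out of sync; extra metadata columns (patient, cluster or type
#' labels) are joined by barcode.
#'
#' @param counts gene x cell matrix of non-negative integer counts (dense or
#'   any Matrix sparse class; stored as `dgCMatrix`)
#' @param gene_ids character vector of unique gene identifiers (rows)
#' @param cell_barcodes character vector of unique cell barcodes (columns)
#' @param cell_meta optional data.frame keyed by a `barcode` column carrying
#'   e.g. `patient_id`, cluster or type labels
#' @param mito_prefix gene-id prefix identifying mitochondria-encoded genes
#'   (default `"MT-"`), used to derive `mito_frac`
#' @return an object of class `CountMatrix`
#' @export
CountMatrix <- function(counts, gene_ids, cell_barcodes, cell_meta = NULL,
                        mito_prefix = "MT-") {
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(gene_ids))
    aml_stop("gene_ids length does not match matrix rows")
  if (ncol(counts) != length(cell_barcodes))
    aml_stop("cell_barcodes length does not match matrix columns")
  if (anyDuplicated(gene_ids)) aml_stop("duplicate gene ids")
  if (anyDuplicated(cell_barcodes)) aml_stop("duplicate cell barcodes")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    aml_stop("counts must be non-negative integers")
  dimnames(counts) <- list(gene_ids, cell_barcodes)

  nUMI <- Matrix::colSums(counts)
  nGene <- Matrix::colSums(counts > 0)
  mito <- startsWith(gene_ids, mito_prefix)
  mito_frac <- rep(0, ncol(counts))
  pos <- nUMI > 0
  if (any(mito)) {
    mito_counts <- Matrix::colSums(counts[mito, , drop = FALSE])
    mito_frac[pos] <- mito_counts[pos] / nUMI[pos]
  }
  meta <- data.frame(barcode = cell_barcodes, nUMI = as.numeric(nUMI),
                     nGene = as.integer(nGene), mito_frac = mito_frac,
                     stringsAsFactors = FALSE)
  if (!is.null(cell_meta)) {
    stopifnot(is.data.frame(cell_meta), "barcode" %in% names(cell_meta))
    extra <- cell_meta[, setdiff(names(cell_meta),
                                 c("nUMI", "nGene", "mito_frac")), drop = FALSE]
    meta <- merge(meta, extra, by = "barcode", all.x = TRUE, sort = FALSE)
    meta <- meta[match(cell_barcodes, meta$barcode), , drop = FALSE]
  }
  rownames(meta) <- NULL
  structure(list(counts = counts, gene_ids = gene_ids,
                 cell_barcodes = cell_barcodes, cell_meta = meta,
                 mito_prefix = mito_prefix),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%.0f UMIs)\n",
              nrow(x$counts), ncol(x$counts), sum(x$cell_meta$nUMI)))
  extra <- setdiff(names(x$cell_meta), c("barcode", "nUMI", "nGene", "mito_frac"))
  if (length(extra)) cat("metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by cells (and optionally genes)
#'
#' Metadata is re-derived for the retained cells.
#'
#' @param cm CountMatrix
#' @param cells logical/integer/character index over cells
#' @param genes optional index over genes
#' @return CountMatrix
#' @export
subset_cells <- function(cm, cells, genes = NULL) {
  stopifnot(is(cm, "CountMatrix"))
  if (is.null(genes)) genes <- seq_len(nrow(cm$counts))
  sub <- cm$counts[genes, cells, drop = FALSE]
  CountMatrix(sub, rownames(sub), colnames(sub),
              cell_meta = cm$cell_meta, mito_prefix = cm$mito_prefix)
}

#' Read a MatrixMarket UMI count matrix
#'
#' Reads the conventional MTX + genes.tsv + barcodes.tsv triplet (1-based MTX
#' coordinates per the MatrixMarket standard) and derives per-cell QC metadata.
#'
#' @param mtx_path path to the MatrixMarket file (genes x cells)
#' @param genes_path one gene id per line (first column if multi-column TSV)
#' @param barcodes_path one cell barcode per line
#' @param meta_path optional CSV/TSV of per-cell metadata with a `barcode` column
#' @param mito_prefix gene-id prefix for mitochondrial genes
#' @return CountMatrix
#' @export
read_counts <- function(mtx_path, genes_path, barcodes_path, meta_path = NULL,
                        mito_prefix = "MT-") {
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) aml_stop("invalid MTX file: ", conditionMessage(e)))
  genes <- read.delim(genes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes))
    aml_stop(sprintf("MTX has %d rows but genes file has %d entries",
                     nrow(m), length(genes)))
  if (ncol(m) != length(barcodes))
    aml_stop(sprintf("MTX has %d columns but barcodes file has %d entries",
                     ncol(m), length(barcodes)))
  meta <- NULL
  if (!is.null(meta_path)) {
    sep <- if (grepl("\\.csv$", meta_path)) "," else "\t"
    meta <- read.delim(meta_path, sep = sep, stringsAsFactors = FALSE)
  }
  cm <- CountMatrix(m, genes, barcodes, cell_meta = meta, mito_prefix = mito_prefix)
  aml_log("read_counts", sprintf("%d genes x %d cells from %s",
                                 nrow(m), ncol(m), mtx_path))
  cm
}

#' Write a CountMatrix as MTX + TSV triplet (plus metadata CSV)
#'
#' @param cm CountMatrix
#' @param dir output directory (created if absent)
#' @param prefix file-name prefix
#' @return invisibly, the paths written
#' @export
write_counts <- function(cm, dir, prefix = "counts") {
  stopifnot(is(cm, "CountMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.tsv",
                                           "_barcodes.tsv", "_meta.csv")))
  Matrix::writeMM(cm$counts, paths[1])
  writeLines(cm$gene_ids, paths[2])
  writeLines(cm$cell_barcodes, paths[3])
  write.table(cm$cell_meta, paths[4], sep = ",", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Construct an undirected edge table
#'
#' Canonical storage for all network outputs: one row per undirected edge, no
#' self-edges, `node_a < node_b` lexically so each edge is stored once.
#'
#' @param node_a,node_b character endpoints
#' @param weight numeric edge weight in `[-1, 1]` (correlation-type scores)
#' @param namespace label for the node namespace (e.g. "pseudocell", "gene")
#' @return data.frame of class `EdgeTable`
#' @export
edge_table <- function(node_a = character(), node_b = character(),
                       weight = numeric(), namespace = "node") {
  stopifnot(length(node_a) == length(node_b), length(node_a) == length(weight))
  keep <- node_a != node_b
  if (any(!keep)) aml_warn(sum(!keep), " self-edges dropped")
  node_a <- node_a[keep]; node_b <- node_b[keep]; weight <- weight[keep]
  swap <- node_a > node_b
  tmp <- node_a[swap]; node_a[swap] <- node_b[swap]; node_b[swap] <- tmp
  df <- data.frame(node_a = node_a, node_b = node_b, weight = weight,
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$node_a, df$node_b), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "namespace") <- namespace
  class(df) <- c("EdgeTable", "data.frame")
  df
}

#' Write / read an EdgeTable as TSV
#'
#' @param et EdgeTable
#' @param path TSV path
#' @return `read_edge_table` returns an EdgeTable; `write_edge_table` its path
#' @export
write_edge_table <- function(et, path) {
  write.table(as.data.frame(et), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @param namespace node namespace label to attach on read
#' @export
read_edge_table <- function(path, namespace = "node") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  edge_table(df$node_a, df$node_b, df$weight, namespace = namespace)
}
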