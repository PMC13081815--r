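#' Single-cell UMI count matrix container
#'
#' Constructs a `count_matrix`, the raw substrate of the single-cell pipeline:
#' a sparse cells x genes matrix of non-negative integer UMI counts together
#' with unique cell barcodes, unique gene identifiers and a per-cell metadata
#' table of categorical labels.
#'
#' @param counts matrix or `Matrix::sparseMatrix` of non-negative integers,
#'   cells in rows, genes in columns.
#' @param cell_ids character vector of unique cell barcodes (defaults to
#'   rownames of `counts`).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   colnames of `counts`).
#' @param cell_meta data.frame of per-cell categorical labels; must contain a
#'   `sample_id` column. A single-sample placeholder is created if omitted.
#' @return An object of class `count_matrix` with elements `counts`
#'   (`dgCMatrix`), `cell_ids`, `gene_ids`, `cell_meta`.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), cell_meta = NULL) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integer-valued")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts))
    stop("length(cell_ids) must equal the number of cells (rows): got ",
         length(cell_ids), " ids for ", nrow(counts), " cells")
  if (length(gene_ids) != ncol(counts))
    stop("length(gene_ids) must equal the number of genes (columns): got ",
         length(gene_ids), " ids for ", ncol(counts), " genes")
  if (anyDuplicated(cell_ids)) stop("duplicated cell barcodes")
  if (anyDuplicated(gene_ids)) stop("duplicated gene identifiers")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(sample_id = rep("sample1", length(cell_ids)),
                            stringsAsFactors = FALSE)
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (nrow(cell_meta) != length(cell_ids))
    stop("cell_meta must have one row per cell")
  if (!"sample_id" %in% names(cell_meta))
    stop("cell_meta must contain a sample_id column")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  cat("  nonzero entries:", length(x$counts@x), "\n")
  cat("  samples:", length(unique(x$cell_meta$sample_id)), "\n")
  fr <- attr(x, "filter_report")
  if (!is.null(fr)) cat("  QC-filtered (see attr(., 'filter_report'))\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

.first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("missing file: none of ", paste(names, collapse = ", "),
       " found in ", dir)
}

.read_id_column <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  as.character(x[[1]])
}

#' Read a UMI count matrix
#'
#' Reads 10x-style Matrix Market triplet directories, 10x-style HDF5
#' feature-barcode matrices, or dense TSV. Matrix Market and HDF5 store
#' features (genes) as rows; the result is always returned in cells x genes
#' orientation. Gzipped `matrix.mtx.gz` / `barcodes.tsv.gz` / `features.tsv.gz`
#' are read transparently.
#'
#' @param path directory (`mtx_dir`) or file (`h5`, `dense_tsv`).
#' @param format one of `"mtx_dir"`, `"h5"`, `"dense_tsv"`.
#' @param cell_meta optional per-cell metadata data.frame or path to a TSV/CSV
#'   whose first column is the cell barcode.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, format = c("mtx_dir", "h5", "dense_tsv"),
                        cell_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("missing file: ", path)
  m <- switch(format,
    mtx_dir = .read_counts_mtx(path),
    h5 = .read_counts_h5(path),
    dense_tsv = .read_counts_dense(path)
  )
  if (!is.null(cell_meta)) {
    if (is.character(cell_meta)) cell_meta <- read_cell_meta(cell_meta)
    idx <- match(m$cell_ids, rownames(cell_meta))
    if (anyNA(idx))
      stop("metadata missing for barcodes: ",
           paste(utils::head(m$cell_ids[is.na(idx)], 5), collapse = ", "))
    meta <- cell_meta[idx, , drop = FALSE]
    rownames(meta) <- NULL
    m <- count_matrix(m$counts, m$cell_ids, m$gene_ids, meta)
  }
  m
}

.read_counts_mtx <- function(dir) {
  mtx <- .first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  bc <- .first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  ft <- .first_existing(dir, c("features.tsv", "features.tsv.gz",
                               "genes.tsv", "genes.tsv.gz"))
  x <- Matrix::readMM(mtx)  # features x barcodes on disk
  barcodes <- .read_id_column(bc)
  features <- .read_id_column(ft)
  if (length(features) != nrow(x))
    stop("format error: features file has ", length(features),
         " entries but matrix declares ", nrow(x), " rows")
  if (length(barcodes) != ncol(x))
    stop("format error: barcodes file has ", length(barcodes),
         " entries but matrix declares ", ncol(x), " columns")
  if (any(x@x != round(x@x))) stop("format error: non-integer entries")
  count_matrix(Matrix::t(x), barcodes, features)
}

.read_counts_dense <- function(path) {
  # cells as rows, header = gene ids, first column = barcode
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  barcodes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("format error: non-numeric entries")
  if (any(vals != round(vals))) stop("format error: non-integer entries")
  count_matrix(vals, barcodes, colnames(vals))
}

.read_counts_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading HDF5 requires the rhdf5 package")
  data <- rhdf5::h5read(path, "matrix/data")
  indices <- rhdf5::h5read(path, "matrix/indices")
  indptr <- rhdf5::h5read(path, "matrix/indptr")
  shape <- rhdf5::h5read(path, "matrix/shape")  # genes, cells
  barcodes <- as.character(rhdf5::h5read(path, "matrix/barcodes"))
  features <- as.character(rhdf5::h5read(path, "matrix/features/id"))
  rhdf5::h5closeAll()
  x <- Matrix::sparseMatrix(i = as.integer(indices) + 1L,
                            p = as.numeric(indptr), x = as.numeric(data),
                            dims = as.integer(shape))
  if (length(features) != nrow(x) || length(barcodes) != ncol(x))
    stop("format error: id datasets do not match declared shape")
  count_matrix(Matrix::t(x), barcodes, features)
}

#' Write a UMI count matrix
#'
#' Inverse of [read_counts()] for all three supported formats; round-trips are
#' bit-exact on integer counts.
#'
#' @param m a [count_matrix].
#' @param path output directory (`mtx_dir`) or file (`h5`, `dense_tsv`).
#' @param format one of `"mtx_dir"`, `"h5"`, `"dense_tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx_dir", "h5", "dense_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "count_matrix"))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    x <- Matrix::t(m$counts)  # features x barcodes on disk
    Matrix::writeMM(x, file.path(path, "matrix.mtx"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    writeLines(m$gene_ids, file.path(path, "features.tsv"))
  } else if (format == "dense_tsv") {
    dense <- as.matrix(m$counts)
    tab <- data.frame(barcode = m$cell_ids, dense, check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(tab) <- c("barcode", m$gene_ids)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("writing HDF5 requires the rhdf5 package")
    x <- Matrix::t(m$counts)  # genes x cells, CSC
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "matrix")
    rhdf5::h5createGroup(path, "matrix/features")
    rhdf5::h5write(x@x, path, "matrix/data")
    rhdf5::h5write(x@i, path, "matrix/indices")
    rhdf5::h5write(x@p, path, "matrix/indptr")
    rhdf5::h5write(dim(x), path, "matrix/shape")
    rhdf5::h5write(m$cell_ids, path, "matrix/barcodes")
    rhdf5::h5write(m$gene_ids, path, "matrix/features/id")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Read per-cell or per-sample metadata
#'
#' First column is the barcode (or sample id) and becomes the rownames;
#' remaining columns are categorical labels. Delimiter is inferred from the
#' file extension (`.csv` = comma, otherwise tab).
#'
#' @param path TSV or CSV file.
#' @return data.frame of labels with barcodes as rownames.
#' @export
read_cell_meta <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicated ids in metadata")
  meta <- tab[, -1, drop = FALSE]
  rownames(meta) <- ids
  meta
}

#' Quality-control thresholds
#'
#' Cells are retained if they express between `min_genes` and `max_genes`
#' genes (inclusive) and have at least `min_counts` total UMIs; genes expressed
#' in fewer than `min_cells_per_gene` of the retained cells are then dropped.
#' "Expressed" means count strictly greater than zero.
#'
#' @param min_genes,max_genes inclusive bounds on genes expressed per cell.
#' @param min_counts minimum total UMI count per cell.
#' @param min_cells_per_gene minimum number of retained cells expressing a
#'   gene.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 4000L,
                          min_counts = 300L, min_cells_per_gene = 10L) {
  stopifnot(min_genes > 0, min_genes <= max_genes,
            min_counts >= 0, min_cells_per_gene >= 0)
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 min_counts = as.integer(min_counts),
                 min_cells_per_gene = as.integer(min_cells_per_gene)),
            class = "qc_thresholds")
}

#' Apply quality-control filters to a count matrix
#'
#' Cell filters are applied first (genes-expressed range and minimum total
#' counts, all bounds inclusive); the gene filter is then computed on the
#' cell-filtered matrix, pooled across all samples. The filtering is
#' idempotent. A `filter_report` attribute records what was removed at each
#' step.
#'
#' @param m a [count_matrix].
#' @param thresholds a [qc_thresholds].
#' @param per_sample if `TRUE`, the gene filter requires `min_cells_per_gene`
#'   expressing cells within every sample rather than pooled across samples.
#' @return The filtered [count_matrix] with a `filter_report` attribute.
#' @export
qc_filter <- function(m, thresholds = qc_thresholds(), per_sample = FALSE) {
  stopifnot(inherits(m, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  t <- thresholds
  x <- m$counts
  genes_per_cell <- Matrix::rowSums(x > 0)
  counts_per_cell <- Matrix::rowSums(x)
  keep_range <- genes_per_cell >= t$min_genes & genes_per_cell <= t$max_genes
  keep_counts <- counts_per_cell >= t$min_counts
  keep_cell <- keep_range & keep_counts
  if (!any(keep_cell)) stop("empty after QC: no cells survive the cell filters")
  xf <- x[keep_cell, , drop = FALSE]
  meta <- m$cell_meta[keep_cell, , drop = FALSE]
  if (per_sample) {
    keep_gene <- rep(TRUE, ncol(xf))
    for (s in unique(meta$sample_id)) {
      xs <- xf[meta$sample_id == s, , drop = FALSE]
      keep_gene <- keep_gene &
        Matrix::colSums(xs > 0) >= t$min_cells_per_gene
    }
  } else {
    keep_gene <- Matrix::colSums(xf > 0) >= t$min_cells_per_gene
  }
  if (!any(keep_gene)) stop("empty after QC: no genes survive the gene filter")
  out <- count_matrix(xf[, keep_gene, drop = FALSE],
                      m$cell_ids[keep_cell], m$gene_ids[keep_gene], meta)
  attr(out, "filter_report") <- list(
    thresholds = unclass(t),
    gene_filter = if (per_sample) "per_sample" else "pooled",
    order = c("cell_gene_range", "cell_min_counts", "gene_min_cells"),
    cells_in = nrow(x),
    cells_removed_gene_range = sum(!keep_range),
    cells_removed_min_counts = sum(keep_range & !keep_counts),
    cells_out = sum(keep_cell),
    genes_in = ncol(x),
    genes_removed = sum(!keep_gene),
    genes_out = sum(keep_gene)
  )
  out
}

#' Log-normalize a count matrix
#'
#' Scales each cell to `target_sum` total counts and applies the natural
#' logarithm of one plus the scaled count:
#' `value[i, g] = ln(1 + target_sum * counts[i, g] / total_i)`.
#'
#' @param m a [count_matrix] (after QC; cells with zero totals are an error).
#' @param target_sum per-cell total after scaling (default 10,000).
#' @return Object of class `normalized_matrix` with elements `values` (sparse
#'   cells x genes), `target_sum`, `log_base = "natural"`, `cell_meta`, and a
#'   `provenance` record of the filters applied.
#' @export
normalize_log <- function(m, target_sum = 10000) {
  stopifnot(inherits(m, "count_matrix"), target_sum > 0)
  totals <- Matrix::rowSums(m$counts)
  if (any(totals == 0))
    stop("cell with zero total counts; run qc_filter first")
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% m$counts
  values <- scaled
  values@x <- log1p(values@x)
  dimnames(values) <- list(m$cell_ids, m$gene_ids)
  structure(list(values = as(values, "CsparseMatrix"),
                 target_sum = target_sum,
                 log_base = "natural",
                 cell_meta = m$cell_meta,
                 provenance = attr(m, "filter_report")),
            class = "normalized_matrix")
}

#' @exportS3Method base::print
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "cells x", ncol(x$values),
      "genes (ln(1 + x), target_sum =", x$target_sum, ")\n")
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

#' Read a bulk RNA-seq count table with its condition design
#'
#' @param path TSV of counts, genes in rows (first column gene id), samples in
#'   columns.
#' @param design_path TSV mapping sample to condition factors; first column is
#'   the sample id. Typical columns: `heat` and `salt` with values `-`/`+`,
#'   optionally `strain` and `replicate`.
#' @return Object of class `bulk_counts` with `counts` (genes x samples
#'   matrix) and `sample_design` (data.frame, one row per sample column).
#' @export
read_bulk <- function(path, design_path) {
  if (!file.exists(path)) stop("missing file: ", path)
  if (!file.exists(design_path)) stop("missing file: ", design_path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    stop("format error: duplicated gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- genes
  if (any(counts < 0)) stop("format error: negative counts")
  design <- utils::read.delim(design_path, header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE)
  sample_ids <- as.character(design[[1]])
  design <- design[, -1, drop = FALSE]
  rownames(design) <- sample_ids
  missing <- setdiff(colnames(counts), sample_ids)
  if (length(missing) > 0)
    stop("samples in counts absent from design: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(sample_ids, colnames(counts))
  if (length(extra) > 0)
    warning("design contains unused sample(s): ",
            paste(extra, collapse = ", "))
  bulk_counts(counts, design[colnames(counts), , drop = FALSE])
}

#' Bulk count container
#'
#' @param counts non-negative genes x samples matrix with gene rownames.
#' @param sample_design data.frame of condition factors, rownames = sample
#'   ids, one row per counts column.
#' @return Object of class `bulk_counts`.
#' @export
bulk_counts <- function(counts, sample_design) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids")
  sample_design <- as.data.frame(sample_design, stringsAsFactors = FALSE)
  if (!all(colnames(counts) %in% rownames(sample_design)))
    stop("every sample must appear in sample_design")
  structure(list(counts = counts,
                 sample_design = sample_design[colnames(counts), ,
                                               drop = FALSE]),
            class = "bulk_counts")
}

#' @exportS3Method base::print
print.bulk_counts <- function(x, ...) {
  cat("bulk_counts:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  print(x$sample_design)
  invisible(x)
}
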