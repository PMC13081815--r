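test_that("matrix market triplets are transposed to cells x genes on read", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "2 2 1"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
  m <- read_counts(dir, "mtx_dir")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(as.numeric(m$counts["c1", "gA"]), 5)
  expect_equal(as.numeric(m$counts["c2", "gB"]), 1)
  expect_equal(sum(m$counts), 6)
})

test_that("empty triplet preserves declared shape as zeros", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
  m <- read_counts(dir, "mtx_dir")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(sum(m$counts), 0)
})

test_that("mismatched id files raise a format error naming the problem", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "1 1 5"), file.path(dir, "matrix.mtx"))
  writeLines(c("c1", "c2", "c3"), file.path(dir, "barcodes.tsv"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
  expect_error(read_counts(dir, "mtx_dir"), "barcodes")
  expect_error(read_counts(file.path(dir, "nope"), "mtx_dir"), "missing")
})

test_that("count matrices round-trip bit-exactly through all three formats", {
  set.seed(7)
  m <- make_cm(matrix(rpois(15 * 8, 2), 15, 8))
  for (fmt in c("mtx_dir", "dense_tsv", "h5")) {
    path <- if (fmt == "mtx_dir") withr::local_tempdir() else
      withr::local_tempfile(fileext = if (fmt == "h5") ".h5" else ".tsv")
    write_counts(m, path, fmt)
    m2 <- read_counts(path, fmt)
    expect_identical(as.matrix(m2$counts), as.matrix(m$counts),
                     label = fmt)
    expect_identical(m2$cell_ids, m$cell_ids)
    expect_identical(m2$gene_ids, m$gene_ids)
  }
})

test_that("count_matrix enforces its invariants", {
  expect_error(make_cm(matrix(-1, 2, 2)), "non-negative")
  expect_error(make_cm(matrix(0.5, 2, 2)), "integer")
  expect_error(count_matrix(matrix(0, 2, 2), cell_ids = c("a", "a"),
                            gene_ids = c("g1", "g2")), "duplicated")
  expect_error(count_matrix(matrix(0, 2, 2), cell_ids = "a",
                            gene_ids = c("g1", "g2")), "cell_ids")
})

test_that("the committed QC fixture reduces to the hand-derived shape", {
  m <- read_counts(qc_fixture_path(), "dense_tsv")
  expect_equal(dim(m), c(6L, 12L))
  f <- qc_filter(m, qc_fixture_thresholds())
  expect_equal(dim(f), c(3L, 7L))
  expect_identical(f$cell_ids, c("c1", "c2", "c5"))
  expect_identical(f$gene_ids, paste0("g0", 1:7))
  rep <- attr(f, "filter_report")
  expect_equal(rep$cells_removed_gene_range, 2)   # c3 (7 genes), c4 (2)
  expect_equal(rep$cells_removed_min_counts, 1)   # c6 (9 UMIs)
  expect_equal(rep$genes_removed, 5)
})

test_that("cell thresholds are inclusive at both boundaries", {
  # one cell with exactly 200 expressed genes and exactly 300 UMIs, one with
  # 4001 expressed genes, one comfortable cell to avoid an empty result
  n_genes <- 4100
  i <- c(rep(1, 200), rep(2, 4001), rep(3, 500))
  j <- c(1:200, 1:4001, 1:500)
  x <- c(c(rep(2, 100), rep(1, 100)), rep(1, 4001), rep(2, 500))
  counts <- Matrix::sparseMatrix(i = i, j = j, x = x,
                                 dims = c(3, n_genes))
  m <- count_matrix(counts, cell_ids = c("boundary", "too_many", "ok"),
                    gene_ids = sprintf("g%04d", 1:n_genes))
  f <- qc_filter(m, qc_thresholds(min_genes = 200, max_genes = 4000,
                                  min_counts = 300, min_cells_per_gene = 1))
  expect_true("boundary" %in% f$cell_ids)    # 200 genes, 300 UMIs kept
  expect_false("too_many" %in% f$cell_ids)   # 4001 genes removed
})

test_that("qc_filter is idempotent and its output violates no threshold", {
  set.seed(11)
  for (rep in 1:5) {
    m <- make_cm(matrix(rpois(40 * 30, 0.8), 40, 30))
    t <- qc_thresholds(min_genes = 3, max_genes = 25, min_counts = 5,
                       min_cells_per_gene = 3)
    f1 <- qc_filter(m, t)
    f2 <- qc_filter(f1, t)
    expect_identical(as.matrix(f2$counts), as.matrix(f1$counts))
    gpc <- Matrix::rowSums(f1$counts > 0)
    expect_true(all(gpc >= 3 & gpc <= 25))
    expect_true(all(Matrix::rowSums(f1$counts) >= 5))
    expect_true(all(Matrix::colSums(f1$counts > 0) >= 3))
  }
})

test_that("empty QC results raise an explicit error", {
  m <- make_cm(matrix(1L, 2, 2))
  expect_error(qc_filter(m, qc_thresholds(min_genes = 10, max_genes = 20,
                                          min_counts = 0,
                                          min_cells_per_gene = 0)),
               "empty after QC")
})

test_that("normalize_log applies ln(1 + target_sum * count / total)", {
  counts <- matrix(0, 2, 3)
  counts[1, ] <- c(5, 4995, 0)      # total 5000
  counts[2, ] <- c(10000, 0, 0)     # total exactly target_sum
  m <- make_cm(counts)
  nm <- normalize_log(m)
  expect_equal(nm$values[1, 1], log(11), tolerance = 1e-12) # 5/5000*1e4 = 10
  expect_equal(nm$values[1, 3], 0)                          # zero stays zero
  expect_equal(nm$values[2, 1], log(1 + 10000))             # identity case
  expect_identical(nm$log_base, "natural")
})

test_that("normalization satisfies the row-sum invariant and round-trips", {
  set.seed(3)
  m <- make_cm(matrix(rpois(20 * 15, 3) + 1, 20, 15))
  nm <- normalize_log(m, target_sum = 10000)
  rows <- unname(rowSums(expm1(as.matrix(nm$values))))
  expect_equal(rows, rep(10000, 20), tolerance = 1e-6)
  # exp - 1, row-normalize recovers counts / total
  rec <- expm1(as.matrix(nm$values))
  rec <- rec / rowSums(rec)
  orig <- as.matrix(m$counts) / rowSums(as.matrix(m$counts))
  expect_equal(rec, orig, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("normalize_log refuses cells with zero totals", {
  m <- make_cm(rbind(c(1, 2), c(0, 0)))
  expect_error(normalize_log(m), "zero total")
})

test_that("bulk counts load with their design and report mismatches", {
  dir <- withr::local_tempdir()
  counts <- data.frame(gene = c("gA", "gB"), s1 = c(1, 2), s2 = c(3, 4),
                       s3 = c(5, 6), s4 = c(7, 8))
  write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  design <- data.frame(sample = paste0("s", 1:4),
                       heat = c("-", "+", "-", "+"),
                       salt = c("-", "-", "+", "+"))
  write.table(design, file.path(dir, "design.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  b <- read_bulk(file.path(dir, "counts.tsv"), file.path(dir, "design.tsv"))
  expect_equal(dim(b$counts), c(2L, 4L))
  expect_identical(rownames(b$sample_design), colnames(b$counts))

  design5 <- rbind(design, data.frame(sample = "s9", heat = "-", salt = "-"))
  write.table(design5, file.path(dir, "design5.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_warning(read_bulk(file.path(dir, "counts.tsv"),
                           file.path(dir, "design5.tsv")), "unused")

  dup <- counts; dup$gene <- c("gA", "gA")
  write.table(dup, file.path(dir, "dup.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_bulk(file.path(dir, "dup.tsv"),
                         file.path(dir, "design.tsv")), "duplicated")

  missing <- design[1:3, ]
  write.table(missing, file.path(dir, "missing.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_bulk(file.path(dir, "counts.tsv"),
                         file.path(dir, "missing.tsv")), "s4")
})
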