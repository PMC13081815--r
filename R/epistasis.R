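#' Normalize bulk counts to replicate-averaged log2 CPM
#'
#' Counts per million per sample, plus a pseudocount of 1, log2-transformed,
#' then averaged across replicates within each condition. Conditions are
#' defined by the `heat` and `salt` columns of the sample design (`-`/`+`),
#' giving the 2x2 dual-stress grid `-HS/-NaCl`, `+HS/-NaCl`, `-HS/+NaCl`,
#' `+HS/+NaCl`. An expression filter (mean CPM >= `min_cpm` in at least one
#' condition) is recorded per gene and applied downstream by correlations and
#' epistasis summaries.
#'
#' @param b a [bulk_counts()] object whose design has `heat` and `salt`
#'   columns with values `-` or `+`.
#' @param min_cpm expression-filter threshold (default 1).
#' @return Object of class `expression_table`: `log2_cpm` (genes x 4
#'   conditions), `pseudocount`, `expressed` (logical per gene),
#'   `n_replicates` per condition.
#' @export
normalize_bulk <- function(b, min_cpm = 1) {
  stopifnot(inherits(b, "bulk_counts"))
  des <- b$sample_design
  if (!all(c("heat", "salt") %in% names(des)))
    stop("sample design must contain 'heat' and 'salt' columns")
  lib <- colSums(b$counts)
  if (any(lib <= 0)) stop("library size must be positive for every sample")
  cpm <- sweep(b$counts, 2, lib, "/") * 1e6
  cond <- paste0(ifelse(des$heat == "+", "+HS", "-HS"), "/",
                 ifelse(des$salt == "+", "+NaCl", "-NaCl"))
  needed <- dual_stress_conditions()
  missing <- setdiff(needed, unique(cond))
  if (length(missing) > 0)
    stop("missing condition(s) of the 2x2 design: ",
         paste(missing, collapse = ", "))
  log2cpm <- log2(cpm + 1)
  by_cond <- sapply(needed, function(cc)
    rowMeans(log2cpm[, cond == cc, drop = FALSE]))
  mean_cpm <- sapply(needed, function(cc)
    rowMeans(cpm[, cond == cc, drop = FALSE]))
  expressed <- apply(mean_cpm, 1, max) >= min_cpm
  structure(list(log2_cpm = by_cond, pseudocount = 1,
                 expressed = expressed, min_cpm = min_cpm,
                 n_replicates = table(cond)[needed]),
            class = "expression_table")
}

#' Canonical dual-stress condition names
#'
#' @return Character vector: unstressed, heat, osmotic, dual.
#' @export
dual_stress_conditions <- function() {
  c("-HS/-NaCl", "+HS/-NaCl", "-HS/+NaCl", "+HS/+NaCl")
}

#' @exportS3Method base::print
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$log2_cpm), "genes x",
      ncol(x$log2_cpm), "conditions (log2 CPM + 1, replicate-averaged)\n")
  cat("  expressed (mean CPM >=", x$min_cpm, "in >= 1 condition):",
      sum(x$expressed), "genes\n")
  invisible(x)
}

#' Log2 fold changes against a reference condition
#'
#' @param e an `expression_table`.
#' @param reference condition name (default the unstressed corner).
#' @return Matrix of per-gene log2 fold changes, one column per non-reference
#'   condition.
#' @export
fold_changes <- function(e, reference = "-HS/-NaCl") {
  stopifnot(inherits(e, "expression_table"))
  if (!reference %in% colnames(e$log2_cpm))
    stop("reference condition '", reference, "' not present")
  others <- colnames(e$log2_cpm)
  lfc <- e$log2_cpm[, others, drop = FALSE] - e$log2_cpm[, reference]
  lfc[, setdiff(others, reference), drop = FALSE]
}

#' Expected dual-stress fold change under independence
#'
#' The log-additive expectation: `ev_dual = lfc_heat + lfc_osmo`, i.e.
#' multiplicative independence of the two stresses on the linear scale.
#'
#' @param lfc_heat,lfc_osmo aligned per-gene log2 fold-change vectors.
#' @return Numeric vector of expected dual-stress log2 fold changes.
#' @export
expected_dual <- function(lfc_heat, lfc_osmo) {
  if (length(lfc_heat) != length(lfc_osmo))
    stop("fold-change vectors must align")
  lfc_heat + lfc_osmo
}

#' Per-gene dual-stress epistasis table
#'
#' Single-stress and dual-stress log2 fold changes relative to the unstressed
#' condition, the log-additive expected dual value, and the deviation
#' `lfc_dual - ev_dual`. Genes failing the expression filter are excluded and
#' counted.
#'
#' @param e an `expression_table`.
#' @param reference reference (unstressed) condition.
#' @return Object of class `epistasis_table`: data.frame with `gene_id`,
#'   `lfc_heat`, `lfc_osmo`, `lfc_dual`, `ev_dual`, `deviation`; attribute
#'   `n_filtered` counts excluded genes.
#' @export
epistasis_table <- function(e, reference = "-HS/-NaCl") {
  lfc <- fold_changes(e, reference)
  keep <- e$expressed
  tab <- data.frame(
    gene_id = rownames(e$log2_cpm)[keep],
    lfc_heat = lfc[keep, "+HS/-NaCl"],
    lfc_osmo = lfc[keep, "-HS/+NaCl"],
    lfc_dual = lfc[keep, "+HS/+NaCl"],
    row.names = NULL, stringsAsFactors = FALSE)
  tab$ev_dual <- expected_dual(tab$lfc_heat, tab$lfc_osmo)
  tab$deviation <- tab$lfc_dual - tab$ev_dual
  structure(tab, class = c("epistasis_table", "data.frame"),
            n_filtered = sum(!keep), reference = reference)
}

#' Read a gene-set file (one gene id per line)
#'
#' @param path text file; blank lines and lines starting with `#` ignored.
#' @param name optional set name (defaults to the file name).
#' @return list with `name` and `gene_ids`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (length(ids) == 0) stop("empty gene set: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  list(name = name, gene_ids = unique(ids))
}

#' Gene-set summaries of dual-stress epistasis
#'
#' Median log2 fold change per condition and median deviation for each gene
#' set, plus a transcriptome-wide `all_genes` row. Gene ids that do not
#' resolve against the table are reported in the `unresolved` attribute.
#'
#' @param t an [epistasis_table()].
#' @param sets named list of gene-id character vectors (or of
#'   [read_gene_set()] results).
#' @return data.frame with one row per set: `set`, `n_genes`,
#'   `median_lfc_heat`, `median_lfc_osmo`, `median_lfc_dual`,
#'   `median_ev_dual`, `median_deviation`.
#' @export
epistasis_summary <- function(t, sets = list()) {
  stopifnot(inherits(t, "epistasis_table"))
  sets <- lapply(sets, function(s) if (is.list(s)) s$gene_ids else s)
  if (is.null(names(sets)) && length(sets) > 0)
    stop("sets must be named")
  unresolved <- list()
  one <- function(name, rows) {
    data.frame(set = name, n_genes = sum(rows),
               median_lfc_heat = stats::median(t$lfc_heat[rows]),
               median_lfc_osmo = stats::median(t$lfc_osmo[rows]),
               median_lfc_dual = stats::median(t$lfc_dual[rows]),
               median_ev_dual = stats::median(t$ev_dual[rows]),
               median_deviation = stats::median(t$deviation[rows]),
               stringsAsFactors = FALSE)
  }
  out <- one("all_genes", rep(TRUE, nrow(t)))
  for (nm in names(sets)) {
    rows <- t$gene_id %in% sets[[nm]]
    missing <- setdiff(sets[[nm]], t$gene_id)
    if (length(missing) > 0) unresolved[[nm]] <- missing
    if (!any(rows)) stop("gene set '", nm, "' resolves to no genes")
    out <- rbind(out, one(nm, rows))
  }
  attr(out, "unresolved") <- unresolved
  out
}

#' Pearson correlation between two conditions
#'
#' Computed on replicate-averaged log2 CPM over genes passing the expression
#' filter.
#'
#' @param e an `expression_table`.
#' @param a,b condition names.
#' @return Pearson r, or `NA` (with attribute `degenerate = TRUE`) when either
#'   column has zero variance.
#' @export
condition_correlation <- function(e, a, b) {
  stopifnot(inherits(e, "expression_table"))
  for (cc in c(a, b)) if (!cc %in% colnames(e$log2_cpm))
    stop("condition '", cc, "' not present")
  keep <- e$expressed
  if (sum(keep) < 3) stop("fewer than 3 genes after the expression filter")
  x <- e$log2_cpm[keep, a]
  y <- e$log2_cpm[keep, b]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, degenerate = TRUE))
  stats::cor(x, y)
}

#' Between-strain transcriptome concordance
#'
#' Squared Pearson correlation of per-gene log2 CPM between two strains in the
#' same condition, over the intersection of expressed genes.
#'
#' @param anc,der `expression_table` objects for the two strains.
#' @param condition shared condition name.
#' @return R-squared, with attribute `n_genes` (intersection size).
#' @export
strain_concordance <- function(anc, der, condition) {
  stopifnot(inherits(anc, "expression_table"),
            inherits(der, "expression_table"))
  for (e in list(anc, der)) if (!condition %in% colnames(e$log2_cpm))
    stop("condition '", condition, "' not present in both tables")
  ga <- rownames(anc$log2_cpm)[anc$expressed]
  gd <- rownames(der$log2_cpm)[der$expressed]
  common <- intersect(ga, gd)
  if (length(common) < 3) stop("gene intersection below 3 genes")
  r <- stats::cor(anc$log2_cpm[common, condition],
                  der$log2_cpm[common, condition])
  structure(r^2, n_genes = length(common))
}
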