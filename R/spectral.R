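#' Eigenspectrum decomposition of an expression matrix
#'
#' Computes the truncated singular value decomposition of the (optionally
#' gene-centered) log-normalized expression matrix. With centering this is
#' ordinary PCA: columns of `U` are the per-cell components (left singular
#' vectors, i.e. the PCs), `s` the singular values, and columns of `V`
#' the gene loadings. `total_variance` is the squared Frobenius norm of the
#' full centered matrix, computed exactly from the data rather than from the
#' retained components, so variance fractions are correct even when `K` is far
#' below the rank.
#'
#' A deterministic sign convention is applied: within each component, the gene
#' loading of largest absolute value is made positive.
#'
#' @param x a `normalized_matrix` or a plain numeric matrix (cells x genes).
#' @param K number of components to retain.
#' @param center mean-center each gene before decomposing (default `TRUE`).
#' @param method `"auto"` picks a dense SVD for small matrices and an
#'   eigendecomposition of the gene-gene Gram matrix when cells greatly
#'   outnumber genes (mathematically identical for the leading components);
#'   `"dense"` forces the dense SVD reference path.
#' @param seed unused by the deterministic solvers; retained so pipelines can
#'   record one seed per stage.
#' @return Object of class `spectral_decomposition` with `U` (cells x K), `s`
#'   (non-increasing), `V` (genes x K), `total_variance`, `centered`, `K`,
#'   `gene_ids`, `cell_ids`.
#' @export
decompose <- function(x, K, center = TRUE, method = c("auto", "dense", "gram"),
                      seed = NULL) {
  method <- match.arg(method)
  meta <- NULL
  gene_ids <- cell_ids <- NULL
  if (inherits(x, "normalized_matrix")) {
    meta <- x$cell_meta
    gene_ids <- colnames(x$values)
    cell_ids <- rownames(x$values)
    x <- x$values
  }
  xd <- as.matrix(x)
  if (!all(is.finite(xd))) stop("non-finite entries in matrix")
  if (is.null(gene_ids)) gene_ids <- colnames(xd)
  if (is.null(cell_ids)) cell_ids <- rownames(xd)
  n <- nrow(xd); p <- ncol(xd)
  maxK <- min(n, p)
  if (K > maxK) {
    warning("K = ", K, " exceeds min(dim) = ", maxK, "; truncating")
    K <- maxK
  }
  if (K < 1) stop("K must be at least 1")
  mu <- if (center) colMeans(xd) else rep(0, p)
  if (method == "auto") method <- if (n >= 4 * p && p > 200) "gram" else "dense"
  if (method == "gram") {
    # eigen-decompose the p x p centered Gram matrix; exact for leading
    # components and much faster when cells >> genes
    C <- crossprod(xd) - n * tcrossprod(mu)
    C <- (C + t(C)) / 2
    e <- eigen(C, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    total_var <- sum(ev)
    s <- sqrt(ev[seq_len(K)])
    V <- e$vectors[, seq_len(K), drop = FALSE]
    scores <- xd %*% V
    scores <- sweep(scores, 2, drop(crossprod(mu, V)), "-")
    pos <- s > max(s[1], .Machine$double.eps) * 1e-12
    U <- scores
    U[, pos] <- sweep(scores[, pos, drop = FALSE], 2, s[pos], "/")
    U[, !pos] <- 0
  } else {
    xc <- sweep(xd, 2, mu, "-")
    total_var <- sum(xc^2)
    sv <- svd(xc, nu = K, nv = K)
    s <- sv$d[seq_len(K)]
    U <- sv$u
    V <- sv$v
  }
  # sign convention: largest-|loading| gene positive per component
  for (k in seq_len(K)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) {
      V[, k] <- -V[, k]
      U[, k] <- -U[, k]
    }
  }
  structure(list(U = U, s = s, V = V, total_variance = total_var,
                 centered = center, K = K, method = method,
                 gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = meta),
            class = "spectral_decomposition")
}

#' @exportS3Method base::print
print.spectral_decomposition <- function(x, ...) {
  cat("spectral_decomposition: K =", x$K, "components,",
      nrow(x$U), "cells x", nrow(x$V), "genes",
      if (x$centered) "(gene-centered)" else "(uncentered)", "\n")
  vf <- variance_fractions(x)
  cat("  variance explained by retained components:",
      sprintf("%.2f%%", 100 * sum(vf$fractions)), "\n")
  invisible(x)
}

#' Variance-explained spectrum
#'
#' @param d a `spectral_decomposition`.
#' @return Object of class `variance_spectrum`: `fractions`
#'   (`f_k = s_k^2 / total_variance`) and their `cumulative` running sum.
#' @export
variance_fractions <- function(d) {
  stopifnot(inherits(d, "spectral_decomposition"))
  f <- d$s^2 / d$total_variance
  structure(list(fractions = f, cumulative = cumsum(f)),
            class = "variance_spectrum")
}

#' Cumulative variance explained by the leading components
#'
#' @param d a `spectral_decomposition`.
#' @param upto include components 1..`upto` (must not exceed `K`).
#' @return Fraction of total variance in `[0, 1]`.
#' @export
variance_explained <- function(d, upto) {
  stopifnot(inherits(d, "spectral_decomposition"))
  if (upto < 1) stop("upto must be at least 1")
  if (upto > d$K) stop("upto exceeds the number of retained components")
  sum(d$s[seq_len(upto)]^2) / d$total_variance
}

#' Top gene loadings of a component
#'
#' Genes ranked by absolute loading (descending), ties broken by gene id
#' (lexicographic); signed loadings are returned.
#'
#' @param d a `spectral_decomposition`.
#' @param component component index in `1..K`.
#' @param n number of genes to return; values beyond the gene count return the
#'   full ranked list.
#' @return data.frame with columns `gene_id` and `loading`.
#' @export
top_loadings <- function(d, component, n = 25) {
  stopifnot(inherits(d, "spectral_decomposition"))
  if (component < 1 || component > d$K) stop("component out of range")
  if (n <= 0) stop("n must be positive")
  v <- d$V[, component]
  ids <- if (is.null(d$gene_ids)) paste0("gene", seq_along(v)) else d$gene_ids
  ord <- order(-abs(v), ids)
  ord <- ord[seq_len(min(n, length(v)))]
  data.frame(gene_id = ids[ord], loading = v[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Linearity of the variance spectrum over a component window
#'
#' Ordinary least-squares fit of variance fractions against component rank;
#' a decaying spectrum gives a negative slope, and an approximately linear
#' decay gives r-squared near 1.
#'
#' @param v a `variance_spectrum` (or numeric vector of fractions).
#' @param range integer vector of component ranks (length >= 3).
#' @return list with `slope`, `intercept`, `r_squared`, and `degenerate`
#'   (`TRUE` when the spectrum is constant over the window, in which case
#'   `r_squared` is reported as 0).
#' @export
spectrum_linearity <- function(v, range = NULL) {
  f <- if (inherits(v, "variance_spectrum")) v$fractions else as.numeric(v)
  if (is.null(range)) range <- seq_along(f)
  if (length(range) < 3) stop("range must contain at least 3 components")
  if (any(range < 1 | range > length(f))) stop("range outside spectrum")
  y <- f[range]
  k <- as.numeric(range)
  if (stats::sd(y) == 0) {
    return(list(slope = 0, intercept = y[1], r_squared = 0,
                degenerate = TRUE))
  }
  slope <- stats::cov(k, y) / stats::var(k)
  list(slope = slope,
       intercept = mean(y) - slope * mean(k),
       r_squared = stats::cor(k, y)^2,
       degenerate = FALSE)
}
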