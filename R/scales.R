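#' Sliding component windows
#'
#' Windows of `width` consecutive components starting at component 1 and
#' advancing by `stride`, covering components up to `min(K, max_pc)`.
#'
#' @param K number of available components.
#' @param width window width in components (default 3).
#' @param stride step between window starts (default 1, i.e. sliding).
#' @param max_pc deepest component covered (default 30, capped at `K`).
#' @return data.frame with columns `window` (index), `start`, `end`.
#' @export
make_windows <- function(K, width = 3, stride = 1, max_pc = 30) {
  stopifnot(width >= 1, stride >= 1)
  if (width > K) stop("width exceeds the number of components")
  last <- min(K, max_pc)
  starts <- seq(1, last - width + 1, by = stride)
  data.frame(window = seq_along(starts), start = starts,
             end = starts + width - 1)
}

#' Sample unordered cell pairs
#'
#' Draws one shared set of distinct unordered cell-index pairs, exhaustive
#' when the total number of pairs fits the budget, otherwise a uniform sample
#' without replacement. The same pair sample is intended to be reused across
#' windows, variables, and permutations so profiles are comparable.
#'
#' @param n_cells number of cells.
#' @param budget maximum number of pairs (default 2e6).
#' @param seed RNG seed used when sampling is needed.
#' @return Object of class `pair_sample` with integer vectors `i`, `j`
#'   (`i < j`), and fields `exhaustive`, `budget`, `seed`.
#' @export
sample_pairs <- function(n_cells, budget = 2e6, seed = 0) {
  stopifnot(n_cells >= 2)
  if (budget < 100) stop("pair budget must be at least 100")
  total <- n_cells * (n_cells - 1) / 2
  if (total <= budget) {
    i <- rep.int(seq_len(n_cells - 1), times = (n_cells - 1):1)
    j <- sequence((n_cells - 1):1, from = 2:n_cells)
    exhaustive <- TRUE
  } else {
    k0 <- .with_seed(seed, sample(total, budget)) - 1  # 0-based linear index
    dec <- .decode_pairs(k0, n_cells)
    i <- dec$i; j <- dec$j
    exhaustive <- FALSE
  }
  structure(list(i = as.integer(i), j = as.integer(j),
                 exhaustive = exhaustive, budget = budget, seed = seed),
            class = "pair_sample")
}

# decode 0-based linear pair indices (lexicographic over i < j) into 1-based
# (i, j); exact for totals below 2^53
.decode_pairs <- function(k0, n) {
  cum <- function(i) i * (n - 1) - i * (i - 1) / 2  # pairs before 0-based row i
  i0 <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k0)) / 2)
  i0 <- pmax(pmin(i0, n - 2), 0)
  # correct any floating-point off-by-one
  over <- cum(i0) > k0
  i0[over] <- i0[over] - 1
  under <- cum(i0 + 1) <= k0
  i0[under] <- i0[under] + 1
  j0 <- k0 - cum(i0) + i0 + 1
  list(i = i0 + 1, j = j0 + 1)
}

#' @exportS3Method base::print
print.pair_sample <- function(x, ...) {
  cat("pair_sample:", length(x$i), "pairs",
      if (x$exhaustive) "(exhaustive)" else
        sprintf("(sampled, budget %g, seed %s)", x$budget, x$seed), "\n")
  invisible(x)
}

# projection of cells onto a component window
.window_projection <- function(d, start, end,
                               weighting = c("scores", "unit")) {
  weighting <- match.arg(weighting)
  cols <- start:end
  P <- d$U[, cols, drop = FALSE]
  if (weighting == "scores")
    P <- sweep(P, 2, d$s[cols], "*")
  P
}

#' Pairwise spectral correlations within a component window
#'
#' For each sampled cell pair, the inner product of the two cells' projections
#' onto the window of components. With `weighting = "scores"` (default) the
#' projection is `U * diag(s)` restricted to the window; `"unit"` uses the
#' bare singular vectors. `normalization = "cosine"` divides by the product of
#' the two projection norms (values in [-1, 1]); cells with zero-norm
#' projections yield 0 and are counted in the `degenerate_cells` attribute.
#'
#' @param d a `spectral_decomposition`.
#' @param window single-row data.frame (or list) with `start` and `end`.
#' @param pairs a [sample_pairs()] object.
#' @param weighting `"scores"` or `"unit"`.
#' @param normalization `"raw"` or `"cosine"`.
#' @return Numeric vector of correlations, one per pair.
#' @export
window_correlations <- function(d, window, pairs,
                                weighting = c("scores", "unit"),
                                normalization = c("raw", "cosine")) {
  stopifnot(inherits(d, "spectral_decomposition"),
            inherits(pairs, "pair_sample"))
  normalization <- match.arg(normalization)
  if (window$start < 1 || window$end > d$K) stop("window outside 1..K")
  P <- .window_projection(d, window$start, window$end, weighting)
  vals <- rowSums(P[pairs$i, , drop = FALSE] * P[pairs$j, , drop = FALSE])
  n_degenerate <- 0L
  if (normalization == "cosine") {
    nrm <- sqrt(rowSums(P^2))
    zero <- nrm == 0
    n_degenerate <- sum(zero)
    nrm[zero] <- 1
    vals <- vals / (nrm[pairs$i] * nrm[pairs$j])
    vals[zero[pairs$i] | zero[pairs$j]] <- 0
  }
  attr(vals, "degenerate_cells") <- n_degenerate
  vals
}

# equal-frequency discretization; tied quantile breaks are merged so heavily
# tied values share one bin. Returns 1-based bin index and the bin count.
.bin_quantile <- function(values, n_bins) {
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7)
  inner <- unique(qs[-c(1, length(qs))])
  bins <- findInterval(values, inner) + 1L
  list(bins = bins, n_bins = length(inner) + 1L)
}

#' Plug-in mutual information of a joint count table
#'
#' `MI = sum_{b,y} (n_by / N) * log2( n_by * N / (n_b * n_y) )` over non-empty
#' cells, in bits. Counts enter the log as exact integer products, so
#' perfectly predictive balanced tables give exactly 1 bit and independent
#' tables exactly 0.
#'
#' @param tab matrix of joint counts (bins x classes).
#' @return Mutual information in bits.
#' @export
mi_from_table <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  if (N == 0) return(0)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  nz <- tab > 0
  prod_margin <- outer(rs, cs)
  mi <- sum((tab[nz] / N) * log2(tab[nz] * N / prod_margin[nz]))
  max(mi, 0)
}

#' Mutual information between a value distribution and a binary label
#'
#' Values are discretized into at most `n_bins` equal-frequency bins (tied
#' quantiles merged); the plug-in estimator is applied to the joint histogram
#' of bin and label, in bits.
#'
#' @param values numeric vector.
#' @param labels vector with at most 2 distinct values (e.g. the same-label
#'   pair indicator).
#' @param n_bins maximum number of bins (default 16).
#' @param binning discretization scheme; only `"quantile"` (equal frequency)
#'   is implemented.
#' @return MI in bits, with attribute `degenerate = TRUE` when labels have a
#'   single class or values are constant.
#' @export
mutual_information <- function(values, labels, n_bins = 16,
                               binning = "quantile") {
  binning <- match.arg(binning, "quantile")
  if (length(values) != length(labels)) stop("values and labels must align")
  if (length(values) < 2) stop("need at least 2 observations")
  y <- as.integer(factor(labels))
  ny <- max(y)
  if (ny > 2) stop("labels must contain at most 2 classes")
  if (ny < 2 || length(unique(values)) == 1) {
    return(structure(0, degenerate = TRUE))
  }
  b <- .bin_quantile(values, n_bins)
  tab <- .joint_table(b$bins, b$n_bins, y - 1L)
  mi_from_table(tab)
}

# joint counts of bin (1..nb) x binary label (0/1), as an nb x 2 matrix
.joint_table <- function(bins, nb, y01) {
  matrix(tabulate(bins + nb * y01, nbins = 2L * nb), ncol = 2)
}

.same_label <- function(labels, pairs) {
  labels[pairs$i] == labels[pairs$j]
}

#' Windowed MI profile of one environmental variable
#'
#' For each sliding window of components, computes the mutual information
#' between the pairwise spectral correlations and the binary indicator of
#' whether the two cells of a pair share the same value of `variable`. The
#' cumulative curve ("MI(CDF)") is the running sum of per-window MI, reported
#' raw and normalized to its final value.
#'
#' @param d a `spectral_decomposition`.
#' @param variable metadata column name (must have >= 2 levels).
#' @param meta per-cell metadata (defaults to the metadata carried by `d`).
#' @param windows data.frame from [make_windows()]; defaults to sliding
#'   width-3 windows over components 1..min(K, max_pc).
#' @param pairs shared [sample_pairs()] object; drawn with `seed` if omitted.
#' @param pair_budget,seed pair-sampling controls when `pairs` is omitted.
#' @param n_bins bins for the MI estimator.
#' @param weighting,normalization passed to [window_correlations()].
#' @param max_pc deepest component used for default windows.
#' @return Object of class `mi_profile`: `variable`, `windows`, `mi` (bits),
#'   `cumulative`, `cumulative_normalized`, and the estimator configuration.
#' @export
mi_profile <- function(d, variable, meta = d$cell_meta, windows = NULL,
                       pairs = NULL, pair_budget = 2e6, seed = 0,
                       n_bins = 16, weighting = "scores",
                       normalization = "raw", max_pc = 30) {
  stopifnot(inherits(d, "spectral_decomposition"))
  labels <- .get_labels(meta, variable, nrow(d$U))
  if (is.null(windows)) windows <- make_windows(d$K, max_pc = max_pc)
  if (is.null(pairs)) pairs <- sample_pairs(nrow(d$U), pair_budget, seed)
  y <- .same_label(labels, pairs)
  mi <- vapply(seq_len(nrow(windows)), function(w) {
    vals <- window_correlations(d, windows[w, ], pairs,
                                weighting = weighting,
                                normalization = normalization)
    as.numeric(mutual_information(vals, y, n_bins = n_bins))
  }, numeric(1))
  .build_profile(variable, windows, mi,
                 config = list(n_bins = n_bins, weighting = weighting,
                               normalization = normalization,
                               pair_budget = pairs$budget, seed = seed,
                               n_pairs = length(pairs$i),
                               exhaustive = pairs$exhaustive))
}

.get_labels <- function(meta, variable, n_cells) {
  if (is.null(meta)) stop("no metadata available")
  if (!variable %in% names(meta))
    stop("variable '", variable, "' not found in metadata")
  labels <- meta[[variable]]
  if (length(labels) != n_cells) stop("metadata does not match cell count")
  if (length(unique(labels)) < 2)
    stop("variable '", variable, "' has fewer than 2 levels")
  labels
}

.build_profile <- function(variable, windows, mi, config, null = NULL) {
  cumulative <- cumsum(mi)
  total <- cumulative[length(cumulative)]
  normalized <- if (total > 0) cumulative / total else rep(NA_real_,
                                                           length(mi))
  structure(list(variable = variable, windows = windows, mi = mi,
                 cumulative = cumulative, cumulative_normalized = normalized,
                 null = null, config = config),
            class = "mi_profile")
}

#' @exportS3Method base::print
print.mi_profile <- function(x, ...) {
  cat("mi_profile for '", x$variable, "': ", nrow(x$windows),
      " windows, total MI ", sprintf("%.4f", sum(x$mi)), " bits\n", sep = "")
  d <- spectral_depth(x)
  if (!is.na(d))
    cat("  spectral depth (half-rise): window", d, "(components",
        x$windows$start[d], "-", x$windows$end[d], ")\n")
  if (!is.null(x$null))
    cat("  null:", x$null$mode, "with", x$null$n_perm, "permutations\n")
  invisible(x)
}

#' Permutation-null MI profile
#'
#' Recomputes the windowed MI profile under label permutations with the same
#' shared pair sample. `per_condition` (default) permutes the variable's value
#' assignment across sample blocks, so all cells of a sample keep a common,
#' permuted label and within-condition transcriptional structure is preserved;
#' `per_cell` permutes labels across individual cells. The envelope reports
#' the per-window null mean and a conservative empirical 95th percentile (the
#' `ceiling(0.95 * (n_perm + 1))`-th order statistic, which accounts for the
#' observed profile being one more draw from the null).
#'
#' @inheritParams mi_profile
#' @param mode `"per_condition"` or `"per_cell"`.
#' @param n_perm number of permutations (default 100).
#' @return List of class `null_profile`: `null_mean`, `null_q95`, `null_mi`
#'   (n_perm x windows matrix), `null_cumulative`, `mode`, `n_perm`, `seed`.
#' @export
null_profile <- function(d, variable, meta = d$cell_meta, windows = NULL,
                         pairs = NULL, pair_budget = 2e6, seed = 0,
                         mode = c("per_condition", "per_cell"),
                         n_perm = 100, n_bins = 16, weighting = "scores",
                         normalization = "raw", max_pc = 30) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1)
  labels <- .get_labels(meta, variable, nrow(d$U))
  if (is.null(windows)) windows <- make_windows(d$K, max_pc = max_pc)
  if (is.null(pairs)) pairs <- sample_pairs(nrow(d$U), pair_budget, seed)
  W <- nrow(windows)
  null_mi <- matrix(NA_real_, n_perm, W)
  if (mode == "per_condition") {
    blk <- .block_structure(meta, labels)
    perms <- .with_seed(seed, replicate(n_perm, sample(blk$n_blocks),
                                        simplify = FALSE))
    pc <- .pair_classes(blk$block_of_cell, pairs)
    for (w in seq_len(W)) {
      vals <- window_correlations(d, windows[w, ], pairs,
                                  weighting = weighting,
                                  normalization = normalization)
      b <- .bin_quantile(vals, n_bins)
      Nw <- .class_table(b$bins, b$n_bins, pc$class, pc$n_classes)
      for (p in seq_len(n_perm)) {
        Lp <- blk$block_labels[perms[[p]]]
        ymatch <- Lp[pc$b1] == Lp[pc$b2]
        tab <- cbind(Nw %*% (!ymatch), Nw %*% ymatch)
        null_mi[p, w] <- mi_from_table(tab)
      }
    }
  } else {
    n <- nrow(d$U)
    perms <- .with_seed(seed, replicate(n_perm, sample(n), simplify = FALSE))
    for (w in seq_len(W)) {
      vals <- window_correlations(d, windows[w, ], pairs,
                                  weighting = weighting,
                                  normalization = normalization)
      b <- .bin_quantile(vals, n_bins)
      for (p in seq_len(n_perm)) {
        lp <- labels[perms[[p]]]
        y01 <- as.integer(lp[pairs$i] == lp[pairs$j])
        tab <- .joint_table(b$bins, b$n_bins, y01)
        null_mi[p, w] <- mi_from_table(tab)
      }
    }
  }
  .summarize_null(null_mi, mode, n_perm, seed)
}

.summarize_null <- function(null_mi, mode, n_perm, seed) {
  k <- min(n_perm, ceiling(0.95 * (n_perm + 1)))
  q95 <- apply(null_mi, 2, function(v) sort(v)[k])
  structure(list(null_mean = colMeans(null_mi), null_q95 = q95,
                 null_mi = null_mi,
                 null_cumulative = t(apply(null_mi, 1, cumsum)),
                 mode = mode, n_perm = n_perm, seed = seed),
            class = "null_profile")
}

# condition blocks for the per-condition shuffle; the variable must be
# constant within each sample block
.block_structure <- function(meta, labels) {
  if (is.null(meta$sample_id))
    stop("per_condition null requires a sample_id metadata column")
  sample_id <- as.character(meta$sample_id)
  blocks <- unique(sample_id)
  block_of_cell <- match(sample_id, blocks)
  block_labels <- vapply(seq_along(blocks), function(b) {
    lv <- unique(labels[block_of_cell == b])
    if (length(lv) != 1)
      stop("variable is not constant within sample block '", blocks[b], "'")
    as.character(lv)
  }, character(1))
  if (all(table(block_labels) == 1)) {
    warning("only one sample block per label level; ",
            "permutation support is trivial")
  }
  list(n_blocks = length(blocks), block_of_cell = block_of_cell,
       block_labels = block_labels)
}

# unordered block-pair class per sampled pair (1..B(B+1)/2, diagonal allowed)
.pair_classes <- function(block_of_cell, pairs) {
  b1 <- pmin(block_of_cell[pairs$i], block_of_cell[pairs$j])
  b2 <- pmax(block_of_cell[pairs$i], block_of_cell[pairs$j])
  B <- max(block_of_cell)
  cls <- (b2 - 1) * b2 / 2 + b1
  n_classes <- B * (B + 1) / 2
  # representative block indices per class id
  c2 <- ceiling((sqrt(8 * seq_len(n_classes) + 1) - 1) / 2)
  c1 <- seq_len(n_classes) - (c2 - 1) * c2 / 2
  list(class = as.integer(cls), n_classes = as.integer(n_classes),
       b1 = c1, b2 = c2)
}

# bins x block-pair-class count matrix
.class_table <- function(bins, nb, class, n_classes) {
  matrix(tabulate(bins + nb * (class - 1L), nbins = nb * n_classes),
         nrow = nb)
}

#' Spectral depth of an MI profile
#'
#' The smallest window index at which the normalized cumulative MI curve
#' reaches `threshold` (default 0.5, the half-rise point). Shallower depth
#' means the cue is encoded in more dominant modes of variation.
#'
#' @param p an `mi_profile`.
#' @param threshold fraction of total cumulative MI (default 0.5).
#' @return Integer window index, or `NA` (flagged) for an all-zero profile.
#' @export
spectral_depth <- function(p, threshold = 0.5) {
  stopifnot(inherits(p, "mi_profile"))
  total <- p$cumulative[length(p$cumulative)]
  if (!is.finite(total) || total <= 0) {
    return(structure(NA_integer_, degenerate = TRUE))
  }
  as.integer(which(p$cumulative_normalized >= threshold)[1])
}

#' Rank environmental variables into a hierarchy by spectral depth
#'
#' Variables are ordered by spectral depth ascending (shallower = higher
#' adaptive priority). Ties are broken by larger total cumulative MI, then by
#' name; variables with undefined depth are placed last and flagged.
#'
#' @param profiles named list of `mi_profile` objects (>= 2).
#' @param threshold depth threshold passed to [spectral_depth()].
#' @return Object of class `hierarchy_ranking` with a `table` data.frame
#'   (`variable`, `depth`, `total_mi`, `rank`), the `ordering` (variable names
#'   by rank), and a `ties` list of depth-tied groups.
#' @export
rank_hierarchy <- function(profiles, threshold = 0.5) {
  stopifnot(length(profiles) >= 2)
  vars <- vapply(profiles, function(p) p$variable, character(1))
  names(profiles) <- vars
  depth <- vapply(profiles, function(p)
    as.integer(spectral_depth(p, threshold)), integer(1))
  total <- vapply(profiles, function(p) sum(p$mi), numeric(1))
  undefined <- is.na(depth)
  depth_key <- ifelse(undefined, .Machine$integer.max, depth)
  ord <- order(depth_key, -total, vars)
  tab <- data.frame(variable = vars[ord], depth = depth[ord],
                    total_mi = total[ord], rank = seq_along(ord),
                    undefined_depth = undefined[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  dupdepth <- unique(tab$depth[duplicated(tab$depth) & !is.na(tab$depth)])
  ties <- lapply(dupdepth, function(dd) tab$variable[!is.na(tab$depth) &
                                                       tab$depth == dd])
  structure(list(table = tab, ordering = tab$variable, ties = ties,
                 threshold = threshold),
            class = "hierarchy_ranking")
}

#' @exportS3Method base::print
print.hierarchy_ranking <- function(x, ...) {
  cat("hierarchy_ranking (depth threshold", x$threshold, "):\n")
  print(x$table, row.names = FALSE)
  if (length(x$ties) > 0)
    cat("  depth ties:", paste(vapply(x$ties, paste, character(1),
                                      collapse = " = "),
                               collapse = "; "), "\n")
  invisible(x)
}

#' Full SCALES analysis of an expression decomposition
#'
#' Orchestrates the windowed spectral-correlation MI procedure for a set of
#' categorical environmental variables: one shared pair sample, per-window
#' correlations and equal-frequency binning computed once and reused across
#' variables and permutations, per-variable MI profiles with per-condition (or
#' per-cell) permutation-null envelopes, spectral depths, and the hierarchy
#' ranking.
#'
#' @inheritParams mi_profile
#' @param variables character vector of metadata column names.
#' @param width,stride,max_pc window geometry (defaults 3 / 1 / 30).
#' @param null `"per_condition"`, `"per_cell"`, or `"none"`.
#' @param n_perm permutations for the null envelope.
#' @param depth_threshold normalized-cumulative threshold for spectral depth.
#' @return Object of class `scales_result`: `profiles` (named list of
#'   `mi_profile`, each with its `null` attached), `hierarchy`, `windows`,
#'   `pairs` summary, and the full parameter `config`.
#' @export
scales_analysis <- function(d, variables, meta = d$cell_meta,
                            width = 3, stride = 1, max_pc = 30,
                            n_bins = 16, pair_budget = 2e6,
                            weighting = "scores", normalization = "raw",
                            null = c("per_condition", "per_cell", "none"),
                            n_perm = 100, seed = 0, depth_threshold = 0.5) {
  null <- match.arg(null)
  stopifnot(inherits(d, "spectral_decomposition"))
  n <- nrow(d$U)
  windows <- make_windows(d$K, width = width, stride = stride,
                          max_pc = max_pc)
  W <- nrow(windows)
  pairs <- sample_pairs(n, pair_budget, seed)
  labels <- lapply(variables, function(v) .get_labels(meta, v, n))
  names(labels) <- variables

  use_blocks <- null == "per_condition"
  if (use_blocks) {
    blks <- lapply(labels, function(l) .block_structure(meta, l))
    pc <- .pair_classes(blks[[1]]$block_of_cell, pairs)
    perms <- .with_seed(seed, replicate(n_perm,
                                        sample(blks[[1]]$n_blocks),
                                        simplify = FALSE))
  } else {
    y_pair <- lapply(labels, .same_label, pairs = pairs)
    if (null == "per_cell")
      perms <- .with_seed(seed, replicate(n_perm, sample(n),
                                          simplify = FALSE))
  }

  mi <- matrix(0, W, length(variables),
               dimnames = list(NULL, variables))
  null_mi <- if (null != "none")
    lapply(variables, function(v) matrix(NA_real_, n_perm, W)) else NULL
  names(null_mi) <- variables

  for (w in seq_len(W)) {
    vals <- window_correlations(d, windows[w, ], pairs,
                                weighting = weighting,
                                normalization = normalization)
    b <- .bin_quantile(vals, n_bins)
    if (use_blocks) {
      Nw <- .class_table(b$bins, b$n_bins, pc$class, pc$n_classes)
      for (v in variables) {
        L <- blks[[v]]$block_labels
        ymatch <- L[pc$b1] == L[pc$b2]
        mi[w, v] <- mi_from_table(cbind(Nw %*% (!ymatch), Nw %*% ymatch))
        for (p in seq_len(n_perm)) {
          Lp <- L[perms[[p]]]
          yp <- Lp[pc$b1] == Lp[pc$b2]
          null_mi[[v]][p, w] <-
            mi_from_table(cbind(Nw %*% (!yp), Nw %*% yp))
        }
      }
    } else {
      for (v in variables) {
        tab <- .joint_table(b$bins, b$n_bins, as.integer(y_pair[[v]]))
        mi[w, v] <- mi_from_table(tab)
        if (null == "per_cell") {
          lab <- labels[[v]]
          for (p in seq_len(n_perm)) {
            lp <- lab[perms[[p]]]
            y01 <- as.integer(lp[pairs$i] == lp[pairs$j])
            null_mi[[v]][p, w] <-
              mi_from_table(.joint_table(b$bins, b$n_bins, y01))
          }
        }
      }
    }
  }

  config <- list(width = width, stride = stride, max_pc = max_pc,
                 n_bins = n_bins, pair_budget = pair_budget,
                 n_pairs = length(pairs$i), exhaustive = pairs$exhaustive,
                 weighting = weighting, normalization = normalization,
                 null = null, n_perm = n_perm, seed = seed,
                 depth_threshold = depth_threshold)
  profiles <- lapply(variables, function(v) {
    nl <- if (null != "none")
      .summarize_null(null_mi[[v]], null, n_perm, seed) else NULL
    .build_profile(v, windows, mi[, v], config = config, null = nl)
  })
  names(profiles) <- variables
  hierarchy <- if (length(profiles) >= 2)
    rank_hierarchy(profiles, threshold = depth_threshold) else NULL
  structure(list(profiles = profiles, hierarchy = hierarchy,
                 windows = windows,
                 pairs = list(n_pairs = length(pairs$i),
                              exhaustive = pairs$exhaustive,
                              budget = pair_budget, seed = seed),
                 config = config),
            class = "scales_result")
}

#' @exportS3Method base::print
print.scales_result <- function(x, ...) {
  cat("scales_result:", length(x$profiles), "variables,",
      nrow(x$windows), "windows,", x$pairs$n_pairs, "pairs\n")
  print(x$hierarchy)
  invisible(x)
}
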