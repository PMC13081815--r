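test_that("window geometry follows width, stride and depth limits", {
  w <- make_windows(30)
  expect_equal(nrow(w), 28)
  expect_equal(w$start[1], 1)
  expect_equal(w$end[1], 3)
  expect_equal(w$start[28], 28)
  expect_equal(w$end[28], 30)

  expect_equal(nrow(make_windows(3)), 1)
  expect_equal(nrow(make_windows(9, stride = 3, max_pc = 9)), 3)
  expect_equal(nrow(make_windows(100)), 28)  # capped at component 30
  expect_error(make_windows(2, width = 3), "width exceeds")
})

test_that("pair sampling is exhaustive under budget, valid and seeded above", {
  p <- sample_pairs(10, budget = 1000)
  expect_true(p$exhaustive)
  expect_equal(length(p$i), 45)
  expect_true(all(p$i < p$j))

  p2 <- sample_pairs(300, budget = 5000, seed = 3)
  expect_false(p2$exhaustive)
  expect_equal(length(p2$i), 5000)
  expect_true(all(p2$i >= 1 & p2$j <= 300 & p2$i < p2$j))
  expect_false(any(duplicated(cbind(p2$i, p2$j))))
  p3 <- sample_pairs(300, budget = 5000, seed = 3)
  expect_identical(p2$i, p3$i)
  expect_identical(p2$j, p3$j)
  expect_error(sample_pairs(10, budget = 10), "at least 100")
})

test_that("linear pair indices decode to the lexicographic enumeration", {
  n <- 40
  full <- sample_pairs(n, budget = 1e6)   # exhaustive reference
  dec <- adaptscales:::.decode_pairs(0:(n * (n - 1) / 2 - 1), n)
  expect_identical(as.integer(dec$i), full$i)
  expect_identical(as.integer(dec$j), full$j)
})

test_that("window correlations reproduce hand-computed inner products", {
  # 4 cells with hand-written 3-component scores (weighting already applied
  # through unit singular values)
  S <- rbind(c(1, 2, 0), c(1, 2, 0), c(0, 0, 3), c(-1, 1, 1))
  d <- make_decomp(U = S, s = c(1, 1, 1))
  p <- sample_pairs(4, budget = 1000)
  w <- list(start = 1, end = 3)
  vals <- window_correlations(d, w, p, weighting = "unit")
  # pairs in order (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
  expect_equal(as.numeric(vals), c(5, 0, 1, 0, 1, 3))

  cos <- window_correlations(d, w, p, weighting = "unit",
                             normalization = "cosine")
  expect_equal(cos[1], 1.0)     # identical projections
  expect_equal(cos[2], 0.0)     # orthogonal projections
  expect_equal(cos[6], 3 / (3 * sqrt(3)))
})

test_that("cosine normalization flags zero-norm projections as degenerate", {
  S <- rbind(c(0, 0), c(1, 1), c(2, 0))
  d <- make_decomp(U = S, s = c(1, 1))
  p <- sample_pairs(3, budget = 1000)
  vals <- window_correlations(d, list(start = 1, end = 2), p,
                              weighting = "unit", normalization = "cosine")
  expect_equal(attr(vals, "degenerate_cells"), 1L)
  expect_equal(as.numeric(vals[1]), 0)  # pair (1,2) involves the zero cell
})

test_that("score weighting scales projections by singular values", {
  U <- cbind(c(1, 0), c(0, 1)) / 1
  d <- make_decomp(U = U, s = c(3, 2))
  p <- sample_pairs(2, budget = 1000)
  raw <- window_correlations(d, list(start = 1, end = 2), p)
  expect_equal(as.numeric(raw), 0)  # orthogonal cells stay orthogonal
  d2 <- make_decomp(U = rbind(c(1, 1), c(1, -1)) / sqrt(2), s = c(3, 2))
  v <- window_correlations(d2, list(start = 1, end = 2), p)
  expect_equal(as.numeric(v), (9 - 4) / 2)  # (3^2 - 2^2)/2 by hand
})

test_that("plug-in MI matches hand cases exactly", {
  # two bins perfectly predicting a balanced binary label: exactly 1 bit
  vals <- c(rep(0, 50), rep(1, 50))
  labs <- c(rep("a", 50), rep("b", 50))
  expect_identical(as.numeric(mutual_information(vals, labs, n_bins = 2)), 1)

  # identical class-conditional histograms: exactly 0
  tab <- rbind(c(10, 20), c(30, 60), c(5, 10))
  expect_identical(mi_from_table(tab), 0)

  # hand-evaluated 2x2 plug-in sum
  tab2 <- rbind(c(30, 10), c(10, 50))
  expect_equal(mi_from_table(tab2), brute_force_mi(tab2), tolerance = 1e-15)

  # degenerate inputs
  expect_true(attr(mutual_information(c(1, 2, 3), c("a", "a", "a")),
                   "degenerate"))
  expect_true(attr(mutual_information(c(2, 2, 2), c("a", "b", "a")),
                   "degenerate"))
  expect_error(mutual_information(1:4, c("a", "b", "c", "a")),
               "at most 2")
})

test_that("MI estimator equals the brute-force sum and respects its bounds", {
  set.seed(21)
  for (rep in 1:50) {
    nb <- sample(2:16, 1)
    tab <- matrix(rpois(nb * 2, 20), nb, 2)
    mi <- mi_from_table(tab)
    expect_equal(mi, brute_force_mi(tab), tolerance = 1e-12)
    py <- colSums(tab) / sum(tab)
    pb <- rowSums(tab) / sum(tab)
    h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
    expect_gte(mi, 0)
    expect_lte(mi, min(h(pb), h(py)) + 1e-12)
  }
})

test_that("merging adjacent bins never increases MI", {
  set.seed(22)
  for (rep in 1:20) {
    nb <- sample(3:16, 1)
    tab <- matrix(rpois(nb * 2, 15), nb, 2)
    k <- sample(nb - 1, 1)
    merged <- tab
    merged[k, ] <- merged[k, ] + merged[k + 1, ]
    merged <- merged[-(k + 1), , drop = FALSE]
    expect_lte(mi_from_table(merged), mi_from_table(tab) + 1e-12)
  }
})

test_that("quantile binning merges ties and caps the bin count", {
  b <- adaptscales:::.bin_quantile(rnorm(1000), 16)
  expect_equal(b$n_bins, 16)
  expect_equal(sort(unique(b$bins)), 1:16)
  # heavily tied values collapse into fewer bins
  b2 <- adaptscales:::.bin_quantile(c(rep(0, 900), rnorm(100)), 16)
  expect_lt(b2$n_bins, 16)
  expect_equal(length(unique(b2$bins)), b2$n_bins)
})

test_that("a profile with all signal in the first window has depth 1", {
  set.seed(23)
  n <- 120
  lab <- rep(c("a", "b"), each = n / 2)
  # signal entirely in components 1..3; deeper components pure noise
  U <- matrix(rnorm(n * 10, sd = 0.02), n, 10)
  U[, 1] <- ifelse(lab == "a", 1, -1) + rnorm(n, sd = 0.05)
  U <- qr.Q(qr(U))
  meta <- data.frame(sample_id = lab, env = lab)
  d <- make_decomp(U = U, s = rep(1, 10), meta = meta)
  p <- mi_profile(d, "env", windows = make_windows(10), pair_budget = 1e4)
  expect_equal(which.max(p$mi), 1L)
  expect_equal(spectral_depth(p), 1L)
  expect_true(all(diff(p$cumulative) >= -1e-15))
  expect_equal(p$cumulative_normalized[length(p$cumulative_normalized)], 1)
})

test_that("spectral depth reads the half-rise of the cumulative curve", {
  mk <- function(mi) adaptscales:::.build_profile("v", make_windows(
    length(mi) + 2), mi, config = list())
  expect_equal(spectral_depth(mk(c(1, rep(0, 27)))), 1L)
  expect_equal(spectral_depth(mk(rep(0.1, 28))), 14L)
  mi <- rep(0.3 / 27, 28); mi[5] <- 0.7
  expect_equal(spectral_depth(mk(mi)), 5L)
  dg <- spectral_depth(mk(rep(0, 28)))
  expect_true(is.na(dg))
  expect_true(attr(dg, "degenerate"))
})

test_that("hierarchy ranking orders by depth with documented tie-breaks", {
  mk <- function(v, mi) adaptscales:::.build_profile(
    v, make_windows(length(mi) + 2), mi, config = list())
  p1 <- mk("alpha", c(1, rep(0, 9)))
  p2 <- mk("beta", c(1, rep(0, 9)))          # identical profile: name tie
  p3 <- mk("gamma", c(rep(0, 5), 1, rep(0, 4)))
  h <- rank_hierarchy(list(p1, p3, p2))
  expect_identical(h$ordering, c("alpha", "beta", "gamma"))
  expect_equal(length(h$ties), 1)
  expect_identical(sort(h$ties[[1]]), c("alpha", "beta"))

  # undefined depth sorts last and is flagged
  p4 <- mk("delta", rep(0, 10))
  h2 <- rank_hierarchy(list(p4, p1, p3))
  expect_identical(h2$ordering[3], "delta")
  expect_true(h2$table$undefined_depth[3])
})

test_that("shuffling cell order leaves MI unchanged with re-indexed pairs", {
  set.seed(24)
  n <- 80
  U <- qr.Q(qr(matrix(rnorm(n * 6), n, 6)))
  lab <- rep(c("x", "y"), length.out = n)
  meta <- data.frame(sample_id = lab, env = lab)
  d <- make_decomp(U = U, s = c(6, 5, 4, 3, 2, 1), meta = meta)
  pairs <- sample_pairs(n, budget = 1e4)
  w <- make_windows(6)
  p1 <- mi_profile(d, "env", windows = w, pairs = pairs)

  perm <- sample(n)
  inv <- order(perm)
  d2 <- make_decomp(U = U[perm, ], s = d$s,
                    meta = meta[perm, , drop = FALSE])
  # re-index the same pairs into the permuted cell order
  pairs2 <- structure(list(i = pmin(inv[pairs$i], inv[pairs$j]),
                           j = pmax(inv[pairs$i], inv[pairs$j]),
                           exhaustive = pairs$exhaustive,
                           budget = pairs$budget, seed = pairs$seed),
                      class = "pair_sample")
  p2 <- mi_profile(d2, "env", windows = w, pairs = pairs2)
  expect_identical(p1$mi, p2$mi)
})

test_that("two-block designs make the per-condition null exact", {
  # with two sample blocks and two label levels, every block permutation
  # yields the same same-label pair structure, so null MI == true MI
  set.seed(25)
  n <- 60
  U <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  meta <- data.frame(sample_id = rep(c("s1", "s2"), each = n / 2),
                     env = rep(c("a", "b"), each = n / 2))
  d <- make_decomp(U = U, s = c(4, 3, 2, 1), meta = meta)
  pairs <- sample_pairs(n, budget = 1e4)
  w <- make_windows(4)
  p <- mi_profile(d, "env", windows = w, pairs = pairs)
  np <- suppressWarnings(  # one block per level: support is trivial here
    null_profile(d, "env", windows = w, pairs = pairs,
                 mode = "per_condition", n_perm = 5, seed = 1))
  for (k in 1:5) expect_equal(np$null_mi[k, ], p$mi, tolerance = 1e-14)
})

test_that("per-cell and per-condition nulls envelope an unrelated label", {
  set.seed(26)
  n <- 200
  U <- qr.Q(qr(matrix(rnorm(n * 6), n, 6)))
  blocks <- rep(sprintf("s%02d", 1:20), each = n / 20)
  env <- rep(rep(c("a", "b"), 10)[1:20], each = n / 20)
  meta <- data.frame(sample_id = blocks, env = env)
  d <- make_decomp(U = U, s = 6:1, meta = meta)
  pairs <- sample_pairs(n, budget = 1e4)
  w <- make_windows(6)
  p <- mi_profile(d, "env", windows = w, pairs = pairs)
  for (mode in c("per_condition", "per_cell")) {
    np <- null_profile(d, "env", windows = w, pairs = pairs, mode = mode,
                       n_perm = 60, seed = 2)
    expect_true(all(np$null_mi >= 0))
    expect_true(all(np$null_q95 >= np$null_mean))
    # label carries no transcriptional signal: profile sits inside the
    # envelope at most windows
    expect_gte(mean(p$mi <= np$null_q95), 0.5)
  }
})

test_that("null_profile validates its preconditions", {
  meta <- data.frame(sample_id = c("s1", "s1", "s2", "s2"),
                     env = c("a", "b", "b", "b"))
  d <- make_decomp(U = diag(4), s = c(4, 3, 2, 1), meta = meta)
  pairs <- sample_pairs(4, budget = 1000)
  expect_error(null_profile(d, "env", windows = make_windows(4),
                            pairs = pairs, mode = "per_condition"),
               "not constant within sample block")
  meta2 <- data.frame(sample_id = c("s1", "s1", "s2", "s2"),
                      env = c("a", "a", "b", "b"))
  d2 <- make_decomp(U = diag(4), s = c(4, 3, 2, 1), meta = meta2)
  expect_warning(null_profile(d2, "env", windows = make_windows(4),
                              pairs = pairs, mode = "per_condition",
                              n_perm = 2),
                 "trivial")
})

test_that("scales_analysis matches the standalone profile computations", {
  set.seed(27)
  n <- 150
  U <- qr.Q(qr(matrix(rnorm(n * 8), n, 8)))
  blocks <- rep(sprintf("s%02d", 1:15), each = 10)
  env <- rep(c("a", "b", "c"), 5)[as.integer(factor(blocks))]
  temp <- rep(c("lo", "hi"), length.out = 15)[as.integer(factor(blocks))]
  meta <- data.frame(sample_id = blocks, env = env, temp = temp)
  d <- make_decomp(U = U, s = 8:1, meta = meta)
  res <- scales_analysis(d, c("env", "temp"), max_pc = 8,
                         null = "per_condition", n_perm = 10, seed = 5)
  w <- res$windows
  pairs <- sample_pairs(n, 2e6, seed = 5)
  for (v in c("env", "temp")) {
    p <- mi_profile(d, v, windows = w, pairs = pairs)
    expect_equal(res$profiles[[v]]$mi, p$mi, tolerance = 1e-14)
  }
  expect_s3_class(res$hierarchy, "hierarchy_ranking")
  expect_error(scales_analysis(d, c("env", "nope"), max_pc = 8),
               "not found")
})
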