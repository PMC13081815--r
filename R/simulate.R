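#' Specification of a synthetic multi-condition single-cell ensemble
#'
#' Parameterizes the planted signal structure emulated by [simulate_scrna()]:
#' a balanced full-factorial grid of environmental cues, each cue's signal
#' planted along one orthonormal gene-loading vector at a chosen spectral
#' depth, a shared leading stress mode applied to all non-reference
#' conditions, a background spectrum of continuous cell-state variation
#' log-linearly interpolated through the cue amplitudes (so each cue sits at
#' its nominal rank of the eigenspectrum), and negative-binomial UMI counts
#' with log-normal library sizes.
#'
#' @param n_genes number of genes (default 1000).
#' @param cells_per_condition cells simulated per condition (default 100).
#' @param cues list of cue descriptors `list(name, levels, depth, effect)`;
#'   `levels` may be an integer (2 or 3) or a character vector of level
#'   names; `depth` is the planted component (1-based); `effect` the per-cell
#'   score standard deviation along the planted loading, in units of
#'   `signal_scale`. The default five cues mirror a yeast multi-environment
#'   ensemble: carbon (depth 2), media (6), osmolarity (10), temperature
#'   (16), ROS (24), with strictly decreasing effects 1.0, 0.8, 0.6, 0.45,
#'   0.35.
#' @param shared_stress_effect amplitude of the leading shared stress mode
#'   applied to every non-reference condition (default 8).
#' @param signal_scale global multiplier converting cue/background effect
#'   units into natural-log expression units (default 3, calibrated so the
#'   leading 30 components of the default ensemble carry roughly 12% of the
#'   total variance, the regime observed in real multi-environment yeast
#'   ensembles).
#' @param baseline_log_mean `c(mean, sd)` of per-gene baseline log abundance.
#' @param dispersion negative-binomial size (inverse dispersion) of UMI
#'   counts (default 2).
#' @param library_size `c(meanlog, sdlog)` of the log-normal per-cell library
#'   size (default median 5000 UMIs).
#' @param n_components number of structured components (default 30).
#' @param seed RNG seed recorded in the output.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000,
                           cells_per_condition = 100,
                           cues = default_cues(),
                           shared_stress_effect = 8,
                           signal_scale = 3,
                           baseline_log_mean = c(0, 1.5),
                           dispersion = 2,
                           library_size = c(log(5000), 0.3),
                           n_components = 30,
                           seed = 0) {
  cues <- lapply(cues, function(cc) {
    if (is.numeric(cc$levels))
      cc$levels <- paste0(cc$name, "_", seq_len(cc$levels))
    stopifnot(length(cc$levels) %in% 2:3, cc$effect >= 0, cc$depth >= 1)
    cc
  })
  depths <- vapply(cues, `[[`, numeric(1), "depth")
  if (anyDuplicated(depths)) stop("planted components must be distinct")
  if (any(depths > n_components))
    stop("planted component exceeds n_components")
  structure(list(n_genes = n_genes,
                 cells_per_condition = cells_per_condition,
                 cues = cues,
                 shared_stress_effect = shared_stress_effect,
                 signal_scale = signal_scale,
                 baseline_log_mean = baseline_log_mean,
                 dispersion = dispersion,
                 library_size = library_size,
                 n_components = n_components,
                 seed = seed),
            class = "synthetic_spec")
}

#' Default five-cue structure for the synthetic ensemble
#' @return List of cue descriptors (see [synthetic_spec()]).
#' @export
default_cues <- function() {
  list(
    list(name = "carbon", levels = c("glucose", "ethanol_glycerol"),
         depth = 2, effect = 1.0),
    list(name = "media", levels = c("YP", "SC"), depth = 6, effect = 0.8),
    list(name = "osmolarity", levels = c("isotonic", "KCl", "sorbitol"),
         depth = 10, effect = 0.6),
    list(name = "temperature", levels = c("30C", "37C"),
         depth = 16, effect = 0.45),
    list(name = "ros", levels = c("none", "H2O2"), depth = 24, effect = 0.35)
  )
}

# centered level codes: 2 levels -> (-1, 1); 3 levels -> (-1, 0, 1)
.cue_code <- function(n_levels) {
  if (n_levels == 2) c(-1, 1) else c(-1, 0, 1)
}

# background per-component score sds, log-linearly interpolated through the
# planted cue amplitudes so that empirical rank tracks planted depth
.background_sds <- function(depths, amps, n_components) {
  pos <- amps > 0
  if (!any(pos)) return(rep(0, n_components))
  depths <- depths[pos]; amps <- amps[pos]
  ord <- order(depths)
  dpts <- depths[ord]; apts <- log(amps[ord])
  ks <- seq_len(n_components)
  if (length(dpts) == 1) return(exp(rep(apts, n_components)))
  f <- stats::approx(dpts, apts, xout = ks, rule = 2)$y
  # linear extrapolation beyond the planted range
  sl1 <- (apts[2] - apts[1]) / (dpts[2] - dpts[1])
  m <- length(dpts)
  sl2 <- (apts[m] - apts[m - 1]) / (dpts[m] - dpts[m - 1])
  f[ks < dpts[1]] <- apts[1] + sl1 * (ks[ks < dpts[1]] - dpts[1])
  f[ks > dpts[m]] <- apts[m] + sl2 * (ks[ks > dpts[m]] - dpts[m])
  exp(f)
}

#' Simulate a multi-condition single-cell UMI ensemble with planted cues
#'
#' Builds orthonormal gene-loading vectors by QR orthogonalization of a seeded
#' Gaussian matrix; composes per-cell log-means from a per-gene baseline, a
#' shared leading stress mode (all non-reference conditions), each cue's
#' centered level code times its effect along its planted loading, and
#' background cell-state scores with sds interpolated through the cue
#' amplitudes; converts log-means to expected counts through a softmax times a
#' log-normal library size; and draws negative-binomial UMI counts. Metadata
#' carries every cue label plus `sample_id` (one sample per condition).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts` (a [count_matrix] with metadata) and
#'   `ground_truth` (planted ordering, depths, loadings, codes, background
#'   sds, per-condition latent means and all noise parameters).
#' @export
simulate_scrna <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    ng <- spec$n_genes
    nk <- spec$n_components
    cues <- spec$cues
    depths <- vapply(cues, `[[`, numeric(1), "depth")
    nlev <- vapply(cues, function(cc) length(cc$levels), integer(1))
    grid <- do.call(expand.grid,
                    c(lapply(cues, function(cc) cc$levels),
                      list(stringsAsFactors = FALSE)))
    names(grid) <- vapply(cues, `[[`, character(1), "name")
    n_cond <- nrow(grid)
    cond_id <- sprintf("cond%02d", seq_len(n_cond))

    # orthonormal loadings
    G <- qr.Q(qr(matrix(stats::rnorm(ng * nk), ng, nk)))
    baseline <- stats::rnorm(ng, spec$baseline_log_mean[1],
                             spec$baseline_log_mean[2])

    # per-condition code per cue, centered
    zc <- sapply(seq_along(cues), function(ci) {
      code <- .cue_code(nlev[ci])
      code[match(grid[[ci]], cues[[ci]]$levels)]
    })
    code_sd <- vapply(nlev, function(l) stats::sd(.cue_code(l)) *
                        sqrt((l - 1) / l), numeric(1))  # population sd
    amps <- vapply(cues, `[[`, numeric(1), "effect") * code_sd *
      spec$signal_scale
    tau <- .background_sds(depths, amps, nk)
    tau[1] <- 0            # component 1 carries the shared stress mode
    tau[depths] <- 0       # cue components carry only the cue signal

    is_ref <- seq_len(n_cond) == 1  # first grid row = all first levels

    n_cells <- n_cond * spec$cells_per_condition
    cond_of_cell <- rep(seq_len(n_cond), each = spec$cells_per_condition)

    # structured per-cell scores on each component
    scores <- matrix(0, n_cells, nk)
    scores[, 1] <- spec$shared_stress_effect * spec$signal_scale *
      as.numeric(!is_ref[cond_of_cell])
    for (ci in seq_along(cues)) {
      scores[, depths[ci]] <- cues[[ci]]$effect * spec$signal_scale *
        zc[cond_of_cell, ci]
    }
    bg <- which(tau > 0)
    if (length(bg) > 0) {
      scores[, bg] <- scores[, bg] +
        matrix(stats::rnorm(n_cells * length(bg)), n_cells) %*%
        diag(tau[bg], nrow = length(bg))
    }

    log_mean <- scores %*% t(G)
    log_mean <- sweep(log_mean, 2, baseline, "+")
    p <- exp(log_mean)
    p <- p / rowSums(p)
    lib <- stats::rlnorm(n_cells, spec$library_size[1], spec$library_size[2])
    mu <- p * lib
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = spec$dispersion),
                     n_cells, ng)

    meta <- data.frame(sample_id = cond_id[cond_of_cell],
                       grid[cond_of_cell, , drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
    cm <- count_matrix(counts,
                       cell_ids = sprintf("cell%05d", seq_len(n_cells)),
                       gene_ids = sprintf("g%04d", seq_len(ng)),
                       cell_meta = meta)
    gt <- list(
      ordering = names(grid)[order(depths)],
      depths = stats::setNames(depths, names(grid)),
      effects = stats::setNames(vapply(cues, `[[`, numeric(1), "effect"),
                                names(grid)),
      realized_score_sds = stats::setNames(amps, names(grid)),
      background_sds = tau,
      loadings = G,
      baseline = baseline,
      condition_table = data.frame(condition = cond_id, grid,
                                   reference = is_ref,
                                   stringsAsFactors = FALSE),
      cue_codes = zc,
      condition_scores_latent = NULL,
      spec = spec
    )
    list(counts = cm, ground_truth = gt)
  })
}

#' Simulate a bulk dual-stress RNA-seq design with controlled epistasis
#'
#' Per-gene log2 expression means follow
#' `base + beta_h * heat + beta_o * salt + gamma * heat * salt`; `gamma` is 0
#' under independence and takes the planted value for genes of flagged sets.
#' Means are laid out in log2-CPM space (so the log-additive structure is
#' exact after CPM normalization with pseudocount 1) and a balancer gene
#' absorbs the remainder of each library, keeping every sample's expected
#' total equal and the design free of composition offsets. Counts are
#' negative-binomial; `noise = FALSE` returns expected counts exactly.
#'
#' @param independence if `TRUE`, `gamma = 0` everywhere except planted sets.
#' @param epistasis_map named numeric vector of per-set interaction shifts in
#'   log2 units (e.g. `c(HSR_like = -1)`); each set receives `set_size`
#'   genes.
#' @param n_genes number of genes (default 2000, excluding the balancer).
#' @param set_size genes per planted set (default 100).
#' @param base_log2 `c(mean, sd)` of baseline log2 CPM (default 7, 1.5).
#' @param beta_sd sd of the per-gene single-stress effects (default 1).
#' @param dispersion negative-binomial size (default 1000, i.e.
#'   technical-replicate-level variation).
#' @param library_size expected reads per sample (default 3e7).
#' @param n_reps replicates per condition (default 3).
#' @param noise draw counts (`TRUE`) or return expected counts (`FALSE`).
#' @param seed RNG seed.
#' @return list with `bulk` (a [bulk_counts()]) and `ground_truth` (betas,
#'   per-gene gamma, set memberships, parameters).
#' @export
simulate_bulk <- function(independence = TRUE, epistasis_map = NULL,
                          n_genes = 2000, set_size = 100,
                          base_log2 = c(7, 1.5), beta_sd = 1,
                          dispersion = 1000, library_size = 3e7,
                          n_reps = 3, noise = TRUE, seed = 0) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  .with_seed(seed, {
    base <- stats::rnorm(n_genes, base_log2[1], base_log2[2])
    beta_h <- stats::rnorm(n_genes, 0, beta_sd)
    beta_o <- stats::rnorm(n_genes, 0, beta_sd)
    gamma <- rep(0, n_genes)
    sets <- list()
    if (!is.null(epistasis_map)) {
      if (is.null(names(epistasis_map))) stop("epistasis_map must be named")
      free <- seq_len(n_genes)
      for (nm in names(epistasis_map)) {
        idx <- free[seq_len(set_size)]
        free <- setdiff(free, idx)
        gamma[idx] <- epistasis_map[[nm]]
        # planted sets are stress-responsive: induced by heat
        beta_h[idx] <- stats::rnorm(set_size, 2, 0.5)
        sets[[nm]] <- sprintf("g%04d", idx)
      }
    }
    if (!independence && is.null(epistasis_map))
      stop("independence = FALSE requires an epistasis_map")
    design <- expand.grid(heat = c("-", "+"), salt = c("-", "+"),
                          rep = seq_len(n_reps), stringsAsFactors = FALSE)
    design$sample <- sprintf("s%02d", seq_len(nrow(design)))
    h <- as.numeric(design$heat == "+")
    o <- as.numeric(design$salt == "+")
    # expected CPM laid out so log2(cpm + 1) is exactly log-additive
    log2_cpm1 <- outer(base, rep(1, nrow(design))) +
      outer(beta_h, h) + outer(beta_o, o) + outer(gamma, h * o)
    # genes driven below zero expression in a condition are silenced there;
    # exact log-additivity holds for the (vast) unclamped majority
    cpm <- pmax(2^log2_cpm1 - 1, 0)
    clamped <- which(apply(log2_cpm1 < 0, 1, any))
    tot <- colSums(cpm)
    if (any(tot >= 1e6))
      stop("expected CPM exceeds the library; lower base_log2 or n_genes")
    cpm <- rbind(cpm, 1e6 - tot)  # balancer gene
    mu <- cpm * library_size / 1e6
    counts <- if (noise) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
             nrow(mu), ncol(mu))
    } else mu
    rownames(counts) <- c(sprintf("g%04d", seq_len(n_genes)), "balancer")
    colnames(counts) <- design$sample
    des <- data.frame(heat = design$heat, salt = design$salt,
                      replicate = design$rep, row.names = design$sample,
                      stringsAsFactors = FALSE)
    gt <- list(base = base, beta_h = beta_h, beta_o = beta_o,
               gamma = gamma, sets = sets,
               clamped_genes = sprintf("g%04d", clamped),
               params = list(n_genes = n_genes, set_size = set_size,
                             dispersion = dispersion,
                             library_size = library_size,
                             n_reps = n_reps, noise = noise, seed = seed))
    list(bulk = bulk_counts(counts, des), ground_truth = gt)
  })
}

#' Simulate a sucrose-gradient A260 trace with known peak areas
#'
#' Sum of Gaussian peaks with specified integrated areas, plus linear baseline
#' drift and Gaussian noise, clipped at zero absorbance.
#'
#' @param peaks list of `list(center, sd, area)`, ordered by center. The
#'   default mimics a yeast gradient: 40S/60S shoulders, a dominant 80S
#'   monosome, and a decaying polysome series.
#' @param drift `c(intercept, slope)` of the linear baseline.
#' @param noise_sd Gaussian noise sd (absorbance units).
#' @param grid sampling positions.
#' @param seed RNG seed.
#' @return list with `trace` (an [absorbance_trace()]) and `ground_truth`
#'   (peak table, monosome/polysome areas taking the largest first-half peak
#'   as the monosome, and the implied P/M ratio).
#' @export
simulate_trace <- function(peaks = default_trace_peaks(),
                           drift = c(0.01, 0.001), noise_sd = 0.002,
                           grid = seq(0, 8, by = 0.005), seed = 0) {
  centers <- vapply(peaks, `[[`, numeric(1), "center")
  if (is.unsorted(centers)) stop("peaks must be ordered by center")
  sds <- vapply(peaks, `[[`, numeric(1), "sd")
  areas <- vapply(peaks, `[[`, numeric(1), "area")
  sep <- diff(centers)
  if (length(sep) > 0 &&
      any(sep < 2 * (utils::head(sds, -1) + utils::tail(sds, -1))))
    warning("adjacent peaks overlap strongly; areas may not be identifiable")
  .with_seed(seed, {
    y <- drift[1] + drift[2] * grid
    for (p in peaks) y <- y + p$area * stats::dnorm(grid, p$center, p$sd)
    if (noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, noise_sd)
    y <- pmax(y, 0)
    half <- grid[1] + (grid[length(grid)] - grid[1]) / 2
    first_half <- centers <= half
    mono_idx <- which(first_half)[which.max(areas[first_half])]
    area_mono <- areas[mono_idx]
    area_poly <- sum(areas[seq_along(areas) > mono_idx])
    gt <- list(peaks = data.frame(center = centers, sd = sds, area = areas),
               monosome_index = mono_idx,
               area_mono = area_mono, area_poly = area_poly,
               pm_ratio = area_poly / area_mono,
               drift = drift, noise_sd = noise_sd, seed = seed)
    list(trace = absorbance_trace(grid, y), ground_truth = gt)
  })
}

#' Default Gaussian peaks of the simulated gradient trace
#' @return List of peak descriptors for [simulate_trace()].
#' @export
default_trace_peaks <- function() {
  list(list(center = 0.8, sd = 0.10, area = 0.20),
       list(center = 1.4, sd = 0.10, area = 0.30),
       list(center = 2.2, sd = 0.12, area = 1.50),
       list(center = 3.4, sd = 0.12, area = 0.35),
       list(center = 4.2, sd = 0.12, area = 0.25),
       list(center = 5.0, sd = 0.12, area = 0.15),
       list(center = 5.8, sd = 0.12, area = 0.08))
}

#' Simulate an OD600 growth curve
#'
#' Models: `exponential` (`od0 * exp(r t)`), `logistic` (rate `r`, capacity
#' `K`), `diauxic` (two exponential phases `r1`, `r2` separated by a lag, with
#' intermediate plateau `plateau1` and final capacity `K`). Measurement noise
#' is multiplicative log-normal (`noise_sd` on the log-OD scale), the
#' proportional error regime of plate readers in the fitted OD range.
#'
#' @param model `"exponential"`, `"logistic"` or `"diauxic"`.
#' @param params named list of model parameters (see Details above); defaults
#'   r = 0.4/h, od0 = 0.02, K = 1.
#' @param interval_min sampling interval in minutes (default 20).
#' @param horizon_h duration in hours (default 48).
#' @param noise_sd log-scale measurement noise sd.
#' @param seed RNG seed.
#' @return list with `curve` (a [growth_curve()]) and `ground_truth`.
#' @export
simulate_growth <- function(model = c("exponential", "logistic", "diauxic"),
                            params = list(), interval_min = 20,
                            horizon_h = 48, noise_sd = 0, seed = 0) {
  model <- match.arg(model)
  p <- utils::modifyList(
    list(r = 0.4, od0 = 0.02, K = 1.0,
         r1 = 0.4, r2 = 0.15, plateau1 = 0.4, lag = 4),
    params)
  if (any(unlist(p[c("r", "r1", "r2")]) < 0)) stop("rates must be positive")
  t <- seq(0, horizon_h, by = interval_min / 60)
  od <- switch(model,
    exponential = p$od0 * exp(p$r * t),
    logistic = p$K * p$od0 * exp(p$r * t) /
      (p$K + p$od0 * (exp(p$r * t) - 1)),
    diauxic = {
      t1 <- log(p$plateau1 / p$od0) / p$r1
      t2 <- t1 + p$lag
      t3 <- t2 + log(p$K / p$plateau1) / p$r2
      lnod <- log(p$od0) + p$r1 * pmin(t, t1) +
        p$r2 * pmax(pmin(t, t3) - t2, 0)
      exp(lnod)
    })
  .with_seed(seed, {
    if (noise_sd > 0) od <- od * exp(stats::rnorm(length(t), 0, noise_sd))
    gt <- c(list(model = model, noise_sd = noise_sd, seed = seed), p)
    if (model == "diauxic") gt$phase_rates <- c(p$r1, p$r2)
    list(curve = growth_curve(t, od), ground_truth = gt)
  })
}

#' Simulate a competitive-fitness count series
#'
#' The expected test-strain fraction follows a logistic trajectory in
#' `s * day`; per-day counts are binomial draws of `n_events` cytometry
#' events (or exact expected counts when `sampling = FALSE`).
#'
#' @param s selection coefficient per day.
#' @param n_events cytometry events per day (default 1e4).
#' @param days measurement days (default 0:3).
#' @param x0 initial test-strain fraction (default 0.5).
#' @param sampling draw binomial counts (`TRUE`) or return expected counts.
#' @param seed RNG seed.
#' @return list with `series` (a [competition_series()]) and `ground_truth`.
#' @export
simulate_competition <- function(s, n_events = 1e4, days = 0:3, x0 = 0.5,
                                 sampling = TRUE, seed = 0) {
  if (n_events <= 0) stop("n_events must be positive")
  logit <- log(x0 / (1 - x0)) + s * days
  x <- 1 / (1 + exp(-logit))
  if (any(n_events * x < 1) || any(n_events * (1 - x) < 1))
    stop("selection coefficient too extreme: expected counts fall below 1")
  .with_seed(seed, {
    if (sampling) {
      test <- stats::rbinom(length(days), n_events, x)
      ref <- n_events - test
      if (any(test == 0) || any(ref == 0))
        stop("sampled zero count; increase n_events or moderate s")
    } else {
      test <- n_events * x
      ref <- n_events * (1 - x)
    }
    gt <- list(s = s, x0 = x0, n_events = n_events, days = days,
               expected_fraction = x, sampling = sampling, seed = seed)
    list(series = competition_series(days, test, ref), ground_truth = gt)
  })
}
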