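#' Absorbance trace container
#'
#' @param position strictly increasing positions (gradient fraction or
#'   arbitrary units).
#' @param a260 non-negative absorbance values, same length (>= 10).
#' @return Object of class `absorbance_trace`.
#' @export
absorbance_trace <- function(position, a260) {
  position <- as.numeric(position); a260 <- as.numeric(a260)
  if (length(position) != length(a260)) stop("columns must align")
  if (length(position) < 10) stop("trace must have at least 10 points")
  if (any(!is.finite(position)) || any(!is.finite(a260)))
    stop("non-finite values in trace")
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  if (any(a260 < 0)) stop("a260 must be non-negative")
  structure(list(position = position, a260 = a260),
            class = "absorbance_trace")
}

#' Read a two-column absorbance trace TSV (position, A260)
#' @param path TSV file with header.
#' @return An [absorbance_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  tab <- utils::read.delim(path, header = TRUE)
  absorbance_trace(tab[[1]], tab[[2]])
}

.moving_average <- function(y, k) {
  stopifnot(k %% 2 == 1)
  if (k == 1) return(y)
  as.numeric(stats::filter(y, rep(1 / k, k), sides = 2)) ->
    sm
  half <- (k - 1) / 2
  n <- length(y)
  for (t in seq_len(half)) {           # shrink the window at the edges
    sm[t] <- mean(y[1:(t + half)])
    sm[n - t + 1] <- mean(y[(n - t + 1 - half):n])
  }
  sm
}

.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Locate monosome and polysome peak regions in an A260 trace
#'
#' The trace is smoothed with a centered moving average; the 80S monosome peak
#' is taken as the largest local maximum in the first half of the trace
#' (positions past the leading 40S/60S shoulder region), bounded by its
#' flanking local minima; the polysome region runs from the minimum after the
#' 80S peak to the end of the trace. Manual bounds, when supplied, override
#' detection and are returned verbatim.
#'
#' @param t an [absorbance_trace()].
#' @param smoothing_window odd moving-average width (default 5).
#' @param monosome_bounds,polysome_bounds optional manual `(lo, hi)` position
#'   bounds; supplying both skips detection.
#' @return Object of class `peak_regions` with `monosome_bounds`,
#'   `polysome_bounds`, `source` (`"manual"` or `"automatic"`).
#' @export
detect_regions <- function(t, smoothing_window = 5,
                           monosome_bounds = NULL, polysome_bounds = NULL) {
  stopifnot(inherits(t, "absorbance_trace"))
  if (!is.null(monosome_bounds) && !is.null(polysome_bounds)) {
    return(.peak_regions(monosome_bounds, polysome_bounds, "manual", t))
  }
  y <- .moving_average(t$a260, smoothing_window)
  pos <- t$position
  maxima <- .local_maxima(y)
  if (length(maxima) == 0)
    stop("no peaks found; supply manual monosome/polysome bounds")
  half <- pos[1] + (pos[length(pos)] - pos[1]) / 2
  cand <- maxima[pos[maxima] <= half]
  if (length(cand) == 0)
    stop("no monosome peak in the first half of the trace; ",
         "supply manual bounds")
  # earliest of the near-tied tallest candidates (80S precedes polysomes)
  mono_idx <- cand[which(y[cand] >= max(y[cand]) * (1 - 1e-9))[1]]
  minima <- .local_maxima(-y)
  left <- c(1L, minima[minima < mono_idx])
  right <- c(minima[minima > mono_idx], length(y))
  lo <- max(left)
  hi <- min(right)
  if (hi >= length(y))
    stop("no minimum after the 80S peak; supply manual bounds")
  .peak_regions(c(pos[lo], pos[hi]), c(pos[hi], pos[length(pos)]),
                "automatic", t)
}

.peak_regions <- function(mono, poly, source, t) {
  mono <- as.numeric(mono); poly <- as.numeric(poly)
  rng <- range(t$position)
  for (b in list(mono, poly)) {
    if (length(b) != 2 || b[1] >= b[2]) stop("bounds must satisfy lo < hi")
    if (b[1] < rng[1] || b[2] > rng[2]) stop("bounds outside trace range")
  }
  if (mono[2] > poly[1] + 1e-12) stop("monosome region must precede polysomes")
  structure(list(monosome_bounds = mono, polysome_bounds = poly,
                 source = source),
            class = "peak_regions")
}

#' Integrate an A260 trace over a region
#'
#' Trapezoidal integral of the baseline-subtracted absorbance, clipped at 0.
#' Baselines: `"linear_endpoints"` (straight line between the region's
#' endpoint absorbances; default), `"min_in_region"` (constant minimum), or
#' `"none"` (raw trapezoid).
#'
#' @param t an [absorbance_trace()].
#' @param bounds numeric `(lo, hi)` in position units, inside the trace.
#' @param baseline baseline rule.
#' @return Integrated area (non-negative for the subtracting baselines).
#' @export
integrate_region <- function(t, bounds,
                             baseline = c("linear_endpoints",
                                          "min_in_region", "none")) {
  stopifnot(inherits(t, "absorbance_trace"))
  baseline <- match.arg(baseline)
  bounds <- as.numeric(bounds)
  if (bounds[1] >= bounds[2]) stop("bounds must satisfy lo < hi")
  if (bounds[1] < t$position[1] || bounds[2] > t$position[length(t$position)])
    stop("bounds outside trace")
  # resample exact endpoints so the integral covers [lo, hi] precisely
  inside <- t$position > bounds[1] & t$position < bounds[2]
  x <- c(bounds[1], t$position[inside], bounds[2])
  y <- c(stats::approx(t$position, t$a260, xout = bounds[1])$y,
         t$a260[inside],
         stats::approx(t$position, t$a260, xout = bounds[2])$y)
  base <- switch(baseline,
    linear_endpoints = y[1] + (y[length(y)] - y[1]) *
      (x - x[1]) / (x[length(x)] - x[1]),
    min_in_region = rep(min(y), length(y)),
    none = rep(0, length(y)))
  yy <- pmax(y - base, 0)
  sum(diff(x) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Polysome-to-monosome ratio
#'
#' Ratio of the integrated polysome area to the integrated 80S monosome area.
#'
#' @param t an [absorbance_trace()].
#' @param regions a [detect_regions()] result (or manual `peak_regions`).
#' @param baseline integration baseline (see [integrate_region()]).
#' @return Object of class `polysome_quant` with `area_mono`, `area_poly`,
#'   `pm_ratio` (`NA` with a flag when the monosome area is not positive),
#'   `baseline`, `regions`.
#' @export
pm_ratio <- function(t, regions, baseline = "linear_endpoints") {
  stopifnot(inherits(regions, "peak_regions"))
  area_mono <- integrate_region(t, regions$monosome_bounds, baseline)
  area_poly <- integrate_region(t, regions$polysome_bounds, baseline)
  ratio <- if (area_mono > 0) area_poly / area_mono else
    structure(NA_real_, degenerate = TRUE)
  structure(list(area_mono = area_mono, area_poly = area_poly,
                 pm_ratio = ratio, baseline = baseline, regions = regions),
            class = "polysome_quant")
}

#' @exportS3Method base::print
print.polysome_quant <- function(x, ...) {
  cat(sprintf("polysome_quant: P/M = %.4f (poly %.4f / mono %.4f, %s baseline, %s regions)\n",
              x$pm_ratio, x$area_poly, x$area_mono, x$baseline,
              x$regions$source))
  invisible(x)
}

#' Growth curve container
#'
#' @param time_h strictly increasing times in hours.
#' @param od600 positive optical densities (after blank subtraction).
#' @param blank optional constant blank subtracted from `od600`.
#' @return Object of class `growth_curve`.
#' @export
growth_curve <- function(time_h, od600, blank = 0) {
  time_h <- as.numeric(time_h); od600 <- as.numeric(od600) - blank
  if (length(time_h) != length(od600)) stop("columns must align")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  structure(list(time_h = time_h, od600 = od600, blank = blank),
            class = "growth_curve")
}

#' Read a growth curve TSV (time_h, OD600)
#' @param path TSV file with header.
#' @param blank constant blank to subtract.
#' @return A [growth_curve()].
#' @export
read_growth_curve <- function(path, blank = 0) {
  if (!file.exists(path)) stop("missing file: ", path)
  tab <- utils::read.delim(path, header = TRUE)
  growth_curve(tab[[1]], tab[[2]], blank = blank)
}

#' Maximum specific growth rate from a growth curve
#'
#' Ordinary least-squares slope of `ln(OD)` versus time over every contiguous
#' window of `window_points` measurements whose ODs all lie within
#' `[od_min, od_max]`; returns the maximum slope, its window, and the window
#' fit r-squared. The default OD floor excludes the near-blank regime where
#' measurement noise dominates. For turbidostat-style rates estimated on a
#' fixed OD band (e.g. 0.4-0.5), set `od_min`/`od_max` accordingly.
#'
#' @param g a [growth_curve()].
#' @param window_points points per fitting window (default 5, about 100
#'   minutes at 20-minute sampling).
#' @param od_min,od_max inclusive OD eligibility bounds (`od_max = NULL`
#'   means unbounded above).
#' @return list with `rate` (per hour), `window` (time span), `indices`,
#'   `r_squared`.
#' @export
max_growth_rate <- function(g, window_points = 5, od_min = 0.05,
                            od_max = NULL) {
  stopifnot(inherits(g, "growth_curve"), window_points >= 2)
  ok <- g$od600 >= od_min & (if (is.null(od_max)) TRUE else
    g$od600 <= od_max) & g$od600 > 0
  n <- length(g$time_h)
  best <- NULL
  for (s in seq_len(n - window_points + 1)) {
    idx <- s:(s + window_points - 1)
    if (!all(ok[idx])) next
    tt <- g$time_h[idx]
    ll <- log(g$od600[idx])
    sl <- stats::cov(tt, ll) / stats::var(tt)
    if (is.null(best) || sl > best$rate) {
      r2 <- if (stats::sd(ll) == 0) 1 else stats::cor(tt, ll)^2
      best <- list(rate = sl, window = range(tt), indices = idx,
                   r_squared = r2)
    }
  }
  if (is.null(best))
    stop("no contiguous window of ", window_points,
         " measurements within the OD range")
  best
}

#' Detect diauxic (biphasic) growth
#'
#' Computes a smoothed instantaneous specific growth-rate series
#' (`d ln OD / dt`) and declares diauxie when two local rate maxima are
#' separated by a trough below `trough_fraction` times the first maximum, with
#' the second maximum above `rate_floor`. This criterion is an explicit
#' operationalization of the biphasic-growth phenotype and is flagged as such.
#'
#' @param g a [growth_curve()].
#' @param trough_fraction trough depth relative to the first maximum
#'   (default 0.5).
#' @param rate_floor minimum second-phase rate, per hour (default 0.05).
#' @param smoothing_window odd moving-average width for the rate series.
#' @return list with `diauxic` (logical), `phase_rates` (rates at the
#'   detected maxima), `trough_rate`, and `criterion = "operational"`.
#' @export
detect_diauxie <- function(g, trough_fraction = 0.5, rate_floor = 0.05,
                           smoothing_window = 5) {
  stopifnot(inherits(g, "growth_curve"))
  if (length(g$time_h) < 2 * smoothing_window + 3)
    stop("too few points for diauxie detection")
  if (any(g$od600 <= 0)) stop("OD must be positive")
  rate <- diff(log(g$od600)) / diff(g$time_h)
  rate <- .moving_average(rate, smoothing_window)
  peaks <- .local_maxima(rate)
  peaks <- peaks[rate[peaks] > rate_floor]
  if (length(peaks) < 2)
    return(list(diauxic = FALSE,
                phase_rates = if (length(peaks)) rate[peaks] else
                  max(rate), trough_rate = NA_real_,
                criterion = "operational"))
  # best pair: first peak, then any later peak with a deep enough trough
  p1 <- peaks[1]
  for (p2 in peaks[-1]) {
    trough <- min(rate[p1:p2])
    if (trough < trough_fraction * rate[p1] && rate[p2] > rate_floor) {
      return(list(diauxic = TRUE, phase_rates = c(rate[p1], rate[p2]),
                  trough_rate = trough, criterion = "operational"))
    }
  }
  list(diauxic = FALSE, phase_rates = rate[peaks], trough_rate = NA_real_,
       criterion = "operational")
}

#' Competition count series container
#'
#' @param day integer days (>= 2 time points).
#' @param count_test,count_reference positive counts per day.
#' @return Object of class `competition_series`.
#' @export
competition_series <- function(day, count_test, count_reference) {
  day <- as.numeric(day)
  if (length(day) < 2) stop("need at least 2 time points")
  if (length(count_test) != length(day) ||
      length(count_reference) != length(day)) stop("columns must align")
  if (any(count_test <= 0) || any(count_reference <= 0))
    stop("counts must be positive")
  structure(list(day = day, count_test = as.numeric(count_test),
                 count_reference = as.numeric(count_reference)),
            class = "competition_series")
}

#' Read a competition series TSV (day, count_test, count_reference)
#' @param path TSV file with header.
#' @return A [competition_series()].
#' @export
read_competition <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  tab <- utils::read.delim(path, header = TRUE)
  competition_series(tab[[1]], tab[[2]], tab[[3]])
}

#' Competitive-fitness selection coefficient
#'
#' OLS slope of `ln(count_test / count_reference)` against day; positive means
#' the test strain is fitter. Daily dilution applied equally to both strains
#' cancels in the ratio and needs no correction.
#'
#' @param c a [competition_series()].
#' @return list with `s` (per day), `intercept`, `r_squared`.
#' @export
competitive_fitness <- function(c) {
  stopifnot(inherits(c, "competition_series"))
  lr <- log(c$count_test / c$count_reference)
  s <- stats::cov(c$day, lr) / stats::var(c$day)
  intercept <- mean(lr) - s * mean(c$day)
  r2 <- if (stats::sd(lr) == 0) 1 else stats::cor(c$day, lr)^2
  list(s = s, intercept = intercept, r_squared = r2)
}
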