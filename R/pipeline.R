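#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file) with the sections below;
#' unknown keys anywhere are rejected before any computation. Every random
#' operation's seed defaults to 0 and is echoed into the run manifest.
#'
#' Sections: `input` (either `counts` + `format` + optional `meta`, or
#' `simulate: scrna` with an optional `spec` override list), `qc`
#' (`min_genes`, `max_genes`, `min_counts`, `min_cells_per_gene`),
#' `normalize` (`target_sum`), `svd` (`components`, `center`), `scales`
#' (`variables`, `width`, `stride`, `max_pc`, `bins`, `pairs`, `null`,
#' `nperm`, `depth_threshold`), optional `epistasis` (`counts`, `design`,
#' `sets`, `reference`), optional `physiology` (`trace`, `growth`,
#' `competition`), `seed`, `out`.
#'
#' @param config named list or path to a YAML file.
#' @return The validated configuration with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- list(
    input = c("counts", "format", "meta", "simulate", "spec"),
    qc = c("min_genes", "max_genes", "min_counts", "min_cells_per_gene"),
    normalize = "target_sum",
    svd = c("components", "center"),
    scales = c("variables", "width", "stride", "max_pc", "bins", "pairs",
               "null", "nperm", "depth_threshold"),
    epistasis = c("counts", "design", "sets", "reference"),
    physiology = c("trace", "growth", "competition"),
    seed = NULL, out = NULL)
  unknown <- setdiff(names(config), names(allowed))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), names(allowed))) {
    keys <- allowed[[sec]]
    if (is.null(keys)) next
    bad <- setdiff(names(config[[sec]]), keys)
    if (length(bad) > 0)
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  if (is.null(config$input)) stop("configuration requires an 'input' section")
  if (is.null(config$out)) stop("configuration requires an 'out' directory")
  defaults <- list(
    qc = list(min_genes = 200, max_genes = 4000, min_counts = 300,
              min_cells_per_gene = 10),
    normalize = list(target_sum = 10000),
    svd = list(components = 30, center = TRUE),
    scales = list(variables = NULL, width = 3, stride = 1, max_pc = 30,
                  bins = 16, pairs = 2e6, null = "per_condition",
                  nperm = 100, depth_threshold = 0.5),
    seed = 0)
  for (sec in names(defaults)) {
    if (sec == "seed") {
      if (is.null(config$seed)) config$seed <- defaults$seed
    } else {
      config[[sec]] <- utils::modifyList(defaults[[sec]],
                                         as.list(config[[sec]]))
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes preprocess (read or simulate counts, QC, normalize) -> SVD ->
#' SCALES, plus epistasis and physiology stages when their inputs are present.
#' All numeric outputs are written as text with full precision, so a rerun
#' with the same configuration and seed is byte-identical; the manifest
#' records every parameter, seed and stage output for reproducibility.
#'
#' @param config named list or YAML path (see [validate_config()]).
#' @return The run manifest (invisibly), also written to
#'   `<out>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("adaptscales")),
                   seed = config$seed, stages = list(),
                   config = config[setdiff(names(config), "out")])
  t0 <- Sys.time()

  # --- preprocess ---------------------------------------------------------
  inp <- config$input
  if (!is.null(inp$simulate)) {
    if (!identical(inp$simulate, "scrna"))
      stop("only 'scrna' simulation is supported as pipeline input")
    spec_args <- if (is.null(inp$spec)) list() else inp$spec
    spec_args$seed <- config$seed
    sim <- simulate_scrna(do.call(synthetic_spec, spec_args))
    cm <- sim$counts
  } else {
    cm <- read_counts(inp$counts, format = inp$format,
                      cell_meta = inp$meta)
  }
  qc <- config$qc
  filtered <- qc_filter(cm, qc_thresholds(qc$min_genes, qc$max_genes,
                                          qc$min_counts,
                                          qc$min_cells_per_gene))
  report <- attr(filtered, "filter_report")
  jsonlite::write_json(report, file.path(out, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  norm <- normalize_log(filtered, target_sum = config$normalize$target_sum)
  manifest$stages$preprocess <- list(cells = nrow(norm$values),
                                     genes = ncol(norm$values),
                                     filter_report = report)

  # --- svd ----------------------------------------------------------------
  d <- decompose(norm, K = config$svd$components,
                 center = config$svd$center, seed = config$seed)
  vf <- variance_fractions(d)
  .write_tsv(data.frame(component = seq_len(d$K),
                        singular_value = d$s,
                        variance_fraction = vf$fractions,
                        cumulative = vf$cumulative),
             file.path(out, "variance_spectrum.tsv"))
  top <- do.call(rbind, lapply(seq_len(min(d$K, 30)), function(k)
    cbind(component = k, top_loadings(d, k, 25))))
  .write_tsv(top, file.path(out, "top_loadings.tsv"))
  manifest$stages$svd <- list(K = d$K, centered = d$centered,
                              total_variance = d$total_variance)

  # --- scales -------------------------------------------------------------
  sc <- config$scales
  variables <- sc$variables
  if (is.null(variables))
    variables <- setdiff(names(norm$cell_meta), "sample_id")
  res <- scales_analysis(d, variables, width = sc$width,
                         stride = sc$stride, max_pc = sc$max_pc,
                         n_bins = sc$bins, pair_budget = sc$pairs,
                         null = sc$null, n_perm = sc$nperm,
                         seed = config$seed,
                         depth_threshold = sc$depth_threshold)
  for (v in variables) {
    p <- res$profiles[[v]]
    tab <- data.frame(window_start = p$windows$start,
                      window_end = p$windows$end,
                      mi_bits = p$mi, cumulative = p$cumulative,
                      cumulative_normalized = p$cumulative_normalized)
    if (!is.null(p$null)) {
      tab$null_mean <- p$null$null_mean
      tab$null_q95 <- p$null$null_q95
    }
    .write_tsv(tab, file.path(out, paste0("scales_", v, ".tsv")))
  }
  hier <- list(
    ordering = res$hierarchy$ordering,
    depths = stats::setNames(as.list(res$hierarchy$table$depth),
                             res$hierarchy$table$variable),
    ties = res$hierarchy$ties,
    threshold = res$hierarchy$threshold)
  jsonlite::write_json(hier, file.path(out, "hierarchy.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stages$scales <- res$config

  # --- epistasis (optional) ----------------------------------------------
  if (!is.null(config$epistasis)) {
    ep <- config$epistasis
    b <- read_bulk(ep$counts, ep$design)
    e <- normalize_bulk(b)
    tab <- epistasis_table(e, reference = ep$reference %||% "-HS/-NaCl")
    sets <- list()
    for (f in ep$sets) {
      gs <- read_gene_set(f)
      sets[[gs$name]] <- gs$gene_ids
    }
    .write_tsv(as.data.frame(tab), file.path(out, "epistasis_table.tsv"))
    .write_tsv(epistasis_summary(tab, sets),
               file.path(out, "epistasis_summary.tsv"))
    cors <- list(
      dual_vs_osmo = as.numeric(condition_correlation(e, "+HS/+NaCl",
                                                      "-HS/+NaCl")),
      dual_vs_heat = as.numeric(condition_correlation(e, "+HS/+NaCl",
                                                      "+HS/-NaCl")))
    jsonlite::write_json(cors, file.path(out, "correlations.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$epistasis <- list(genes = nrow(tab),
                                      filtered = attr(tab, "n_filtered"))
  }

  # --- physiology (optional) ---------------------------------------------
  if (!is.null(config$physiology)) {
    ph <- config$physiology
    phys <- list()
    if (!is.null(ph$trace)) {
      tr <- read_trace(ph$trace)
      q <- pm_ratio(tr, detect_regions(tr))
      phys$pm_ratio <- as.numeric(q$pm_ratio)
      phys$area_mono <- q$area_mono
      phys$area_poly <- q$area_poly
    }
    if (!is.null(ph$growth)) {
      g <- read_growth_curve(ph$growth)
      fit <- max_growth_rate(g)
      phys$max_growth_rate <- fit$rate
      phys$growth_fit_r2 <- fit$r_squared
    }
    if (!is.null(ph$competition)) {
      cs <- read_competition(ph$competition)
      fit <- competitive_fitness(cs)
      phys$selection_coefficient <- fit$s
      phys$fitness_fit_r2 <- fit$r_squared
    }
    jsonlite::write_json(phys, file.path(out, "physiology.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$physiology <- names(phys)
  }

  manifest$wall_clock_s <- as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# text output with full precision so reruns are byte-identical
.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- .fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
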