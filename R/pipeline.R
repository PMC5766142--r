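#' Pipeline configuration
#'
#' Collects every stage parameter behind one validated list. The analysis
#' defaults mirror the thresholds the method is built around: DMR calls at
#' adjusted p <= 0.10 (inclusive), expression and cis calls at adjusted
#' p < 0.05 (strict), a raw-p gate of 0.05 into the cis scan, a 1 Mb cis
#' window, and a 25 kb gene-subset distance.
#'
#' Input is either a [sim_config()] (synthetic mode) or a named list of
#' `paths` with elements `coverage` (named vector of per-sample files),
#' `expression`, `probes`, `samples`, `genes`, `islands` and optionally
#' `snp_panel`.
#'
#' @param sim A [sim_config()]; ignored when `paths` is given.
#' @param paths Named list of input files (see above).
#' @param max_gap_bp,corr_threshold,min_sites,min_depth Clustering
#'   parameters (see [cluster_adjacent_sites()]).
#' @param q_dmr,q_de,q_meqtr FDR thresholds per stage.
#' @param p_gate Raw-p gate into the cis scan.
#' @param window_bp cis window (bp).
#' @param subset_distance_bp Gene-subset distance (bp).
#' @param promoter_bp Promoter length for annotation (bp).
#' @param blacklist `"auto"` (detect from the SNP panel), `"none"`, or a
#'   BED path of intervals to exclude.
#' @param contrast,baseline_contrast Cell labels for the treated and
#'   baseline comparisons.
#' @param coverage_dialect Coordinate dialect of coverage files.
#' @param seed Seed forwarded to the simulation stage.
#' @return A list of class `dmrbeta_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            max_gap_bp = 1000, corr_threshold = 0.5,
                            min_sites = 3, min_depth = 5,
                            q_dmr = 0.10, q_de = 0.05, q_meqtr = 0.05,
                            p_gate = 0.05, window_bp = 1e6,
                            subset_distance_bp = 25000, promoter_bp = 2000,
                            blacklist = "auto",
                            contrast = c("KO_HDM", "WT_HDM"),
                            baseline_contrast = c("KO_saline", "WT_saline"),
                            coverage_dialect = "bismark-1-based",
                            seed = 1L) {
  for (th in c("q_dmr", "q_de", "q_meqtr", "p_gate")) {
    assert_scalar_number(get(th), th, lower = 1e-12, upper = 1)
  }
  assert_scalar_number(window_bp, "window_bp", lower = 1)
  assert_scalar_number(subset_distance_bp, "subset_distance_bp", lower = 1)
  if (!is.null(sim) && is.null(paths)) {
    sim$seed <- seed
    sim <- validate_sim_config(unclass(sim))
  }
  structure(list(
    sim = if (is.null(paths)) sim else NULL, paths = paths,
    max_gap_bp = max_gap_bp, corr_threshold = corr_threshold,
    min_sites = min_sites, min_depth = min_depth,
    q_dmr = q_dmr, q_de = q_de, q_meqtr = q_meqtr, p_gate = p_gate,
    window_bp = window_bp, subset_distance_bp = subset_distance_bp,
    promoter_bp = promoter_bp, blacklist = blacklist,
    contrast = contrast, baseline_contrast = baseline_contrast,
    coverage_dialect = coverage_dialect, seed = seed
  ), class = "dmrbeta_pipeline_config")
}

#' Run the full methylation/expression pipeline
#'
#' Executes every stage in order: (synthetic) data generation or reading,
#' adjacent-site clustering, cluster summarization, the treated and
#' baseline DMR contrasts, strain-blacklist detection and application,
#' baseline subtraction, annotation, expression normalization and
#' differential expression, the cis methylation-expression scan, and the
#' enrichment statistics. Returns every stage output plus a run report of
#' counts at each filter step; optionally writes all outputs and the report
#' (JSON) to a directory. Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list: `data`, `clusters`, `dmr` (treated contrast, all
#'   flags), `dmr_baseline`, `dmr_called` (surviving calls), `annotated`,
#'   `distribution`, `blacklist`, `expression` (normalized), `de`,
#'   `meqtr`, `enrichment`, `coef_normality_p`, and `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "dmrbeta_pipeline_config")) {
    abort("config must come from pipeline_config()",
          class = "dmrbeta_config_error")
  }
  report <- list(seed = config$seed, config_hash = rlang::hash(
    config[setdiff(names(config), "paths")]))

  if (!is.null(config$sim)) {
    data <- simulate_dataset(config$sim)
    snps <- simulate_strain_snps(config$sim, data$design)
  } else {
    p <- config$paths
    for (f in c("coverage", "expression", "probes", "samples", "genes",
                "islands")) {
      if (is.null(p[[f]])) {
        abort(paste0("pipeline paths are missing `", f, "`"),
              class = "dmrbeta_config_error")
      }
    }
    design <- read_sample_sheet(p$samples)
    data <- list(
      counts = read_coverage(p$coverage, design,
                             dialect = config$coverage_dialect),
      expression = read_expression(p$expression, p$probes, design),
      design = design,
      genes = read_genes(p$genes),
      islands = read_bed(p$islands),
      truth = NULL
    )
    snps <- if (!is.null(p$snp_panel)) read_snp_panel(p$snp_panel) else NULL
  }

  clusters <- cluster_adjacent_sites(
    data$counts, max_gap_bp = config$max_gap_bp,
    corr_threshold = config$corr_threshold, min_sites = config$min_sites,
    min_depth = config$min_depth) |>
    summarize_clusters(data$counts)
  report$n_sites <- dplyr::n_distinct(data$counts$pos, data$counts$chrom)
  report$n_clusters <- nrow(clusters)

  dmr <- call_dmrs(clusters, data$design, contrast = config$contrast,
                   q_threshold = config$q_dmr, genes = data$genes)
  dmr_baseline <- call_dmrs(clusters, data$design,
                            contrast = config$baseline_contrast,
                            q_threshold = config$q_dmr, genes = data$genes)
  report$n_clusters_tested <- sum(is.na(dmr$skip_reason))
  report$n_dmrs_called <- sum(dmr$called)

  blacklist <- if (identical(config$blacklist, "none")) NULL
  else if (identical(config$blacklist, "auto")) {
    if (is.null(snps)) NULL else detect_strain_blacklist(snps, data$design)
  } else read_bed(config$blacklist)

  dmr <- subtract_baseline(dmr, dmr_baseline)
  if (!is.null(blacklist)) dmr <- apply_blacklist(dmr, blacklist)
  report$n_baseline_shared <- sum(dmr$called & dmr$baseline_shared)
  report$n_blacklisted <- sum(dmr$called & dmr$blacklisted &
                                !dmr$baseline_shared)
  called <- dmr_calls(dmr)
  report$n_dmrs_reported <- nrow(called)

  annotated <- annotate_dmrs(called, data$genes, data$islands,
                             promoter_bp = config$promoter_bp)
  distribution <- genomic_distribution_summary(annotated)

  expr_norm <- data$expression |>
    quantile_normalize(design = data$design) |>
    log2_transform(design = data$design)
  de <- differential_expression(expr_norm, data$design,
                                contrast = config$contrast,
                                baseline_contrast = config$baseline_contrast,
                                q_threshold = config$q_de)
  report$n_probes <- nrow(de)
  report$n_de_significant <- sum(de$significant)
  report$n_de_baseline_shared <- sum(de$significant & de$baseline_shared)
  report$n_de_reported <- nrow(de_calls(de))

  meqtr <- cis_scan(dmr, clusters, expr_norm, data$design,
                    p_gate = config$p_gate, window_bp = config$window_bp,
                    q_threshold = config$q_meqtr)
  report$n_clusters_gated <- dplyr::n_distinct(meqtr$cluster_id)
  report$n_pairs_tested <- nrow(meqtr)
  report$n_pairs_significant <- sum(meqtr$significant)
  report$n_pairs_negative_significant <-
    sum(meqtr$significant & meqtr$sign == "-", na.rm = TRUE)

  enrichment <- enrichment_tests(meqtr, dmr_directions = called$direction)
  coef_norm <- coefficient_normality(meqtr)

  result <- list(data = data, snps = snps, clusters = clusters, dmr = dmr,
                 dmr_baseline = dmr_baseline, dmr_called = called,
                 annotated = annotated, distribution = distribution,
                 blacklist = blacklist, expression = expr_norm, de = de,
                 meqtr = meqtr, enrichment = enrichment,
                 coef_normality_p = coef_norm, report = report)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    x <- dplyr::select(x, -dplyr::where(is.list))
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }
  tsv(result$dmr, "dmr_full.tsv")
  tsv(result$dmr_called, "dmr_called.tsv")
  if (nrow(result$dmr_called) > 0L) {
    write_bed(result$dmr_called[c("chrom", "start", "end")],
              file.path(out_dir, "dmr_called.bed"))
  }
  tsv(result$annotated, "dmr_annotated.tsv")
  tsv(result$distribution, "genomic_distribution.tsv")
  if (!is.null(result$blacklist) && nrow(result$blacklist) > 0L) {
    write_bed(result$blacklist, file.path(out_dir, "blacklist.bed"))
  }
  tsv(result$de, "de.tsv")
  tsv(result$meqtr, "meqtr.tsv")
  tsv(result$enrichment, "enrichment.tsv")
  jsonlite::write_json(result$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
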