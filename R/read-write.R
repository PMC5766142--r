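#' Read per-sample bismark-style coverage files into one count table
#'
#' Merges one coverage file per sample (columns: chrom, start, end,
#' percent methylation, methylated count, unmethylated count) into a single
#' long table keyed by (chrom, pos, sample). Sites absent from a sample's
#' file are filled with depth 0; sites with zero depth in every sample are
#' dropped (and reported via a message). Internal coordinates are 0-based;
#' the `dialect` flag says how to interpret the file's start column.
#'
#' @param paths Character vector of file paths, named by sample id (or
#'   unnamed and in the same order as `design$sample`).
#' @param design Sample design tibble (`sample`, `genotype`, `treatment`).
#' @param dialect `"bismark-1-based"` (default; start column is a 1-based
#'   position) or `"bed-0-based"`.
#' @return Long tibble: chrom, pos, sample, meth, depth.
#' @export
read_coverage <- function(paths, design,
                          dialect = c("bismark-1-based", "bed-0-based")) {
  dialect <- match.arg(dialect)
  assert_columns(design, c("sample", "genotype", "treatment"), "design")
  if (is.null(names(paths)) || any(names(paths) == "")) {
    if (length(paths) != nrow(design)) {
      abort("unnamed `paths` must have one entry per design sample",
            class = "dmrbeta_config_error")
    }
    names(paths) <- design$sample
  }
  missing <- setdiff(design$sample, names(paths))
  if (length(missing) > 0L) {
    abort(paste0("no coverage file supplied for sample(s): ",
                 paste(missing, collapse = ", ")),
          class = "dmrbeta_config_error")
  }
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0L) {
    abort(paste0("coverage file not found: ", paste(absent, collapse = ", ")),
          class = "dmrbeta_io_error")
  }

  per_sample <- purrr::map2(paths[design$sample], design$sample,
                            read_one_coverage, dialect = dialect)
  long <- dplyr::bind_rows(per_sample)
  if (nrow(long) == 0L) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          sample = character(0), meth = integer(0),
                          depth = integer(0)))
  }
  full <- tidyr::expand_grid(
    dplyr::distinct(long, .data$chrom, .data$pos),
    sample = design$sample
  ) |>
    dplyr::left_join(long, by = c("chrom", "pos", "sample")) |>
    dplyr::mutate(meth = dplyr::coalesce(.data$meth, 0L),
                  depth = dplyr::coalesce(.data$depth, 0L))
  dead <- full |>
    dplyr::summarise(all_zero = all(.data$depth == 0L),
                     .by = c("chrom", "pos"))
  n_dead <- sum(dead$all_zero)
  if (n_dead > 0L) {
    inform(sprintf("read_coverage: dropped %d site(s) with zero depth in all samples",
                   n_dead))
    full <- dplyr::semi_join(full,
                             dplyr::filter(dead, !.data$all_zero),
                             by = c("chrom", "pos"))
  }
  dplyr::arrange(full, .data$chrom, .data$pos, .data$sample)
}

read_one_coverage <- function(path, sample, dialect) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(raw) == 0L) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          sample = character(0), meth = integer(0),
                          depth = integer(0)))
  }
  if (ncol(raw) != 6L) {
    abort(sprintf("%s: expected 6 columns, found %d", path, ncol(raw)),
          class = "dmrbeta_format_error")
  }
  start <- suppressWarnings(as.integer(raw[[2]]))
  m <- suppressWarnings(as.integer(raw[[5]]))
  u <- suppressWarnings(as.integer(raw[[6]]))
  bad <- which(is.na(start) | is.na(m) | is.na(u) | m < 0 | u < 0)
  if (length(bad) > 0L) {
    abort(sprintf("%s: malformed line(s): %s", path,
                  paste(head(bad, 5), collapse = ", ")),
          class = "dmrbeta_format_error")
  }
  pos <- if (dialect == "bismark-1-based") start - 1L else start
  tibble::tibble(chrom = raw[[1]], pos = pos, sample = sample,
                 meth = m, depth = m + u)
}

#' Write one coverage file per sample
#'
#' Inverse of [read_coverage()]; columns are chrom, start, end, percent
#' methylation, methylated count, unmethylated count.
#'
#' @param counts Long count table (chrom, pos, sample, meth, depth).
#' @param dir Output directory (created if needed).
#' @param dialect Coordinate dialect for the start column.
#' @return Invisibly, the named vector of written paths.
#' @export
write_coverage <- function(counts, dir,
                           dialect = c("bismark-1-based", "bed-0-based")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- sort(unique(counts$sample))
  paths <- setNames(file.path(dir, paste0(samples, ".cov")), samples)
  for (smp in samples) {
    d <- dplyr::filter(counts, .data$sample == smp, .data$depth > 0L) |>
      dplyr::arrange(.data$chrom, .data$pos)
    start <- if (dialect == "bismark-1-based") d$pos + 1L else d$pos
    out <- tibble::tibble(
      chrom = d$chrom, start = start, end = d$pos + 1L,
      pct = round(100 * d$meth / d$depth, 4),
      count_m = d$meth, count_u = d$depth - d$meth
    )
    readr::write_tsv(out, paths[[smp]], col_names = FALSE, progress = FALSE)
  }
  invisible(paths)
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' @param path BED file path.
#' @return Tibble (chrom, start, end, and name/score/strand when present),
#'   validated (start < end) and sorted by (chrom, start).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "dmrbeta_io_error")
  }
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0)))
  }
  out <- tibble::tibble(chrom = raw[[1]],
                        start = suppressWarnings(as.integer(raw[[2]])),
                        end = suppressWarnings(as.integer(raw[[3]])))
  bad <- which(is.na(out$start) | is.na(out$end) | out$start >= out$end)
  if (length(bad) > 0L) {
    abort(sprintf("%s: invalid interval on line(s): %s", path,
                  paste(head(bad, 5), collapse = ", ")),
          class = "dmrbeta_format_error")
  }
  if (ncol(raw) >= 4L) out$name <- raw[[4]]
  if (ncol(raw) >= 5L) out$score <- suppressWarnings(as.numeric(raw[[5]]))
  if (ncol(raw) >= 6L) {
    strand <- raw[[6]]
    ok <- strand %in% c("+", "-", ".")
    if (!all(ok)) {
      abort(sprintf("%s: invalid strand on line(s): %s", path,
                    paste(head(which(!ok), 5), collapse = ", ")),
            class = "dmrbeta_format_error")
    }
    out$strand <- strand
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write intervals as BED
#'
#' @param x Tibble with chrom, start, end and optionally name, score, strand.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: fill gaps so later columns stay valid
  if ("strand" %in% cols && !"score" %in% cols) x$score <- 0
  if (any(c("score", "strand") %in% cols) && !"name" %in% cols) x$name <- "."
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  readr::write_tsv(x[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' @param path BED12 file path.
#' @return Gene-model tibble with exon start/end list-columns and the
#'   thick (CDS) interval used to resolve UTRs.
#' @export
read_genes <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    return(make_genes(validate_sim_config(unclass(sim_config(n_genes = 0))))[0, ])
  }
  if (ncol(raw) < 12L) {
    abort(sprintf("%s: BED12 requires 12 columns, found %d", path, ncol(raw)),
          class = "dmrbeta_format_error")
  }
  start <- as.integer(raw[[2]])
  sizes <- purrr::map(strsplit(raw[[11]], ","), as.integer)
  offs <- purrr::map(strsplit(raw[[12]], ","), as.integer)
  tibble::tibble(
    chrom = raw[[1]], start = start, end = as.integer(raw[[3]]),
    name = raw[[4]], strand = raw[[6]],
    thick_start = as.integer(raw[[7]]), thick_end = as.integer(raw[[8]]),
    exon_starts = purrr::map2(offs, start, function(o, s) o + s),
    exon_ends = purrr::pmap(list(offs, sizes, start),
                            function(o, sz, s) o + sz + s)
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Write gene models as BED12
#'
#' @param genes Gene-model tibble (as produced by [simulate_dataset()] or
#'   [read_genes()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genes <- function(genes, path) {
  out <- tibble::tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$name, score = 0L, strand = genes$strand,
    thick_start = genes$thick_start, thick_end = genes$thick_end,
    rgb = "0,0,0",
    block_count = lengths(genes$exon_starts),
    block_sizes = purrr::map2_chr(genes$exon_starts, genes$exon_ends,
                                  function(s, e) paste(e - s, collapse = ",")),
    block_starts = purrr::map2_chr(genes$exon_starts, genes$start,
                                   function(s, g) paste(s - g, collapse = ","))
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read an expression matrix and attach probe coordinates
#'
#' @param matrix_path TSV with a `probe_id` column and one column per sample.
#' @param probe_bed_path BED file whose name column holds probe ids.
#' @param design Sample design; matrix columns must match its samples.
#' @return Expression tibble: probe_id, chrom, start, end, `testable`
#'   (FALSE for probes lacking coordinates) and one intensity column per
#'   sample, ordered as in `design`.
#' @export
read_expression <- function(matrix_path, probe_bed_path, design) {
  mat <- readr::read_tsv(matrix_path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  assert_columns(mat, "probe_id", "expression matrix")
  if (anyDuplicated(mat$probe_id)) {
    abort(paste0("duplicated probe id(s): ",
                 paste(unique(mat$probe_id[duplicated(mat$probe_id)]),
                       collapse = ", ")),
          class = "dmrbeta_format_error")
  }
  have <- setdiff(names(mat), "probe_id")
  missing <- setdiff(design$sample, have)
  extra <- setdiff(have, design$sample)
  if (length(missing) > 0L || length(extra) > 0L) {
    abort(sprintf("expression matrix samples do not match design (missing: %s; unexpected: %s)",
                  paste(missing, collapse = ", "),
                  paste(extra, collapse = ", ")),
          class = "dmrbeta_config_error")
  }
  probes <- read_bed(probe_bed_path)
  if (!"name" %in% names(probes)) probes$name <- character(nrow(probes))
  coords <- dplyr::select(probes, probe_id = "name", "chrom", "start", "end")
  out <- dplyr::left_join(mat, coords, by = "probe_id") |>
    dplyr::mutate(testable = !is.na(.data$start))
  n_untestable <- sum(!out$testable)
  if (n_untestable > 0L) {
    warn(sprintf("%d probe(s) lack coordinates and are untestable for cis analysis",
                 n_untestable))
  }
  dplyr::select(out, "probe_id", "chrom", "start", "end", "testable",
                dplyr::all_of(design$sample))
}

#' @rdname read_expression
#' @param expression Expression tibble to write.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>_probes.bed`.
#' @export
write_expression <- function(expression, prefix) {
  samples <- setdiff(names(expression),
                     c("probe_id", "chrom", "start", "end", "testable"))
  readr::write_tsv(expression[c("probe_id", samples)],
                   paste0(prefix, ".tsv"), progress = FALSE)
  bed <- expression |>
    dplyr::filter(!is.na(.data$start)) |>
    dplyr::transmute(chrom = .data$chrom, start = .data$start,
                     end = .data$end, name = .data$probe_id)
  write_bed(bed, paste0(prefix, "_probes.bed"))
  invisible(prefix)
}

#' Read or write the sample sheet
#'
#' @param path TSV with columns sample, genotype, treatment.
#' @return Design tibble.
#' @export
read_sample_sheet <- function(path) {
  d <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  assert_columns(d, c("sample", "genotype", "treatment"), "sample sheet")
  if (anyDuplicated(d$sample)) {
    abort("sample ids must be unique", class = "dmrbeta_format_error")
  }
  bad_g <- setdiff(unique(d$genotype), c("WT", "KO"))
  bad_t <- setdiff(unique(d$treatment), c("saline", "HDM"))
  if (length(bad_g) || length(bad_t)) {
    abort(sprintf("unknown genotype/treatment level(s): %s",
                  paste(c(bad_g, bad_t), collapse = ", ")),
          class = "dmrbeta_format_error")
  }
  d
}

#' @rdname read_sample_sheet
#' @param design Design tibble to write.
#' @export
write_sample_sheet <- function(design, path) {
  readr::write_tsv(design[c("sample", "genotype", "treatment")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read or write the strain-informative SNP panel
#'
#' @param path TSV with columns chrom, pos, sample, matches_alt.
#' @return Long SNP panel tibble.
#' @export
read_snp_panel <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    sample = readr::col_character(), matches_alt = readr::col_logical()),
    progress = FALSE)
}

#' @rdname read_snp_panel
#' @param panel Panel tibble to write.
#' @export
write_snp_panel <- function(panel, path) {
  readr::write_tsv(panel, path, progress = FALSE)
  invisible(path)
}

#' Write every table of a simulated study to a directory
#'
#' Materializes the output of [simulate_dataset()] (plus a SNP panel) as the
#' plain-text files the reading functions consume: per-sample coverage
#' files, expression matrix + probe BED, sample sheet, gene BED12, island
#' BED, SNP panel, and ground-truth TSVs.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory.
#' @param snps Optional SNP panel from [simulate_strain_snps()].
#' @return Invisibly, `dir`.
#' @export
write_study_files <- function(dataset, dir, snps = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_coverage(dataset$counts, file.path(dir, "coverage"),
                 dialect = "bed-0-based")
  write_expression(dataset$expression, file.path(dir, "expression"))
  write_sample_sheet(dataset$design, file.path(dir, "samples.tsv"))
  write_genes(dataset$genes, file.path(dir, "genes.bed"))
  write_bed(dataset$islands, file.path(dir, "islands.bed"))
  if (!is.null(snps)) write_snp_panel(snps, file.path(dir, "snp_panel.tsv"))
  tr <- dataset$truth
  flat <- tr$clusters |>
    dplyr::mutate(positions = purrr::map_chr(.data$positions, paste,
                                             collapse = ","))
  readr::write_tsv(flat, file.path(dir, "truth_clusters.tsv"), progress = FALSE)
  readr::write_tsv(tr$cis_pairs, file.path(dir, "truth_cis_pairs.tsv"),
                   progress = FALSE)
  readr::write_tsv(tr$de_probes, file.path(dir, "truth_de_probes.tsv"),
                   progress = FALSE)
  if (!is.null(tr$contam_region)) {
    readr::write_tsv(tr$contam_region, file.path(dir, "truth_contam.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}
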