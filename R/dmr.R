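#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort ascending, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j}
#' capped at 1, mapped back to input order. Thin wrapper over
#' [stats::p.adjust()] with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Adjusted values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "dmrbeta_input_error")
  }
  p.adjust(p, method = "BH")
}

#' Test methylation clusters for a group difference
#'
#' Fits every eligible summarized cluster with a depth-weighted beta
#' regression of the pooled proportion on group membership
#' (`contrast[1]` vs `contrast[2]`, the second group being the reference),
#' adjusts the Wald p-values with Benjamini-Hochberg across all fitted
#' clusters, and flags clusters with adjusted p at or below `q_threshold`
#' (boundary inclusive) as called DMRs. Direction is `hypo` when the first
#' contrast group is less methylated. Clusters are skipped (with a reason)
#' when a contrast group has fewer than `min_samples` non-missing samples;
#' non-converged fits are retained with p = 1.
#'
#' @param clusters Summarized clusters from [summarize_clusters()].
#' @param design Sample design tibble.
#' @param contrast Two `genotype_treatment` labels, tested as
#'   `contrast[1] - contrast[2]`; default KO_HDM vs WT_HDM.
#' @param q_threshold FDR threshold for the `called` flag (inclusive).
#' @param genes Optional gene-model tibble for nearest-gene labels.
#' @param min_samples Minimum non-missing samples per group.
#' @return A `dmr_results` tibble, one row per cluster: coordinates,
#'   estimate (logit-scale group effect), phi, std.error, p_raw, p_adj,
#'   direction, called, baseline_shared, blacklisted, skip_reason,
#'   nearest_gene, gene_distance.
#' @export
call_dmrs <- function(clusters, design, contrast = c("KO_HDM", "WT_HDM"),
                      q_threshold = 0.10, genes = NULL, min_samples = 2) {
  check_contrast(design, contrast)
  if (!"data" %in% names(clusters)) {
    abort("clusters must be summarized first (see summarize_clusters())",
          class = "dmrbeta_config_error")
  }
  if (nrow(clusters) == 0L) {
    warn("no clusters to test")
    out <- tibble::tibble(cluster_id = integer(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          n_sites = integer(0), estimate = numeric(0),
                          std.error = numeric(0), phi = numeric(0),
                          p_raw = numeric(0), converged = logical(0),
                          skip_reason = character(0), p_adj = numeric(0),
                          direction = character(0), called = logical(0),
                          baseline_shared = logical(0),
                          blacklisted = logical(0),
                          nearest_gene = character(0),
                          gene_distance = numeric(0))
    class(out) <- c("dmr_results", class(out))
    return(out)
  }
  grp <- setNames(group_label(design$genotype, design$treatment),
                  design$sample)

  fit_one <- function(d) {
    d$group <- grp[d$sample]
    d <- d[!d$missing & d$group %in% contrast, , drop = FALSE]
    n_a <- sum(d$group == contrast[1])
    n_b <- sum(d$group == contrast[2])
    if (n_a < min_samples || n_b < min_samples) {
      return(tibble::tibble(estimate = NA_real_, std.error = NA_real_,
                            phi = NA_real_, p_raw = NA_real_,
                            converged = FALSE,
                            skip_reason = "insufficient samples in a group"))
    }
    d$group <- factor(d$group, levels = c(contrast[2], contrast[1]))
    fit <- fit_beta_regression(d, y ~ group, weights = depth)
    term <- paste0("group", contrast[1])
    tibble::tibble(estimate = unname(fit$coefficients[term]),
                   std.error = unname(fit$se[term]),
                   phi = fit$phi,
                   p_raw = fit_term_p(fit, term),
                   converged = fit$converged,
                   skip_reason = NA_character_)
  }

  res <- dplyr::bind_cols(
    dplyr::select(clusters, "cluster_id", "chrom", "start", "end", "n_sites"),
    dplyr::bind_rows(purrr::map(clusters$data, fit_one))
  )
  tested <- is.na(res$skip_reason)
  res$p_adj <- NA_real_
  res$p_adj[tested] <- bh_adjust(res$p_raw[tested])
  res <- res |>
    dplyr::mutate(
      direction = dplyr::case_when(
        !tested | is.na(.data$estimate) ~ NA_character_,
        .data$estimate < 0 ~ "hypo",
        TRUE ~ "hyper"),
      called = tested & !is.na(.data$p_adj) & .data$p_adj <= q_threshold,
      baseline_shared = FALSE,
      blacklisted = FALSE
    )
  res <- annotate_nearest_gene(res, genes)
  class(res) <- c("dmr_results", class(res))
  res
}

annotate_nearest_gene <- function(res, genes) {
  if (is.null(genes) || nrow(genes) == 0L || nrow(res) == 0L) {
    res$nearest_gene <- NA_character_
    res$gene_distance <- NA_real_
    return(res)
  }
  mids <- floor((res$start + res$end) / 2)
  hit <- purrr::map(seq_len(nrow(res)), function(i) {
    g <- genes[genes$chrom == res$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) {
      return(list(name = NA_character_, dist = Inf))
    }
    d <- pmax(0, g$start - mids[i], mids[i] - (g$end - 1L))
    best <- which(d == min(d))
    best <- best[order(g$name[best])][1]   # lexicographic tie-break
    list(name = g$name[best], dist = d[best])
  })
  res$nearest_gene <- purrr::map_chr(hit, "name")
  res$gene_distance <- purrr::map_dbl(hit, "dist")
  res
}

#' Flag treated-contrast DMRs that are shared with a baseline contrast
#'
#' A treated DMR is baseline-shared when its interval overlaps (by at least
#' 1 bp) any called baseline DMR, or when its nearest gene equals a called
#' baseline DMR's nearest gene. Shared entries are flagged, never deleted:
#' downstream reporting via [dmr_calls()] excludes them.
#'
#' @param treated `dmr_results` from the treated contrast.
#' @param baseline `dmr_results` from the baseline (vehicle) contrast; only
#'   its called rows are used.
#' @return `treated` with its `baseline_shared` flag updated.
#' @export
subtract_baseline <- function(treated, baseline) {
  base <- dplyr::filter(baseline, .data$called)
  if (nrow(base) == 0L || nrow(treated) == 0L) {
    return(treated)
  }
  olap <- purrr::map_lgl(seq_len(nrow(treated)), function(i) {
    any(base$chrom == treated$chrom[i] &
          base$start < treated$end[i] &
          base$end > treated$start[i])
  })
  gene_hit <- !is.na(treated$nearest_gene) &
    treated$nearest_gene %in% base$nearest_gene[!is.na(base$nearest_gene)]
  treated$baseline_shared <- treated$baseline_shared | olap | gene_hit
  treated
}

#' Detect an alternate-strain background region from a SNP panel
#'
#' Slides windows along each chromosome; a window is flagged when the
#' fraction of informative SNP observations matching the alternate strain is
#' at least `match_frac` in KO samples and at most `1 - match_frac` in WT
#' samples. Overlapping flagged windows are merged into maximal intervals.
#' Windows without SNPs are skipped.
#'
#' @param panel Long SNP panel (chrom, pos, sample, matches_alt).
#' @param design Sample design.
#' @param window_bp,step_bp Window size and step (bp).
#' @param match_frac Group-specific match-fraction threshold.
#' @return Tibble of blacklist intervals (chrom, start, end).
#' @export
detect_strain_blacklist <- function(panel, design, window_bp = 1e6,
                                    step_bp = 5e5, match_frac = 0.9) {
  if (window_bp < step_bp) {
    abort("window_bp must be >= step_bp", class = "dmrbeta_config_error")
  }
  if (nrow(panel) == 0L) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0)))
  }
  panel <- dplyr::left_join(panel, design[c("sample", "genotype")],
                            by = "sample")
  out <- panel |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(df, key) {
      starts <- seq(0, max(df$pos), by = step_bp)
      flagged <- purrr::map_lgl(starts, function(s) {
        win <- df[df$pos >= s & df$pos < s + window_bp, , drop = FALSE]
        if (nrow(win) == 0L) return(FALSE)
        ko <- mean(win$matches_alt[win$genotype == "KO"])
        wt <- mean(win$matches_alt[win$genotype == "WT"])
        isTRUE(ko >= match_frac) && isTRUE(wt <= 1 - match_frac)
      })
      if (!any(flagged)) return(NULL)
      merge_intervals(tibble::tibble(chrom = key$chrom,
                                     start = starts[flagged],
                                     end = starts[flagged] + window_bp))
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0)))
  }
  out
}

merge_intervals <- function(x) {
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  out <- x[1, ]
  if (nrow(x) > 1L) for (i in 2:nrow(x)) {
    k <- nrow(out)
    if (x$chrom[i] == out$chrom[k] && x$start[i] <= out$end[k]) {
      out$end[k] <- max(out$end[k], x$end[i])
    } else {
      out <- dplyr::bind_rows(out, x[i, ])
    }
  }
  out
}

#' Flag DMRs overlapping blacklist intervals
#'
#' @param dmrs `dmr_results` tibble.
#' @param blacklist Interval tibble from [detect_strain_blacklist()] or
#'   [read_bed()].
#' @return `dmrs` with its `blacklisted` flag updated.
#' @export
apply_blacklist <- function(dmrs, blacklist) {
  if (nrow(dmrs) == 0L || is.null(blacklist) || nrow(blacklist) == 0L) {
    return(dmrs)
  }
  hit <- purrr::map_lgl(seq_len(nrow(dmrs)), function(i) {
    any(blacklist$chrom == dmrs$chrom[i] &
          blacklist$start < dmrs$end[i] &
          blacklist$end > dmrs$start[i])
  })
  dmrs$blacklisted <- dmrs$blacklisted | hit
  dmrs
}

#' Reported DMR calls after all filters
#'
#' @param dmrs `dmr_results` tibble.
#' @return The rows that are called and neither baseline-shared nor
#'   blacklisted.
#' @export
dmr_calls <- function(dmrs) {
  dplyr::filter(dmrs, .data$called, !.data$baseline_shared,
                !.data$blacklisted)
}

#' Subset analysis of clusters near a gene list
#'
#' Selects tested clusters whose interval lies within `distance_bp` of any
#' listed gene body (boundary inclusive; distance 0 when overlapping),
#' re-applies Benjamini-Hochberg within the subset only, and flags subset
#' calls at the (inclusive) threshold.
#'
#' @param dmrs `dmr_results` tibble carrying raw p-values for all clusters.
#' @param gene_list Tibble with columns name, chrom, start, end — or a
#'   character vector of gene names resolved against `genes`.
#' @param genes Gene-model tibble used to resolve a character `gene_list`.
#' @param distance_bp Maximum gap between cluster and gene body (bp).
#' @param q_threshold Within-subset FDR threshold (inclusive).
#' @return The subset rows with columns `subset_gene`, `subset_distance`,
#'   `p_adj_subset` and `called_subset`.
#' @export
subset_near_genes <- function(dmrs, gene_list, genes = NULL,
                              distance_bp = 25000, q_threshold = 0.10) {
  if (is.character(gene_list)) {
    if (is.null(genes)) {
      abort("a character gene_list needs `genes` to resolve coordinates",
            class = "dmrbeta_config_error")
    }
    found <- genes[genes$name %in% gene_list, c("name", "chrom", "start", "end")]
    missing <- setdiff(gene_list, found$name)
    if (length(missing) > 0L) {
      warn(paste0("gene name(s) not resolvable, skipped: ",
                  paste(missing, collapse = ", ")))
    }
    gene_list <- found
  }
  if (nrow(gene_list) == 0L || nrow(dmrs) == 0L) {
    out <- dmrs[0, ]
    out$subset_gene <- character(0)
    out$subset_distance <- numeric(0)
    out$p_adj_subset <- numeric(0)
    out$called_subset <- logical(0)
    return(out)
  }
  tested <- dplyr::filter(dmrs, !is.na(.data$p_raw))
  near <- dplyr::inner_join(
    tested, dplyr::rename(gene_list, subset_gene = "name",
                          g_start = "start", g_end = "end"),
    by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(subset_distance = interval_distance(
      .data$start, .data$end, .data$g_start, .data$g_end)) |>
    dplyr::filter(.data$subset_distance <= distance_bp) |>
    dplyr::slice_min(.data$subset_distance, by = "cluster_id",
                     with_ties = FALSE) |>
    dplyr::select(-"g_start", -"g_end")
  near$p_adj_subset <- bh_adjust(near$p_raw)
  near$called_subset <- near$p_adj_subset <= q_threshold
  near
}
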