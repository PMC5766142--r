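#' cis methylation-expression association scan
#'
#' Takes the methylation clusters that pass a raw-p gate on the group
#' contrast (strict `p_raw < p_gate`), pairs each with every coordinate-
#' bearing expression probe whose midpoint lies within `window_bp` of the
#' cluster midpoint on the same chromosome, and fits, per pair, a
#' depth-weighted beta regression of cluster methylation on probe
#' expression with genotype as an additive covariate (methylation is the
#' response, expression the predictor). P-values for the expression
#' coefficient are adjusted with Benjamini-Hochberg across all tested
#' pairs; significance is strict (`p_adj < q_threshold`). The sign of each
#' association is the sign of the expression coefficient.
#'
#' @param dmrs `dmr_results` carrying a raw p per cluster (the gate).
#' @param clusters Summarized clusters (the per-sample proportions).
#' @param expression Normalized log2 expression tibble with coordinates.
#' @param design Sample design.
#' @param p_gate Raw-p gate on the methylation contrast (strict).
#' @param window_bp cis window, midpoint to midpoint (bp).
#' @param q_threshold FDR threshold across tested pairs (strict).
#' @param treatment Samples used for the association; defaults to the
#'   HDM-treated animals of both genotypes, matching the contrast that
#'   produced the gate.
#' @return A `meqtr_results` tibble: cluster_id, probe_id, coordinates,
#'   distance_bp, estimate, sign, p_raw, p_adj, significant, converged.
#' @export
cis_scan <- function(dmrs, clusters, expression, design, p_gate = 0.05,
                     window_bp = 1e6, q_threshold = 0.05,
                     treatment = "HDM") {
  keep_samples <- design$sample[design$treatment %in% treatment]
  sub_design <- design[design$sample %in% keep_samples, , drop = FALSE]

  cand <- dmrs |>
    dplyr::filter(!is.na(.data$p_raw), .data$p_raw < p_gate) |>
    dplyr::select("cluster_id", "chrom", "start", "end")
  probes <- expression |>
    dplyr::filter(!is.na(.data$start)) |>
    dplyr::select("probe_id", "chrom", p_start = "start", p_end = "end")
  n_excluded <- sum(is.na(expression$start))
  if (n_excluded > 0L) {
    inform(sprintf("cis_scan: %d probe(s) without coordinates excluded",
                   n_excluded))
  }
  empty <- tibble::tibble(cluster_id = integer(0), probe_id = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), distance_bp = numeric(0),
                          estimate = numeric(0), sign = character(0),
                          p_raw = numeric(0), p_adj = numeric(0),
                          significant = logical(0), converged = logical(0))
  class(empty) <- c("meqtr_results", class(empty))
  if (nrow(cand) == 0L || nrow(probes) == 0L) {
    warn("cis_scan: no candidate cluster-probe pairs")
    return(empty)
  }
  pairs <- dplyr::inner_join(cand, probes, by = "chrom",
                             relationship = "many-to-many") |>
    dplyr::mutate(distance_bp = abs(floor((.data$start + .data$end) / 2) -
                                      floor((.data$p_start + .data$p_end) / 2))) |>
    dplyr::filter(.data$distance_bp <= window_bp)
  if (nrow(pairs) == 0L) {
    warn("cis_scan: no candidate cluster-probe pairs")
    return(empty)
  }

  cl_data <- setNames(clusters$data, clusters$cluster_id)
  expr_m <- as.matrix(expression[match(pairs$probe_id, expression$probe_id),
                                 sub_design$sample, drop = FALSE])
  geno <- setNames(sub_design$genotype, sub_design$sample)

  fits <- purrr::map(seq_len(nrow(pairs)), function(i) {
    d <- cl_data[[as.character(pairs$cluster_id[i])]]
    d <- d[d$sample %in% sub_design$sample & !d$missing, , drop = FALSE]
    d$expr <- expr_m[i, d$sample]
    d$genotype <- geno[d$sample]
    form <- if (length(unique(d$genotype)) > 1L) y ~ expr + genotype else
      y ~ expr
    fit <- fit_beta_regression(d, form, weights = depth)
    tibble::tibble(estimate = unname(fit$coefficients["expr"]),
                   p_raw = fit_term_p(fit, "expr"),
                   converged = fit$converged)
  })
  out <- dplyr::bind_cols(
    dplyr::select(pairs, "cluster_id", "probe_id", "chrom", "start", "end",
                  "distance_bp"),
    dplyr::bind_rows(fits)
  )
  out$p_adj <- bh_adjust(out$p_raw)
  out$sign <- ifelse(is.na(out$estimate), NA_character_,
                     ifelse(out$estimate < 0, "-", "+"))
  out$significant <- out$p_adj < q_threshold
  out <- out[c("cluster_id", "probe_id", "chrom", "start", "end",
               "distance_bp", "estimate", "sign", "p_raw", "p_adj",
               "significant", "converged")]
  class(out) <- c("meqtr_results", class(out))
  out
}

#' Exact binomial enrichment statistics for a cis scan
#'
#' Three statistics over the scanned pairs, each an exact binomial tail:
#' (a) `negative_direction` — one-sided test of the count of negative-sign
#' (canonically anti-correlated) associations against a null proportion of
#' 0.5; (b) `nominal_p` — one-sided test of the count of pairs with raw
#' p < 0.05 against a null of 0.05; (c) `sign_balance_significant` —
#' two-sided test of the negative count among significant pairs against
#' 0.5. When a vector of DMR directions is supplied, a fourth one-sided
#' test (`hypomethylation`) checks enrichment of hypomethylated calls
#' against 0.5. Tests with no eligible observations are reported with a
#' reason instead of a p-value.
#'
#' @param results `meqtr_results` tibble from [cis_scan()].
#' @param dmr_directions Optional character vector of DMR directions
#'   (`"hypo"`/`"hyper"`), e.g. `dmr_calls(x)$direction`.
#' @return Tibble: test, n_total, n_in_class, null_proportion, alternative,
#'   p_value, reason.
#' @export
#' @examples
#' enrichment_tests(
#'   tibble::tibble(sign = c("-", "-", "+"), p_raw = c(0.01, 0.2, 0.6),
#'                  significant = c(TRUE, FALSE, FALSE)))
enrichment_tests <- function(results, dmr_directions = NULL) {
  one <- function(test, k, n, p0, alternative) {
    if (n == 0L) {
      return(tibble::tibble(test = test, n_total = 0L, n_in_class = 0L,
                            null_proportion = p0, alternative = alternative,
                            p_value = NA_real_,
                            reason = "no eligible observations"))
    }
    p <- binom.test(k, n, p = p0, alternative = alternative)$p.value
    tibble::tibble(test = test, n_total = as.integer(n),
                   n_in_class = as.integer(k), null_proportion = p0,
                   alternative = alternative, p_value = p,
                   reason = NA_character_)
  }
  signs <- results$sign[!is.na(results$sign)]
  praw <- results$p_raw[!is.na(results$p_raw)]
  sig_signs <- results$sign[results$significant & !is.na(results$sign)]
  out <- dplyr::bind_rows(
    one("negative_direction", sum(signs == "-"), length(signs), 0.5,
        "greater"),
    one("nominal_p", sum(praw < 0.05), length(praw), 0.05, "greater"),
    one("sign_balance_significant", sum(sig_signs == "-"), length(sig_signs),
        0.5, "two.sided")
  )
  if (!is.null(dmr_directions)) {
    dirs <- dmr_directions[!is.na(dmr_directions)]
    out <- dplyr::bind_rows(
      out, one("hypomethylation", sum(dirs == "hypo"), length(dirs), 0.5,
               "greater"))
  }
  out
}

#' Normality check of the association-coefficient distribution
#'
#' Shapiro-Wilk test on the cis-scan expression coefficients; reported for
#' context only, never used as a gate.
#'
#' @param results `meqtr_results` tibble.
#' @return The Shapiro-Wilk p-value (NA when fewer than 3 coefficients).
#' @export
coefficient_normality <- function(results) {
  est <- results$estimate[is.finite(results$estimate)]
  if (length(est) < 3L) return(NA_real_)
  shapiro.test(est)$p.value
}
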