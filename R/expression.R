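#' Quantile-normalize an expression matrix
#'
#' Classical rank-mean quantile normalization (via
#' [limma::normalizeQuantiles()] with tie averaging): each sample column is
#' sorted, values at each rank are averaged across samples, and the rank
#' means are assigned back by original rank; tied values receive the mean
#' over their rank range. Afterwards every column has the same empirical
#' distribution.
#'
#' @param expression Expression tibble (probe_id, coordinates, one column
#'   per sample).
#' @param design Optional design used to identify sample columns; otherwise
#'   every column beyond the probe metadata is treated as a sample.
#' @return The tibble with normalized sample columns.
#' @export
quantile_normalize <- function(expression, design = NULL) {
  samples <- expression_samples(expression, design)
  if (length(samples) < 2L || nrow(expression) == 0L) {
    return(expression)
  }
  m <- as.matrix(expression[samples])
  const <- apply(m, 2, function(x) diff(range(x)) == 0)
  if (any(const)) {
    warn(paste0("constant intensity column(s): ",
                paste(samples[const], collapse = ", ")))
  }
  expression[samples] <- as.data.frame(limma::normalizeQuantiles(m, ties = TRUE))
  expression
}

#' Log2-transform raw intensities
#'
#' @param expression Expression tibble.
#' @param offset Added before the log to avoid log of zero.
#' @inheritParams quantile_normalize
#' @return The tibble with `log2(x + offset)` sample columns.
#' @export
log2_transform <- function(expression, offset = 1, design = NULL) {
  samples <- expression_samples(expression, design)
  if (any(as.matrix(expression[samples]) + offset <= 0)) {
    abort("negative intensities after offset", class = "dmrbeta_input_error")
  }
  expression[samples] <- log2(expression[samples] + offset)
  expression
}

expression_samples <- function(expression, design = NULL) {
  if (!is.null(design)) {
    missing <- setdiff(design$sample, names(expression))
    if (length(missing) > 0L) {
      abort(paste0("expression matrix lacks sample column(s): ",
                   paste(missing, collapse = ", ")),
            class = "dmrbeta_config_error")
    }
    return(design$sample)
  }
  setdiff(names(expression), c("probe_id", "chrom", "start", "end", "testable"))
}

#' Per-probe differential expression with a cell-means model
#'
#' For each probe, fits the two-factor cell-means model over the four
#' genotype-by-treatment cells on normalized log2 intensities and tests the
#' requested cell difference with a t-statistic using the pooled
#' within-cell variance (df = N - number of cells). P-values are adjusted
#' with Benjamini-Hochberg across probes; significance is strict
#' (`p_adj < q_threshold`). Probes significant in the baseline contrast are
#' flagged `baseline_shared` and excluded from the headline list
#' ([de_calls()]) while remaining in the full table. Probes constant across
#' all samples get p = 1 and a `degenerate` flag.
#'
#' @param expression Normalized log2 expression tibble.
#' @param design Sample design.
#' @param contrast Two `genotype_treatment` cell labels
#'   (`contrast[1] - contrast[2]`).
#' @param baseline_contrast Optional second contrast (e.g. the saline
#'   cells) used to flag constitutive differences.
#' @param q_threshold FDR threshold (strict).
#' @return A `de_results` tibble: probe_id, log2fc, p_raw, p_adj,
#'   significant, degenerate, baseline_shared (and the baseline contrast's
#'   p-values when requested).
#' @export
differential_expression <- function(expression, design,
                                    contrast = c("KO_HDM", "WT_HDM"),
                                    baseline_contrast = c("KO_saline", "WT_saline"),
                                    q_threshold = 0.05) {
  check_contrast(design, contrast)
  samples <- design$sample
  m <- as.matrix(expression[samples])
  rownames(m) <- expression$probe_id
  cells <- factor(group_label(design$genotype, design$treatment))
  k <- nlevels(cells)
  n_tot <- ncol(m)

  cell_means <- vapply(levels(cells), function(cl)
    rowMeans(m[, cells == cl, drop = FALSE]), numeric(nrow(m)))
  fitted <- cell_means[, as.character(cells), drop = FALSE]
  sse <- rowSums((m - fitted)^2)
  df <- n_tot - k
  s2 <- sse / df

  contrast_p <- function(ct) {
    n_a <- sum(cells == ct[1]); n_b <- sum(cells == ct[2])
    fc <- cell_means[, ct[1]] - cell_means[, ct[2]]
    se <- sqrt(s2 * (1 / n_a + 1 / n_b))
    t <- ifelse(se > 0, fc / se, 0)
    p <- ifelse(se > 0, 2 * pt(-abs(t), df), 1)
    list(fc = fc, p = p)
  }

  main <- contrast_p(contrast)
  degenerate <- sse == 0 &
    apply(cell_means, 1, function(x) diff(range(x)) == 0)
  main$p[degenerate] <- 1

  out <- tibble::tibble(
    probe_id = expression$probe_id,
    log2fc = unname(main$fc),
    p_raw = unname(main$p),
    p_adj = bh_adjust(unname(main$p)),
    degenerate = unname(degenerate)
  )
  out$significant <- out$p_adj < q_threshold
  out$baseline_shared <- FALSE
  if (!is.null(baseline_contrast)) {
    check_contrast(design, baseline_contrast)
    base <- contrast_p(baseline_contrast)
    base$p[degenerate] <- 1
    out$p_raw_baseline <- unname(base$p)
    out$p_adj_baseline <- bh_adjust(unname(base$p))
    out$baseline_shared <- out$p_adj_baseline < q_threshold
  }
  class(out) <- c("de_results", class(out))
  out
}

#' Headline differentially expressed probes
#'
#' @param de `de_results` tibble.
#' @return Significant probes that are not baseline-shared.
#' @export
de_calls <- function(de) {
  dplyr::filter(de, .data$significant, !.data$baseline_shared)
}
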