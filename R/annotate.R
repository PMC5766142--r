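#' Annotate DMRs by gene context and CpG-island context
#'
#' Gene context is assigned by overlap with precedence
#' promoter > 5' UTR > 3' UTR > exon > intron > intergenic, where the
#' promoter is `promoter_bp` upstream of the strand-aware transcription
#' start, UTRs are the exonic portions outside the thick (CDS) interval,
#' exon means the coding exonic portion, and intron is the remaining gene
#' body. Island context comes from the gap (in bases strictly between the
#' intervals) to the nearest CpG island: 0 is `island`, 1-3000 is `shore`,
#' more than 3000 is `distant`.
#'
#' @param dmrs Tibble of intervals (chrom, start, end); typically
#'   [dmr_calls()] output.
#' @param genes Gene-model tibble (BED12-lite, with exon list-columns and
#'   thick interval).
#' @param islands Island interval tibble.
#' @param promoter_bp Promoter length upstream of the TSS (bp).
#' @return `dmrs` with gene_context, island_context, island_distance and
#'   length_bp columns.
#' @export
annotate_dmrs <- function(dmrs, genes, islands, promoter_bp = 2000) {
  if (nrow(dmrs) == 0L) {
    dmrs$gene_context <- character(0)
    dmrs$island_context <- character(0)
    dmrs$island_distance <- numeric(0)
    dmrs$length_bp <- integer(0)
    return(dmrs)
  }
  dmrs$gene_context <- vapply(seq_len(nrow(dmrs)), function(i) {
    gene_context_one(dmrs$chrom[i], dmrs$start[i], dmrs$end[i], genes,
                     promoter_bp)
  }, character(1))
  dmrs$island_distance <- vapply(seq_len(nrow(dmrs)), function(i) {
    isl <- islands[islands$chrom == dmrs$chrom[i], , drop = FALSE]
    if (nrow(isl) == 0L) return(Inf)
    min(interval_distance(dmrs$start[i], dmrs$end[i], isl$start, isl$end))
  }, numeric(1))
  dmrs$island_context <- dplyr::case_when(
    dmrs$island_distance == 0 ~ "island",
    dmrs$island_distance <= 3000 ~ "shore",
    TRUE ~ "distant")
  dmrs$length_bp <- as.integer(dmrs$end - dmrs$start)
  dmrs
}

overlaps_any <- function(s, e, starts, ends) {
  length(starts) > 0L && any(starts < e & ends > s)
}

gene_context_one <- function(chrom, s, e, genes, promoter_bp) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) return("intergenic")
  found <- c(promoter = FALSE, utr5 = FALSE, utr3 = FALSE, exon = FALSE,
             intron = FALSE)
  for (i in seq_len(nrow(g))) {
    plus <- g$strand[i] != "-"
    prom <- if (plus) c(g$start[i] - promoter_bp, g$start[i]) else
      c(g$end[i], g$end[i] + promoter_bp)
    if (overlaps_any(s, e, prom[1], prom[2])) found["promoter"] <- TRUE
    if (!overlaps_any(s, e, g$start[i], g$end[i])) next

    ex_s <- g$exon_starts[[i]]; ex_e <- g$exon_ends[[i]]
    ts <- g$thick_start[i]; te <- g$thick_end[i]
    # exonic pieces clipped to the regions left of / inside / right of CDS
    clip <- function(lo, hi) {
      cs <- pmax(ex_s, lo); ce <- pmin(ex_e, hi)
      keep <- cs < ce
      list(s = cs[keep], e = ce[keep])
    }
    left <- clip(-Inf, ts); cds <- clip(ts, te); right <- clip(te, Inf)
    utr5 <- if (plus) left else right
    utr3 <- if (plus) right else left
    if (overlaps_any(s, e, utr5$s, utr5$e)) found["utr5"] <- TRUE
    if (overlaps_any(s, e, utr3$s, utr3$e)) found["utr3"] <- TRUE
    if (overlaps_any(s, e, cds$s, cds$e)) found["exon"] <- TRUE
    # intronic: inside the gene body but outside every exon
    in_exon <- overlaps_any(s, e, ex_s, ex_e)
    gaps_s <- ex_e[-length(ex_e)]; gaps_e <- ex_s[-1]
    if (overlaps_any(s, e, gaps_s, gaps_e) || !in_exon) {
      found["intron"] <- TRUE
    }
  }
  labels <- c(promoter = "promoter", utr5 = "5UTR", utr3 = "3UTR",
              exon = "exon", intron = "intron")
  for (k in names(labels)) if (found[k]) return(labels[[k]])
  "intergenic"
}

#' Tabulate the genomic distribution of annotated DMRs
#'
#' @param annotations Output of [annotate_dmrs()].
#' @return Tibble (axis, category, n, pct): one row per gene-context and
#'   island-context category, plus a `gene_body` aggregate
#'   (5UTR + exon + intron + 3UTR) on the gene axis.
#' @export
genomic_distribution_summary <- function(annotations) {
  gene_levels <- c("promoter", "5UTR", "exon", "intron", "3UTR", "intergenic")
  island_levels <- c("island", "shore", "distant")
  n_total <- nrow(annotations)
  tab <- function(axis, values, levels) {
    cnt <- as.integer(table(factor(values, levels = levels)))
    tibble::tibble(axis = axis, category = levels, n = cnt,
                   pct = if (n_total > 0) 100 * cnt / n_total else
                     rep(0, length(levels)))
  }
  gene <- tab("gene", annotations$gene_context, gene_levels)
  body_n <- sum(gene$n[gene$category %in% c("5UTR", "exon", "intron", "3UTR")])
  body <- tibble::tibble(axis = "gene", category = "gene_body", n = body_n,
                         pct = if (n_total > 0) 100 * body_n / n_total else 0)
  dplyr::bind_rows(gene, body,
                   tab("island", annotations$island_context, island_levels))
}
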