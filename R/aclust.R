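#' Cluster correlated adjacent CpG sites
#'
#' Bottom-up agglomeration of neighbouring CpG sites into methylation
#' clusters, one chromosome at a time. Every site starts as its own cluster;
#' a cluster is merged with its right neighbour while (a) the gap between
#' their nearest member sites is at most `max_gap_bp` and (b) the complete-
#' linkage similarity — the minimum Spearman correlation of per-site
#' methylation proportions, over samples with depth `>= min_depth` at both
#' sites, across all cross-cluster site pairs — is at least
#' `corr_threshold`. The sweep is greedy left-to-right (upstream pairs merge
#' first) and repeats until no merge is possible. Clusters with fewer than
#' `min_sites` sites are discarded; a minimum of three sites constitutes a
#' cluster by default.
#'
#' A site pair with fewer than 3 samples of adequate depth, or with a
#' degenerate (zero-variance) proportion vector, is treated as
#' uncorrelatable and never merged across.
#'
#' @param counts Long count table (chrom, pos, sample, meth, depth) as
#'   returned by [read_coverage()] or [simulate_dataset()].
#' @param max_gap_bp Maximum gap between nearest member sites of two
#'   clusters for a merge (bp).
#' @param corr_threshold Minimum complete-linkage Spearman correlation.
#' @param min_sites Minimum number of sites per reported cluster.
#' @param min_depth Minimum per-site depth for a sample to enter a
#'   correlation.
#' @return Tibble of clusters: cluster_id, chrom, start, end (half-open,
#'   covering the final CG dinucleotide), n_sites, positions (list-column
#'   of ordered site positions).
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n_sites = 100, n_clusters_true = 10,
#'                                  n_probes = 0, n_cis_true = 0,
#'                                  n_de_true = 0, seed = 3))
#' cl <- cluster_adjacent_sites(d$counts)
#' nrow(cl)
cluster_adjacent_sites <- function(counts, max_gap_bp = 1000,
                                   corr_threshold = 0.5, min_sites = 3,
                                   min_depth = 5) {
  assert_columns(counts, c("chrom", "pos", "sample", "meth", "depth"),
                 "count table")
  assert_scalar_number(corr_threshold, "corr_threshold", -1, 1)
  assert_scalar_number(min_sites, "min_sites", lower = 1)
  if (nrow(counts) == 0L) {
    return(empty_clusters())
  }
  samples <- sort(unique(counts$sample))
  out <- counts |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(df, key) {
      cl <- cluster_one_chrom(df, samples, max_gap_bp, corr_threshold,
                              min_sites, min_depth)
      if (nrow(cl) > 0L) cl$chrom <- key$chrom
      cl
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0L) {
    return(empty_clusters())
  }
  out |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(cluster_id = dplyr::row_number()) |>
    dplyr::select("cluster_id", "chrom", "start", "end", "n_sites",
                  "positions")
}

empty_clusters <- function() {
  tibble::tibble(cluster_id = integer(0), chrom = character(0),
                 start = integer(0), end = integer(0), n_sites = integer(0),
                 positions = list())
}

cluster_one_chrom <- function(df, samples, max_gap_bp, corr_threshold,
                              min_sites, min_depth) {
  wide_m <- site_matrix(df, samples, "meth")
  wide_d <- site_matrix(df, samples, "depth")
  pos <- as.integer(rownames(wide_m))
  n <- length(pos)
  if (n == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          n_sites = integer(0), positions = list()))
  }
  prop <- wide_m / ifelse(wide_d == 0, NA, wide_d)

  # pairwise similarity on demand, memoized (adjacent merges revisit pairs)
  cache <- new.env(parent = emptyenv())
  pair_cor <- function(i, j) {
    key <- paste0(i, "_", j)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ok <- which(wide_d[i, ] >= min_depth & wide_d[j, ] >= min_depth &
                  !is.na(prop[i, ]) & !is.na(prop[j, ]))
    val <- if (length(ok) < 3L) -Inf else {
      r <- suppressWarnings(stats::cor(prop[i, ok], prop[j, ok],
                                       method = "spearman"))
      if (is.na(r)) -Inf else r
    }
    cache[[key]] <- val
    val
  }
  link <- function(a, b) {
    m <- Inf
    for (i in a) for (j in b) {
      m <- min(m, pair_cor(i, j))
      if (m < corr_threshold) return(m)
    }
    m
  }

  clusters <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(clusters)) {
      a <- clusters[[i]]; b <- clusters[[i + 1L]]
      gap <- pos[b[1]] - pos[a[length(a)]]
      if (gap <= max_gap_bp && link(a, b) >= corr_threshold) {
        clusters[[i]] <- c(a, b)
        clusters[[i + 1L]] <- NULL
        merged <- TRUE
        # stay: the grown cluster may absorb the next neighbour too
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }

  keep <- clusters[lengths(clusters) >= min_sites]
  if (length(keep) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          n_sites = integer(0), positions = list()))
  }
  tibble::tibble(
    start = vapply(keep, function(k) pos[k[1]], integer(1)),
    end = vapply(keep, function(k) pos[k[length(k)]] + 2L, integer(1)),
    n_sites = lengths(keep),
    positions = purrr::map(keep, function(k) pos[k])
  )
}

site_matrix <- function(df, samples, value) {
  w <- df |>
    dplyr::select("pos", "sample", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "sample", values_from = dplyr::all_of(value),
                       values_fill = 0L) |>
    dplyr::arrange(.data$pos)
  missing <- setdiff(samples, names(w))
  for (s in missing) w[[s]] <- 0L
  m <- as.matrix(w[samples])
  rownames(m) <- w$pos
  m
}

#' Pool member-site counts into per-sample cluster summaries
#'
#' For each cluster and sample, the pooled methylated count
#' \eqn{M_s = \sum_i m_{is}}, pooled depth \eqn{D_s = \sum_i d_{is}} and
#' pooled proportion \eqn{y_s = M_s / D_s} over the member sites. Samples
#' with zero pooled depth are flagged missing.
#'
#' @param clusters Cluster tibble from [cluster_adjacent_sites()].
#' @param counts The count table the clusters were built from.
#' @return `clusters` with a nested `data` list-column; each element is a
#'   tibble (sample, meth, depth, y, missing) with one row per sample.
#' @export
summarize_clusters <- function(clusters, counts) {
  if (nrow(clusters) == 0L) {
    clusters$data <- list()
    return(clusters)
  }
  map <- clusters |>
    dplyr::select("cluster_id", "chrom", "positions") |>
    tidyr::unnest_longer("positions", values_to = "pos")
  samples <- sort(unique(counts$sample))
  pooled <- map |>
    dplyr::inner_join(counts, by = c("chrom", "pos"),
                      relationship = "many-to-many") |>
    dplyr::summarise(meth = sum(.data$meth), depth = sum(.data$depth),
                     .by = c("cluster_id", "sample")) |>
    tidyr::complete(cluster_id = clusters$cluster_id, sample = samples,
                    fill = list(meth = 0L, depth = 0L)) |>
    dplyr::mutate(y = ifelse(.data$depth > 0, .data$meth / .data$depth,
                             NA_real_),
                  missing = .data$depth == 0L) |>
    dplyr::arrange(.data$cluster_id, .data$sample) |>
    tidyr::nest(.by = "cluster_id")
  dplyr::left_join(clusters, pooled, by = "cluster_id")
}
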