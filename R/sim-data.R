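#' Simulate a complete methylation + expression study
#'
#' Generates, under one seed, every table the analysis pipeline consumes:
#' per-sample CpG methylation counts with spatially clustered and
#' within-cluster-correlated sites, an expression matrix with probe
#' coordinates, gene models and CpG islands, the sample design, and a
#' ground-truth record of everything planted.
#'
#' The generative model for site \eqn{i}, sample \eqn{s}:
#' \deqn{logit(p_{is}) = b_i + u_{c(i)s} + e_{is} + \delta_c \Delta \cdot
#'   1[s \in affected]}
#' with per-site baseline \eqn{b_i \sim N(\mu_b, \sigma_b^2)}, a shared
#' per-(cluster, sample) latent \eqn{u_{cs} \sim N(0, \rho\sigma_L^2)} and
#' site noise \eqn{e_{is} \sim N(0, (1-\rho)\sigma_L^2)} so that the latent
#' within-cluster correlation is \eqn{\rho}. Depths are negative binomial
#' (floored at 1) and methylated counts are binomial given depth and
#' \eqn{p_{is}}. Treatment-specific effects (`n_dmrs_true`) affect the
#' KO_HDM cell only; constitutive effects (`n_baseline_dmrs`) affect all KO
#' samples. The planted effect size `effect_logit` is defined on the scale
#' a beta regression estimates — the difference in logit of the group-mean
#' proportion: the latent shift \eqn{\delta_c} applied in the affected
#' group is solved per cluster so that the marginal logit-of-mean
#' difference equals `effect_logit` (a shift applied directly on the
#' latent scale would be recovered attenuated, because the regression
#' marginalizes over the per-sample latent). Expression for a planted cis pair is linear in the cluster's
#' latent methylation proportion on the log2 scale.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `counts` (long tibble: chrom, pos, sample,
#'   meth, depth), `expression` (tibble: probe_id, chrom, start, end, one
#'   column per sample, raw intensity scale), `design` (sample, genotype,
#'   treatment), `genes` (BED12-lite tibble with exon list-columns),
#'   `islands`, and `truth` (planted clusters, DMR intervals, cis pairs,
#'   DE probes, contaminated region).
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n_sites = 200, n_clusters_true = 20,
#'                                  n_probes = 40, n_cis_true = 4, seed = 7))
#' dplyr::count(d$truth$clusters, type)
simulate_dataset <- function(config) {
  config <- validate_sim_config(unclass(config))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  design <- make_design(cfg$n_per_group)
  n_samp <- nrow(design)
  ko <- design$genotype == "KO"
  ko_hdm <- ko & design$treatment == "HDM"

  layout <- layout_sites(cfg)
  sites <- layout$sites        # tibble: pos, cluster_id (NA for isolated)
  clusters <- layout$clusters  # tibble: cluster_id, type, sign, sites list

  n_sites <- nrow(sites)
  b <- rnorm(n_sites, cfg$baseline_logit_mean, cfg$baseline_logit_sd)
  # sites of one cluster share their baseline level (CpG-dense patches are
  # locally homogeneous); isolated sites keep their own draw
  if (nrow(clusters) > 0L) {
    first_site <- vapply(clusters$sites, function(s) s[1], integer(1))
    for (k in seq_len(nrow(clusters))) {
      idx <- clusters$sites[[k]]
      b[idx] <- b[first_site[k]] + rnorm(length(idx), 0, 0.1)
    }
  }

  rho <- cfg$within_cluster_rho
  sd_u <- cfg$latent_sd * sqrt(rho)
  sd_e <- cfg$latent_sd * sqrt(1 - rho)

  # the planted effect is defined on the estimand scale — the difference in
  # logit of the group-mean proportion, which is what the beta regression
  # estimates; solve for the latent shift that achieves it under the
  # Gaussian per-sample cluster latent (a direct latent shift would be
  # recovered attenuated, by marginalization over that latent)
  if (nrow(clusters) > 0L) {
    clusters$latent_shift <- vapply(seq_len(nrow(clusters)), function(k) {
      if (clusters$sign[k] == 0) return(0)
      b_c <- b[clusters$sites[[k]][1]]
      latent_shift_for_marginal(b_c, sd_u, clusters$sign[k] * cfg$effect_logit)
    }, numeric(1))
  }

  # latent logits: sites x samples
  logit <- matrix(b, n_sites, n_samp) +
    matrix(rnorm(n_sites * n_samp, 0, 1), n_sites, n_samp) *
      ifelse(is.na(sites$cluster_id), cfg$latent_sd, sd_e)
  u <- matrix(0, max(1L, nrow(clusters)), n_samp)
  if (nrow(clusters) > 0L) {
    u <- matrix(rnorm(nrow(clusters) * n_samp, 0, sd_u), ncol = n_samp)
    for (k in seq_len(nrow(clusters))) {
      idx <- clusters$sites[[k]]
      eff <- clusters$latent_shift[k] *
        affected_samples(clusters$type[k], ko, ko_hdm)
      logit[idx, ] <- logit[idx, ] +
        matrix(u[k, ] + eff, length(idx), n_samp, byrow = TRUE)
    }
  }

  p <- plogis(logit)
  depth <- matrix(pmax(1L, rnbinom(n_sites * n_samp, mu = cfg$depth_mean,
                                   size = cfg$depth_dispersion)),
                  n_sites, n_samp)
  meth <- matrix(rbinom(n_sites * n_samp, as.vector(depth), as.vector(p)),
                 n_sites, n_samp)

  counts <- tibble::tibble(
    chrom = cfg$chrom,
    pos = rep(sites$pos, times = n_samp),
    sample = rep(design$sample, each = n_sites),
    meth = as.vector(meth),
    depth = as.vector(depth)
  ) |>
    dplyr::arrange(.data$pos, .data$sample)

  # per-(cluster, sample) latent methylation (logit scale) drives planted
  # cis expression links; the logit scale keeps the association strength
  # comparable across clusters whatever their baseline level
  lat_cluster <- NULL
  if (nrow(clusters) > 0L) {
    lat_cluster <- t(vapply(seq_len(nrow(clusters)), function(k) {
      idx <- clusters$sites[[k]]
      eff <- clusters$latent_shift[k] *
        affected_samples(clusters$type[k], ko, ko_hdm)
      mean(b[idx]) + u[k, ] + eff
    }, numeric(n_samp)))
  }

  genes <- make_genes(cfg)
  islands <- make_islands(cfg, clusters, sites)
  expr <- make_expression(cfg, design, clusters, sites, lat_cluster,
                          ko_hdm)

  site_pos <- sites$pos
  cluster_tbl <- clusters |>
    dplyr::mutate(
      chrom = cfg$chrom,
      start = vapply(.data$sites, function(i) min(site_pos[i]), integer(1)),
      end = vapply(.data$sites, function(i) max(site_pos[i]) + 2L, integer(1)),
      n_sites = lengths(.data$sites),
      positions = purrr::map(.data$sites, function(i) site_pos[i])
    ) |>
    dplyr::select("cluster_id", "chrom", "start", "end", "n_sites",
                  "type", "sign", "latent_shift", "positions")

  truth <- list(
    clusters = cluster_tbl,
    dmr_intervals = dplyr::filter(cluster_tbl, .data$type == "dmr"),
    baseline_intervals = dplyr::filter(cluster_tbl, .data$type == "baseline"),
    cis_pairs = expr$cis_pairs,
    de_probes = expr$de_probes,
    contam_region = if (is.null(cfg$contam_region)) NULL else
      tibble::tibble(chrom = cfg$chrom,
                     start = cfg$contam_region[1],
                     end = cfg$contam_region[2])
  )

  list(counts = counts, expression = expr$matrix, design = design,
       genes = genes, islands = islands, truth = truth, config = cfg)
}

# mean proportion under a Gaussian latent on the logit scale
marginal_mean_prop <- function(b, sd_u) {
  if (sd_u < 1e-8) return(plogis(b))
  stats::integrate(function(u) plogis(b + u) * stats::dnorm(u, 0, sd_u),
                   -8 * sd_u, 8 * sd_u, rel.tol = 1e-10)$value
}

# latent shift whose marginal logit-of-mean difference equals `target`
latent_shift_for_marginal <- function(b, sd_u, target) {
  base <- qlogis(marginal_mean_prop(b, sd_u))
  f <- function(d) qlogis(marginal_mean_prop(b + d, sd_u)) - base - target
  stats::uniroot(f, lower = target - 3, upper = target + 3,
                 extendInt = "yes", tol = 1e-8)$root
}

affected_samples <- function(type, ko, ko_hdm) {
  switch(type,
         dmr = as.numeric(ko_hdm),
         baseline = as.numeric(ko),
         numeric(length(ko)))
}

make_design <- function(n_per_group) {
  grid <- expand.grid(genotype = c("WT", "KO"),
                      treatment = c("saline", "HDM"),
                      rep = seq_len(n_per_group),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample = sprintf("%s_%s_%02d", grid$genotype, grid$treatment, grid$rep),
    genotype = grid$genotype,
    treatment = grid$treatment
  ) |>
    dplyr::arrange(.data$sample)
}

# place planted clusters and isolated background sites on one chromosome,
# anchored far enough apart (>> typical max_gap) that distinct slots can
# never be merged by adjacency alone
layout_sites <- function(cfg) {
  sizes <- if (cfg$n_clusters_true > 0)
    sample(3:8, cfg$n_clusters_true, replace = TRUE) else integer(0)
  n_bg <- max(0L, cfg$n_sites - sum(sizes))
  n_slots <- cfg$n_clusters_true + n_bg
  if (n_slots == 0L) {
    return(list(sites = tibble::tibble(pos = integer(0),
                                       cluster_id = integer(0)),
                clusters = tibble::tibble(cluster_id = integer(0),
                                          type = character(0),
                                          sign = numeric(0),
                                          latent_shift = numeric(0),
                                          sites = list())))
  }
  anchors <- round(cfg$chrom_length * seq_len(n_slots) / (n_slots + 1)) +
    sample(-500:500, n_slots, replace = TRUE)
  cluster_slots <- sort(sample(n_slots, cfg$n_clusters_true))

  pos <- integer(0)
  site_cluster <- integer(0)
  ci <- 0L
  for (j in seq_len(n_slots)) {
    if (j %in% cluster_slots) {
      ci <- ci + 1L
      offs <- cumsum(c(0L, sample(20:150, sizes[ci] - 1L, replace = TRUE)))
      pos <- c(pos, anchors[j] + offs)
      site_cluster <- c(site_cluster, rep(ci, sizes[ci]))
    } else {
      pos <- c(pos, anchors[j])
      site_cluster <- c(site_cluster, NA_integer_)
    }
  }
  stopifnot(!is.unsorted(pos))

  types <- rep("null", cfg$n_clusters_true)
  effect_ids <- sample(cfg$n_clusters_true,
                       cfg$n_dmrs_true + cfg$n_baseline_dmrs)
  types[effect_ids[seq_len(cfg$n_dmrs_true)]] <- "dmr"
  if (cfg$n_baseline_dmrs > 0)
    types[effect_ids[cfg$n_dmrs_true + seq_len(cfg$n_baseline_dmrs)]] <- "baseline"
  signs <- ifelse(types == "null", 0,
                  sample(c(-1, 1), cfg$n_clusters_true, replace = TRUE))

  clusters <- tibble::tibble(
    cluster_id = seq_len(cfg$n_clusters_true),
    type = types,
    sign = signs,
    latent_shift = 0,
    sites = purrr::map(seq_len(cfg$n_clusters_true),
                       function(k) which(site_cluster == k))
  )
  list(sites = tibble::tibble(pos = as.integer(pos),
                              cluster_id = site_cluster),
       clusters = clusters)
}

make_genes <- function(cfg) {
  n <- cfg$n_genes
  if (n == 0L) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0),
                          strand = character(0), thick_start = integer(0),
                          thick_end = integer(0), exon_starts = list(),
                          exon_ends = list()))
  }
  len <- sample(5000:100000, n, replace = TRUE)
  start <- sort(sample.int(max(1, cfg$chrom_length - max(len)), n))
  end <- start + len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  exons <- purrr::map(seq_len(n), function(i) {
    n_ex <- sample(3:8, 1)
    cuts <- sort(sample(seq(start[i] + 50, end[i] - 50), 2 * (n_ex - 1)))
    es <- as.integer(c(start[i], cuts[seq(2, length(cuts), by = 2)]))
    ee <- as.integer(c(cuts[seq(1, length(cuts), by = 2)], end[i]))
    list(starts = es, ends = ee)
  })
  exon_starts <- purrr::map(exons, "starts")
  exon_ends <- purrr::map(exons, "ends")
  tibble::tibble(
    chrom = cfg$chrom, start = start, end = end,
    name = sprintf("gene%03d", seq_len(n)), strand = strand,
    thick_start = purrr::map2_int(exon_starts, exon_ends,
                                  function(s, e) as.integer(floor((s[1] + e[1]) / 2))),
    thick_end = purrr::map2_int(exon_starts, exon_ends,
                                function(s, e) {
                                  k <- length(s)
                                  as.integer(ceiling((s[k] + e[k]) / 2))
                                }),
    exon_starts = exon_starts, exon_ends = exon_ends
  )
}

make_islands <- function(cfg, clusters, sites) {
  n <- cfg$n_islands
  if (n == 0L) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0)))
  }
  n_at_cluster <- min(nrow(clusters), floor(n / 2))
  at <- if (n_at_cluster > 0) sample(nrow(clusters), n_at_cluster) else integer(0)
  starts <- integer(0)
  ends <- integer(0)
  for (k in at) {
    idx <- clusters$sites[[k]]
    s <- min(sites$pos[idx]) - sample(50:300, 1)
    e <- max(sites$pos[idx]) + sample(50:300, 1)
    starts <- c(starts, max(0L, s)); ends <- c(ends, e)
  }
  n_rand <- n - n_at_cluster
  rs <- sample.int(cfg$chrom_length - 2000L, n_rand)
  starts <- c(starts, rs)
  ends <- c(ends, rs + sample(300:2000, n_rand, replace = TRUE))
  tibble::tibble(chrom = cfg$chrom, start = as.integer(starts),
                 end = as.integer(ends)) |>
    dplyr::arrange(.data$start)
}

make_expression <- function(cfg, design, clusters, sites, lat_cluster, ko_hdm) {
  n_probe <- cfg$n_probes
  n_samp <- nrow(design)
  probe_id <- sprintf("probe%04d", seq_len(n_probe))

  # choose cis target clusters: planted-effect clusters first so the pairs
  # survive a raw-p gate on the methylation contrast
  pref <- c(which(clusters$type %in% c("dmr", "baseline")),
            which(clusters$type == "null"))
  cis_targets <- head(pref, cfg$n_cis_true)
  cis_probe <- sample(n_probe, length(cis_targets))
  cis_sign <- sample(c(-1, 1), length(cis_targets), replace = TRUE)

  non_cis <- setdiff(seq_len(n_probe), cis_probe)
  de_probe <- head(non_cis, cfg$n_de_true)
  de_sign <- sample(c(-1, 1), length(de_probe), replace = TRUE)

  # coordinates: cis probes within the 1 Mb window of their target cluster,
  # the rest uniform; 60-mer probes
  start <- sample.int(cfg$chrom_length - 60L, n_probe)
  for (j in seq_along(cis_targets)) {
    idx <- clusters$sites[[cis_targets[j]]]
    mid <- round(mean(range(sites$pos[idx])))
    d <- sample(10000:500000, 1) * sample(c(-1, 1), 1)
    start[cis_probe[j]] <- min(max(0, mid + d), cfg$chrom_length - 60)
  }

  base <- rnorm(n_probe, 8, 1.5)
  z <- matrix(base, n_probe, n_samp) +
    matrix(rnorm(n_probe * n_samp, 0, cfg$expr_sd), n_probe, n_samp)
  for (j in seq_along(cis_targets)) {
    m <- lat_cluster[cis_targets[j], ]
    z[cis_probe[j], ] <- z[cis_probe[j], ] +
      cis_sign[j] * cfg$cis_slope * (m - mean(m))
  }
  for (j in seq_along(de_probe)) {
    z[de_probe[j], ko_hdm] <- z[de_probe[j], ko_hdm] +
      de_sign[j] * cfg$de_log2fc
  }

  intensity <- 2^z
  mat <- tibble::as_tibble(setNames(as.data.frame(intensity), design$sample))
  matrix_tbl <- dplyr::bind_cols(
    tibble::tibble(probe_id = probe_id, chrom = cfg$chrom,
                   start = as.integer(start), end = as.integer(start + 60L)),
    mat
  )

  cis_pairs <- tibble::tibble(
    cluster_id = clusters$cluster_id[cis_targets],
    probe_id = probe_id[cis_probe],
    sign = cis_sign
  )
  de_probes <- tibble::tibble(probe_id = probe_id[de_probe], sign = de_sign)
  list(matrix = matrix_tbl, cis_pairs = cis_pairs, de_probes = de_probes)
}

#' Simulate a strain-informative SNP panel
#'
#' Emits genome-wide strain-informative SNP positions with a per-sample
#' indicator of matching the alternate (contaminating) strain. Inside the
#' configured contaminated block, KO samples match the alternate strain at
#' rate 0.98 and WT samples at 0.02; everywhere else both match at the 0.02
#' background rate.
#'
#' @param config A [sim_config()] object.
#' @param design Optional sample design; defaults to the design
#'   [simulate_dataset()] would build for this config.
#' @return Long tibble: chrom, pos, sample, matches_alt (logical).
#' @export
simulate_strain_snps <- function(config, design = NULL) {
  cfg <- validate_sim_config(unclass(config))
  design <- design %||% make_design(cfg$n_per_group)
  withr::with_seed(cfg$seed + 104729L, {
    pos <- seq(round(cfg$snp_spacing / 2), cfg$chrom_length,
               by = cfg$snp_spacing)
    pos <- as.integer(pos + sample(seq(-round(cfg$snp_spacing / 4),
                                       round(cfg$snp_spacing / 4)),
                                   length(pos), replace = TRUE))
    pos <- sort(unique(pmax(0L, pmin(pos, as.integer(cfg$chrom_length - 1L)))))
    inside <- if (is.null(cfg$contam_region)) rep(FALSE, length(pos)) else
      pos >= cfg$contam_region[1] & pos < cfg$contam_region[2]
    out <- tidyr::expand_grid(pos = pos, sample = design$sample) |>
      dplyr::left_join(design, by = "sample")
    rate <- ifelse(rep(inside, each = nrow(design)) & out$genotype == "KO",
                   0.98, 0.02)
    out$matches_alt <- runif(nrow(out)) < rate
    tibble::tibble(chrom = cfg$chrom, pos = out$pos, sample = out$sample,
                   matches_alt = out$matches_alt)
  })
}
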