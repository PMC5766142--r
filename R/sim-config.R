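#' Configuration for the synthetic methylation/expression study generator
#'
#' Builds and validates the parameter set for [simulate_dataset()] and
#' [simulate_strain_snps()]. The defaults describe a two-factor mouse study
#' (genotype WT/KO crossed with saline/HDM treatment) profiled by targeted
#' bisulfite capture and a one-color expression array: spatially clustered
#' CpG sites with exchangeable within-cluster correlation on the logit scale,
#' negative-binomial sequencing depths, group effects planted on the logit
#' scale in a subset of clusters, expression probes with planted cis links of
#' both signs to cluster methylation, and a contiguous block of the genome
#' carrying an alternate strain background.
#'
#' @param n_per_group Samples per genotype-by-treatment cell (4 cells).
#' @param n_sites Total CpG sites simulated (clustered plus isolated).
#' @param n_clusters_true Number of planted correlated clusters.
#' @param n_dmrs_true Planted clusters carrying a treatment-specific genotype
#'   effect (appears in the KO_HDM cell only).
#' @param n_baseline_dmrs Planted clusters carrying a constitutive genotype
#'   effect (appears in KO samples under both treatments); these are the
#'   regions a baseline-subtraction step should remove.
#' @param effect_logit Planted group effect size on the logit scale.
#' @param baseline_logit_mean,baseline_logit_sd Normal distribution of the
#'   per-site baseline methylation level on the logit scale.
#' @param within_cluster_rho Latent correlation of sites within a planted
#'   cluster, in `[0, 1]`.
#' @param latent_sd Total per-sample latent standard deviation on the logit
#'   scale (split between the shared cluster component and site noise
#'   according to `within_cluster_rho`).
#' @param depth_mean,depth_dispersion Mean and size parameter of the
#'   negative-binomial read-depth distribution (floored at 1).
#' @param n_probes Expression probes.
#' @param n_cis_true Planted cluster-probe cis associations. Pairs are
#'   attached to planted effect clusters first (so they survive a raw-p gate
#'   on the methylation contrast), then to other clusters.
#' @param cis_slope Magnitude of the planted expression change (log2 units)
#'   per unit change in the cluster's latent logit methylation; each
#'   planted pair gets a random sign.
#' @param n_de_true Probes with a planted KO_HDM-specific expression shift.
#' @param de_log2fc Magnitude of that shift in log2 units (random sign).
#' @param expr_sd Residual expression noise, standard deviation in log2 units.
#' @param chrom,chrom_length Name and length of the simulated chromosome.
#' @param contam_region Planted alternate-strain block as
#'   `c(start, end)` (0-based half-open) on `chrom`, or `NULL` for none.
#' @param n_genes,n_islands Number of gene models / CpG islands to place.
#' @param snp_spacing Approximate spacing of strain-informative SNPs (bp).
#' @param seed Integer random seed; identical seeds give identical output.
#'
#' @return A validated list of class `dmrbeta_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 300, n_clusters_true = 30, seed = 1)
#' cfg$n_dmrs_true
sim_config <- function(n_per_group = 10,
                       n_sites = 2000,
                       n_clusters_true = 200,
                       n_dmrs_true = 5,
                       n_baseline_dmrs = 0,
                       effect_logit = 1.5,
                       baseline_logit_mean = 0,
                       baseline_logit_sd = 1.2,
                       within_cluster_rho = 0.95,
                       latent_sd = 0.6,
                       depth_mean = 30,
                       depth_dispersion = 5,
                       n_probes = 400,
                       n_cis_true = 20,
                       cis_slope = 3,
                       n_de_true = 20,
                       de_log2fc = 1.0,
                       expr_sd = 0.5,
                       chrom = "chrS",
                       chrom_length = 6e7,
                       contam_region = c(2e7, 3.4e7),
                       n_genes = 60,
                       n_islands = 80,
                       snp_spacing = 20000,
                       seed = 1L) {
  cfg <- list(
    n_per_group = n_per_group, n_sites = n_sites,
    n_clusters_true = n_clusters_true, n_dmrs_true = n_dmrs_true,
    n_baseline_dmrs = n_baseline_dmrs, effect_logit = effect_logit,
    baseline_logit_mean = baseline_logit_mean,
    baseline_logit_sd = baseline_logit_sd,
    within_cluster_rho = within_cluster_rho, latent_sd = latent_sd,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    n_probes = n_probes, n_cis_true = n_cis_true, cis_slope = cis_slope,
    n_de_true = n_de_true, de_log2fc = de_log2fc, expr_sd = expr_sd,
    chrom = chrom, chrom_length = chrom_length,
    contam_region = contam_region, n_genes = n_genes, n_islands = n_islands,
    snp_spacing = snp_spacing, seed = seed
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  assert_scalar_number(cfg$n_per_group, "n_per_group", lower = 1)
  assert_scalar_number(cfg$n_sites, "n_sites", lower = 0)
  assert_scalar_number(cfg$n_clusters_true, "n_clusters_true", lower = 0)
  assert_scalar_number(cfg$n_dmrs_true, "n_dmrs_true", lower = 0)
  assert_scalar_number(cfg$n_baseline_dmrs, "n_baseline_dmrs", lower = 0)
  if (cfg$n_dmrs_true + cfg$n_baseline_dmrs > cfg$n_clusters_true) {
    abort("n_dmrs_true + n_baseline_dmrs must be <= n_clusters_true",
          class = "dmrbeta_config_error")
  }
  assert_scalar_number(cfg$within_cluster_rho, "within_cluster_rho", 0, 1)
  assert_scalar_number(cfg$latent_sd, "latent_sd", lower = 0)
  assert_scalar_number(cfg$depth_mean, "depth_mean", lower = .Machine$double.eps)
  assert_scalar_number(cfg$depth_dispersion, "depth_dispersion",
                       lower = .Machine$double.eps)
  assert_scalar_number(cfg$baseline_logit_sd, "baseline_logit_sd", lower = 0)
  assert_scalar_number(cfg$n_probes, "n_probes", lower = 0)
  assert_scalar_number(cfg$n_cis_true, "n_cis_true", 0, cfg$n_probes)
  assert_scalar_number(cfg$n_de_true, "n_de_true", 0, cfg$n_probes)
  assert_scalar_number(cfg$expr_sd, "expr_sd", lower = 0)
  assert_scalar_number(cfg$chrom_length, "chrom_length", lower = 1)
  assert_scalar_number(cfg$snp_spacing, "snp_spacing", lower = 1)
  assert_scalar_number(cfg$seed, "seed", lower = -2^31, upper = 2^31 - 1)
  if (!is.null(cfg$contam_region)) {
    if (length(cfg$contam_region) != 2L ||
        cfg$contam_region[1] >= cfg$contam_region[2] ||
        cfg$contam_region[1] < 0 ||
        cfg$contam_region[2] > cfg$chrom_length) {
      abort("contam_region must be c(start, end) within [0, chrom_length)",
            class = "dmrbeta_config_error")
    }
  }
  structure(cfg, class = "dmrbeta_config")
}
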