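small_cfg <- function(n_dmrs_true = 3, contam_region = c(2e6, 5e6), ...) {
  sim_config(n_per_group = 4, n_sites = 120, n_clusters_true = 12,
             n_dmrs_true = n_dmrs_true, n_probes = 30, n_cis_true = 3,
             n_de_true = 3, chrom_length = 1e7,
             contam_region = contam_region,
             n_genes = 10, n_islands = 10, ...)
}

test_that("counts respect their bounds and ordering", {
  d <- simulate_dataset(small_cfg(seed = 5))
  expect_true(all(d$counts$meth >= 0))
  expect_true(all(d$counts$meth <= d$counts$depth))
  expect_true(all(d$counts$depth >= 1))
  pos <- unique(d$counts$pos)
  expect_false(is.unsorted(pos, strictly = TRUE))
})

test_that("identical seeds give byte-identical written files", {
  dirs <- file.path(withr::local_tempdir(), c("a", "b"))
  for (dir in dirs) {
    cfg <- small_cfg(seed = 7)
    write_study_files(simulate_dataset(cfg), dir,
                      snps = simulate_strain_snps(cfg))
  }
  fa <- sort(list.files(dirs[1], recursive = TRUE))
  fb <- sort(list.files(dirs[2], recursive = TRUE))
  expect_identical(fa, fb)
  md5a <- unname(tools::md5sum(file.path(dirs[1], fa)))
  md5b <- unname(tools::md5sum(file.path(dirs[2], fb)))
  expect_identical(md5a, md5b)
})

test_that("no planted effects means an empty true-DMR table", {
  d <- simulate_dataset(small_cfg(n_dmrs_true = 0, seed = 2))
  expect_identical(nrow(d$truth$dmr_intervals), 0L)
  expect_true(all(d$truth$clusters$type == "null"))
})

test_that("every true DMR interval contains at least 3 simulated sites", {
  d <- simulate_dataset(small_cfg(seed = 9))
  pos <- unique(d$counts$pos)
  for (i in seq_len(nrow(d$truth$dmr_intervals))) {
    tr <- d$truth$dmr_intervals[i, ]
    expect_gte(sum(pos >= tr$start & pos < tr$end), 3)
    expect_lte(tr$end, d$config$chrom_length)
  }
})

test_that("grand mean methylation is near 0.5 when the baseline logit is centred", {
  # Monte-Carlo over replicate generators; each replicate pools ~2k sites
  means <- vapply(1:20, function(s) {
    d <- simulate_dataset(
      sim_config(n_per_group = 2, n_sites = 250, n_clusters_true = 10,
                 n_dmrs_true = 0, n_probes = 0, n_cis_true = 0,
                 n_de_true = 0, baseline_logit_mean = 0,
                 chrom_length = 5e6, contam_region = NULL, n_genes = 2,
                 n_islands = 2, seed = 100 + s))
    mean(d$counts$meth / d$counts$depth)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.02)
})

test_that("within-cluster correlation of site proportions approaches the target", {
  rho <- 0.9
  d <- simulate_dataset(
    sim_config(n_per_group = 60, n_sites = 200, n_clusters_true = 25,
               n_dmrs_true = 0, n_probes = 0, n_cis_true = 0, n_de_true = 0,
               within_cluster_rho = rho, depth_mean = 2000,
               chrom_length = 2e7, contam_region = NULL, n_genes = 2,
               n_islands = 2, seed = 42))
  cors <- c()
  for (k in seq_len(nrow(d$truth$clusters))) {
    ps <- d$truth$clusters$positions[[k]]
    sub <- d$counts[d$counts$pos %in% ps, ]
    w <- tidyr::pivot_wider(sub[c("pos", "sample", "meth", "depth")],
                            names_from = "sample",
                            values_from = c("meth", "depth"))
    nm <- grepl("^meth_", names(w))
    prop <- as.matrix(w[nm]) / as.matrix(w[gsub("meth", "depth", names(w)[nm])])
    cm <- stats::cor(t(prop))
    cors <- c(cors, cm[upper.tri(cm)])
  }
  # high depth limit: binomial attenuation is small but not zero
  expect_gt(mean(cors), rho - 0.08)
  expect_lt(mean(cors), rho + 0.05)
})

test_that("planted group effect is recovered from group mean proportions", {
  # difference in logit of group-mean proportions over true DMR sites
  # converges to effect_logit as samples and depth grow
  d <- simulate_dataset(
    sim_config(n_per_group = 150, n_sites = 160, n_clusters_true = 30,
               n_dmrs_true = 30, effect_logit = 1.0, depth_mean = 500,
               n_probes = 0, n_cis_true = 0, n_de_true = 0,
               chrom_length = 2e7, contam_region = NULL, n_genes = 2,
               n_islands = 2, seed = 11))
  grp <- setNames(sim_groups(d$design), d$design$sample)
  effs <- vapply(seq_len(nrow(d$truth$dmr_intervals)), function(i) {
    tr <- d$truth$dmr_intervals[i, ]
    sub <- d$counts[d$counts$pos %in% tr$positions[[1]], ]
    sub$group <- grp[sub$sample]
    ko <- sub[sub$group == "KO_HDM", ]; wt <- sub[sub$group == "WT_HDM", ]
    tr$sign * (qlogis(mean(ko$meth / ko$depth)) -
                 qlogis(mean(wt$meth / wt$depth)))
  }, numeric(1))
  expect_lt(abs(mean(effs) - 1.0), 0.08)
})

test_that("strain SNP panel matches the planted contamination pattern", {
  cfg <- small_cfg(seed = 13)
  snps <- simulate_strain_snps(cfg)
  design <- simulate_dataset(cfg)$design
  snps <- dplyr::left_join(snps, design, by = "sample")
  inside <- snps$pos >= 2e6 & snps$pos < 5e6
  expect_gt(mean(snps$matches_alt[inside & snps$genotype == "KO"]), 0.9)
  expect_lt(mean(snps$matches_alt[inside & snps$genotype == "WT"]), 0.05)
  expect_lt(mean(snps$matches_alt[!inside]), 0.05)
  # no contamination planted: no positional enrichment anywhere
  snps0 <- simulate_strain_snps(small_cfg(contam_region = NULL, seed = 13))
  snps0 <- dplyr::left_join(snps0, design, by = "sample")
  in0 <- snps0$pos >= 2e6 & snps0$pos < 5e6
  expect_lt(abs(mean(snps0$matches_alt[in0]) -
                  mean(snps0$matches_alt[!in0])), 0.02)
  # determinism
  expect_identical(snps, dplyr::left_join(simulate_strain_snps(cfg), design,
                                          by = "sample"))
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(sim_config(n_dmrs_true = 10, n_clusters_true = 5),
               "n_dmrs_true")
  expect_error(sim_config(within_cluster_rho = 1.5), "within_cluster_rho")
  expect_error(sim_config(depth_mean = 0), "depth_mean")
  expect_error(sim_config(contam_region = c(5e7, 9e7)), "contam_region")
})
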