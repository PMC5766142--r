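# a fully synthetic miniature for the pairing logic: one gated cluster, a
# probe exactly at the window edge and one just beyond
test_that("the cis window boundary is respected midpoint-to-midpoint", {
  design <- toy_design(sprintf("s%d", 1:8),
                       rep(c("KO", "WT"), each = 4), "HDM")
  set.seed(1)
  cl_data <- tibble::tibble(sample = design$sample, meth = 10L, depth = 30L,
                            y = plogis(rnorm(8)), missing = FALSE)
  clusters <- tibble::tibble(cluster_id = 1L, chrom = "c1", start = 1000L,
                             end = 1100L, n_sites = 3L,
                             positions = list(c(1000L, 1050L, 1098L)),
                             data = list(cl_data))
  dmrs <- tibble::tibble(cluster_id = 1L, chrom = "c1", start = 1000L,
                         end = 1100L, p_raw = 0.01)
  mid <- floor((1000 + 1100) / 2)   # 1050
  mk_probe <- function(id, p_mid) {
    tibble::tibble(probe_id = id, chrom = "c1", start = p_mid - 30L,
                   end = p_mid + 30L)
  }
  expr <- dplyr::bind_rows(mk_probe("at_edge", mid + 1000000L),
                           mk_probe("beyond", mid + 1000001L),
                           mk_probe("near", mid + 5000L))
  vals <- matrix(rnorm(3 * 8, 8), 3, 8, dimnames = list(NULL, design$sample))
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(as.data.frame(vals)))
  got <- cis_scan(dmrs, clusters, expr, design, p_gate = 0.05,
                  window_bp = 1e6)
  expect_setequal(got$probe_id, c("at_edge", "near"))
  expect_equal(got$distance_bp[got$probe_id == "at_edge"], 1e6)
})

test_that("no clusters under the gate yields an empty scan with a warning", {
  design <- toy_design(sprintf("s%d", 1:4), c("KO", "KO", "WT", "WT"), "HDM")
  dmrs <- tibble::tibble(cluster_id = 1L, chrom = "c1", start = 1L,
                         end = 10L, p_raw = 0.2)
  expr <- tibble::tibble(probe_id = "p", chrom = "c1", start = 1L, end = 61L)
  for (s in design$sample) expr[[s]] <- 1
  expect_warning(got <- cis_scan(dmrs, tibble::tibble(), expr, design),
                 "no candidate")
  expect_identical(nrow(got), 0L)
})

test_that("tested pairs equal a brute-force double loop on simulated data", {
  cfg <- sim_config(n_per_group = 4, n_sites = 300, n_clusters_true = 30,
                    n_dmrs_true = 8, n_probes = 60, n_cis_true = 6,
                    chrom_length = 2e7, contam_region = NULL,
                    n_genes = 5, n_islands = 5, seed = 61)
  d <- simulate_dataset(cfg)
  cl <- summarize_clusters(cluster_adjacent_sites(d$counts), d$counts)
  dmr <- call_dmrs(cl, d$design)
  norm <- log2_transform(quantile_normalize(d$expression,
                                            design = d$design),
                         design = d$design)
  got <- cis_scan(dmr, cl, norm, d$design)
  want <- 0L
  for (i in seq_len(nrow(dmr))) {
    if (is.na(dmr$p_raw[i]) || dmr$p_raw[i] >= 0.05) next
    cmid <- floor((dmr$start[i] + dmr$end[i]) / 2)
    for (j in seq_len(nrow(norm))) {
      if (is.na(norm$start[j]) || norm$chrom[j] != dmr$chrom[i]) next
      pmid <- floor((norm$start[j] + norm$end[j]) / 2)
      if (abs(cmid - pmid) <= 1e6) want <- want + 1L
    }
  }
  expect_identical(nrow(got), want)
  expect_true(all(got$distance_bp <= 1e6))
  expect_true(all(got$p_adj >= got$p_raw, na.rm = TRUE))
})

test_that("coefficient signs agree with strong observed correlations", {
  cfg <- sim_config(n_per_group = 6, n_sites = 200, n_clusters_true = 20,
                    n_dmrs_true = 10, n_probes = 50, n_cis_true = 10,
                    chrom_length = 2e7, contam_region = NULL,
                    n_genes = 5, n_islands = 5, seed = 62)
  d <- simulate_dataset(cfg)
  cl <- summarize_clusters(cluster_adjacent_sites(d$counts), d$counts)
  dmr <- call_dmrs(cl, d$design)
  norm <- log2_transform(quantile_normalize(d$expression,
                                            design = d$design),
                         design = d$design)
  got <- cis_scan(dmr, cl, norm, d$design)
  hdm <- d$design$sample[d$design$treatment == "HDM"]
  geno <- d$design$genotype[match(hdm, d$design$sample)]
  checked <- agree <- 0L
  for (i in seq_len(nrow(got))) {
    cd <- cl$data[[which(cl$cluster_id == got$cluster_id[i])]]
    y <- cd$y[match(hdm, cd$sample)]
    e <- as.numeric(norm[norm$probe_id == got$probe_id[i], hdm])
    # the model adjusts for genotype, so compare against the
    # genotype-partialled correlation
    r <- suppressWarnings(cor(resid(lm(y ~ geno)), resid(lm(e ~ geno))))
    if (is.na(r) || abs(r) <= 0.5 || is.na(got$estimate[i])) next
    checked <- checked + 1L
    agree <- agree + (got$sign[i] == ifelse(r < 0, "-", "+"))
  }
  expect_gt(checked, 5L)
  expect_identical(agree, checked)
})

test_that("exact binomial enrichment matches enumeration and hand cases", {
  # four pairs, two negative, one-sided: 11/16 by enumerating all outcomes
  r4 <- tibble::tibble(sign = c("-", "-", "+", "+"),
                       p_raw = c(0.2, 0.3, 0.4, 0.5),
                       significant = FALSE)
  got <- enrichment_tests(r4)
  expect_equal(got$p_value[got$test == "negative_direction"], 11 / 16)
  # a single negative pair: tail is exactly one half
  r1 <- tibble::tibble(sign = "-", p_raw = 0.4, significant = FALSE)
  expect_equal(enrichment_tests(r1)$p_value[1], 0.5)
  # no significant pairs: the sign-balance test reports a reason
  expect_identical(
    got$reason[got$test == "sign_balance_significant"],
    "no eligible observations")
})

test_that("the normality check reports a Shapiro-Wilk p-value", {
  set.seed(4)
  r <- tibble::tibble(estimate = rnorm(50))
  expect_equal(coefficient_normality(r),
               shapiro.test(r$estimate)$p.value)
  expect_true(is.na(coefficient_normality(tibble::tibble(estimate = 1))))
})

test_that("under a global null the cis scan controls the FDR", {
  cfg <- sim_config(n_per_group = 6, n_sites = 300, n_clusters_true = 40,
                    n_dmrs_true = 10, n_probes = 80, n_cis_true = 0,
                    chrom_length = 2e7, contam_region = NULL,
                    n_genes = 5, n_islands = 5, seed = 63)
  d <- simulate_dataset(cfg)
  cl <- summarize_clusters(cluster_adjacent_sites(d$counts), d$counts)
  dmr <- call_dmrs(cl, d$design)
  norm <- log2_transform(quantile_normalize(d$expression,
                                            design = d$design),
                         design = d$design)
  got <- cis_scan(dmr, cl, norm, d$design)
  expect_gt(nrow(got), 20)
  expect_lte(mean(got$significant), 0.05 + 2 / nrow(got))
})
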