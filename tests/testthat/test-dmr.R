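sim_tested_dmrs <- function(seed = 51, ...) {
  d <- simulate_dataset(sim_config(n_per_group = 5, n_sites = 150,
                                   n_clusters_true = 15, n_dmrs_true = 3,
                                   n_probes = 0, n_cis_true = 0,
                                   n_de_true = 0, chrom_length = 1e7,
                                   contam_region = NULL, n_genes = 10,
                                   n_islands = 5, seed = seed, ...))
  cl <- summarize_clusters(cluster_adjacent_sites(d$counts), d$counts)
  list(data = d, dmr = call_dmrs(cl, d$design, genes = d$genes))
}

test_that("BH adjustment matches hand-applied step-up on fixed vectors", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_error(bh_adjust(c(0.2, 1.4)), class = "dmrbeta_input_error")
})

test_that("BH is a monotone transform: permuting inputs permutes outputs", {
  set.seed(8)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_equal(bh_adjust(p), oracle_bh(p))
})

test_that("the adjusted-p threshold for DMR calls is inclusive", {
  run <- sim_tested_dmrs()
  dmr <- run$dmr
  # re-call at a threshold exactly equal to an achieved adjusted p
  q_star <- sort(dmr$p_adj)[3]
  cl <- summarize_clusters(cluster_adjacent_sites(run$data$counts),
                           run$data$counts)
  re <- call_dmrs(cl, run$data$design, q_threshold = q_star,
                  genes = run$data$genes)
  expect_true(all(re$called[re$p_adj == q_star]))
  expect_identical(sum(re$called), sum(re$p_adj <= q_star, na.rm = TRUE))
})

test_that("direction reflects the sign of the group coefficient", {
  run <- sim_tested_dmrs()
  ok <- !is.na(run$dmr$estimate)
  expect_identical(run$dmr$direction[ok],
                   ifelse(run$dmr$estimate[ok] < 0, "hypo", "hyper"))
  expect_true(all(run$dmr$p_adj >= run$dmr$p_raw, na.rm = TRUE))
})

test_that("nearest genes are the closest by midpoint with deterministic ties", {
  genes <- tibble::tibble(chrom = "c1",
                          start = c(1000L, 5000L, 5000L),
                          end = c(2000L, 6000L, 6000L),
                          name = c("zeta", "beta", "alpha"),
                          strand = "+")
  res <- tibble::tibble(cluster_id = 1:2, chrom = "c1",
                        start = c(2100L, 5500L), end = c(2200L, 5600L))
  got <- dmrbeta:::annotate_nearest_gene(res, genes)
  expect_identical(got$nearest_gene, c("zeta", "alpha"))
  expect_equal(got$gene_distance, c(151, 0))
})

test_that("baseline subtraction flags overlap or shared-gene matches", {
  treated <- tibble::tibble(
    cluster_id = 1:4, chrom = "c1",
    start = c(100L, 5000L, 9000L, 20000L),
    end = c(300L, 5200L, 9100L, 20100L),
    called = TRUE, baseline_shared = FALSE, blacklisted = FALSE,
    nearest_gene = c("g1", "g2", "g3", "g4"))
  baseline <- tibble::tibble(
    cluster_id = 1:2, chrom = "c1",
    start = c(299L, 40000L), end = c(400L, 40100L),
    called = c(TRUE, TRUE), nearest_gene = c("gX", "g3"))
  got <- subtract_baseline(treated, baseline)
  expect_identical(got$baseline_shared, c(TRUE, FALSE, TRUE, FALSE))

  # empty baseline leaves the list untouched
  expect_identical(subtract_baseline(treated, baseline[0, ]), treated)

  # random panels against the O(n*m) oracle
  set.seed(6)
  for (rep in 1:5) {
    tr <- tibble::tibble(cluster_id = 1:20, chrom = "c1",
                         start = sample.int(1e5, 20))
    tr$end <- tr$start + sample.int(500, 20)
    tr$called <- TRUE; tr$baseline_shared <- FALSE; tr$blacklisted <- FALSE
    tr$nearest_gene <- sample(sprintf("g%d", 1:8), 20, replace = TRUE)
    ba <- tibble::tibble(cluster_id = 1:10, chrom = "c1",
                         start = sample.int(1e5, 10))
    ba$end <- ba$start + sample.int(500, 10)
    ba$called <- TRUE
    ba$nearest_gene <- sample(sprintf("g%d", 1:8), 10, replace = TRUE)
    got <- subtract_baseline(tr, ba)$baseline_shared
    want <- oracle_overlaps(tr, ba) | tr$nearest_gene %in% ba$nearest_gene
    expect_identical(got, want)
  }
})

test_that("strain blacklisting requires group-specific matching", {
  design <- toy_design(sprintf("s%d", 1:8),
                       rep(c("WT", "KO"), each = 4),
                       rep(c("saline", "HDM"), 4))
  pos <- seq(10000L, 990000L, by = 20000L)
  none <- tidyr::expand_grid(chrom = "c1", pos = pos,
                             sample = design$sample) |>
    dplyr::mutate(matches_alt = FALSE)
  expect_identical(nrow(detect_strain_blacklist(none, design,
                                                window_bp = 2e5,
                                                step_bp = 1e5)), 0L)
  # matches in both groups equally: not flagged
  both <- dplyr::mutate(none, matches_alt = TRUE)
  expect_identical(nrow(detect_strain_blacklist(both, design,
                                                window_bp = 2e5,
                                                step_bp = 1e5)), 0L)
  # KO-specific matches are flagged and merged
  ko_only <- dplyr::mutate(
    none, matches_alt = .data$sample %in% design$sample[design$genotype == "KO"] &
      .data$pos >= 3e5 & .data$pos < 7e5)
  got <- detect_strain_blacklist(ko_only, design, window_bp = 2e5,
                                 step_bp = 1e5)
  expect_identical(nrow(got), 1L)
  expect_lte(got$start, 3e5)
  expect_gte(got$end, 7e5)
  expect_error(detect_strain_blacklist(none, design, window_bp = 1e5,
                                       step_bp = 2e5),
               class = "dmrbeta_config_error")
})

test_that("blacklisted DMRs are flagged, not deleted, and excluded from calls", {
  dmrs <- tibble::tibble(cluster_id = 1:3, chrom = "c1",
                         start = c(100L, 1000L, 5000L),
                         end = c(200L, 1100L, 5100L),
                         called = TRUE, baseline_shared = FALSE,
                         blacklisted = FALSE)
  bl <- tibble::tibble(chrom = "c1", start = 900, end = 1050)
  got <- apply_blacklist(dmrs, bl)
  expect_identical(got$blacklisted, c(FALSE, TRUE, FALSE))
  expect_identical(nrow(got), 3L)
  expect_identical(dmr_calls(got)$cluster_id, c(1L, 3L))
})

test_that("gene-subset analysis re-adjusts within the subset with an inclusive boundary", {
  dmrs <- tibble::tibble(cluster_id = 1:5, chrom = "c1",
                         start = c(74900L, 74899L, 100500L, 200000L, 135100L),
                         end = c(75000L, 74999L, 100600L, 200100L, 135200L),
                         p_raw = c(0.005, 0.1, 0.9, 0.001, 0.02))
  genes <- tibble::tibble(name = "geneA", chrom = "c1",
                          start = 100000L, end = 110000L)
  got <- subset_near_genes(dmrs, genes, distance_bp = 25000,
                           q_threshold = 0.10)
  # cluster 1 ends exactly 25,000 bp away: included; cluster 2 is 25,001: out
  expect_true(1L %in% got$cluster_id)
  expect_false(2L %in% got$cluster_id)
  # cluster 4 is far away; cluster 3 overlaps (distance 0); cluster 5 is 25,100 out
  expect_setequal(got$cluster_id, c(1L, 3L))
  expect_equal(got$p_adj_subset[got$cluster_id == 1L],
               oracle_bh(c(0.005, 0.9))[1])

  # five clusters with stated p-values: subset BH equals hand step-up
  dmrs5 <- tibble::tibble(cluster_id = 1:5, chrom = "c1",
                          start = 100000L + (0:4) * 1000L,
                          end = 100100L + (0:4) * 1000L,
                          p_raw = c(0.01, 0.02, 0.03, 0.04, 0.5))
  got5 <- subset_near_genes(dmrs5, genes, distance_bp = 25000)
  expect_equal(sort(got5$p_adj_subset), sort(oracle_bh(dmrs5$p_raw)))

  # unresolvable gene names are warned about and skipped
  expect_warning(
    empty <- subset_near_genes(dmrs, "nope",
                               genes = tibble::tibble(
                                 chrom = "c1", start = 1L, end = 2L,
                                 name = "other", strand = "+")),
    "nope")
  expect_identical(nrow(empty), 0L)
})
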