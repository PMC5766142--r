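---
title: "Models and methods behind dmrbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dmrbeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dmrbeta)
```

This vignette explains the statistical models the package implements, the
choices that were genuinely open when it was designed, and what its
synthetic-data validation does and does not demonstrate.

## The analysis problem

The package targets studies that profile DNA methylation by targeted
bisulfite capture in a two-factor design — genotype (WT vs a knockout)
crossed with treatment (saline vs an allergen such as house-dust-mite
extract) — together with an expression array on the same animals. The
scientific questions are (i) which groups of neighbouring CpG sites are
differentially methylated between genotypes under treatment, after
removing differences that already exist at baseline and regions where the
knockout line carries a different strain background, and (ii) which nearby
transcripts co-vary with those methylation clusters in *cis*.

## Adjacent-site clustering

Methylation is spatially correlated: neighbouring CpGs tend to change
together, and testing clusters instead of single sites pools depth and
reduces the multiple-testing burden. `cluster_adjacent_sites()` performs a
bottom-up agglomeration per chromosome. Every site starts as a singleton;
a cluster merges with its right neighbour while

* the genomic gap between their nearest member sites is at most
  `max_gap_bp` (default 1,000 bp), and
* the *complete-linkage* similarity — the minimum Spearman correlation of
  per-site methylation proportions across samples, over all cross-cluster
  site pairs — is at least `corr_threshold` (default 0.5).

Merging sweeps left-to-right and repeats until no merge is possible;
clusters with fewer than `min_sites` (default 3) sites are dropped.

Design choices worth recording:

* **Spearman, not Pearson.** Proportions live on a bounded, logit-warped
  scale; a rank correlation is invariant to that warping.
* **Complete linkage.** Taking the *minimum* cross-pair correlation
  prevents chaining, where a run of pairwise-similar sites grows into a
  long cluster whose ends are uncorrelated.
* **Determinism.** The left-to-right sweep with merge-left-first
  tie-breaking makes output independent of any hash or processing order;
  the result is also invariant to sample ordering, which the test suite
  checks.
* **Depth filter.** A sample enters a pairwise correlation only if both
  sites have depth at least `min_depth` (default 5); a pair with fewer than
  3 usable samples, or a degenerate proportion vector, is uncorrelatable
  and never merged across. Only the 3-site minimum is externally fixed;
  the other defaults are conventional and exposed in the API.

## Depth-weighted beta regression

Each cluster is summarized per sample by the pooled proportion
$y_s = \sum_i m_{is} / \sum_i d_{is}$ and pooled depth $D_s$. The response
model is a beta regression in the mean–precision parameterization,

$$y_s \sim \mathrm{Beta}(\mu_s \phi, (1-\mu_s)\phi), \qquad
  \operatorname{logit}(\mu_s) = \mathbf{x}_s^\top \beta,$$

whose weighted log-likelihood
$\ell(\beta,\phi) = \sum_s w_s \log f(y'_s;\mu_s,\phi)$ is maximized
numerically. Conventions:

* **Boundary shrinkage.** The beta density is undefined at 0 and 1, and
  pooled proportions do reach the boundary at moderate depth, so responses
  are shrunk with $y' = (y(n-1) + 0.5)/n$ (Smithson–Verkuilen), $n$ being
  the number of non-missing samples for the cluster.
* **Weight normalization.** Raw depths as likelihood weights would let a
  deeply sequenced cluster masquerade as having more animals than it does.
  Weights are rescaled to sum to $n$: $w_s = n D_s / \sum_t D_t$. Equal
  depths then reproduce the unweighted fit exactly (tested).
* **Optimization.** Start values come from weighted least squares on
  $\operatorname{logit}(y')$ and a method-of-moments precision; the search
  runs L-BFGS-B on $(\beta, \log\phi)$ with $\phi \in [0.01, 10^6]$, a
  Nelder–Mead fallback, and non-intercept covariates centred internally
  for conditioning (the intercept and its variance are transformed back).
  Non-convergence or a singular Hessian yields `converged = FALSE`, which
  downstream tests treat as p = 1 — conservative rather than silent.
* **Small-sample Wald calibration.** The Wald test was retained (it is the
  conventional, cheap per-cluster default), but at $n \approx 20$ the ML
  precision estimate is biased upward, deflating Hessian-based standard
  errors: the plain normal-reference Wald test is anticonservative at the
  nominal 5% level and, more damaging for FDR control, roughly twofold
  inflated in the far tail. The package therefore inflates standard errors
  by $\sqrt{n/(n-p)}$ — the analogue of the ML-versus-residual-df variance
  bias in a normal model — and refers the ratio to $t_{n-p-1}$. The
  acceptance suite verifies the resulting type-I error on 2,000 simulated
  null clusters sits near nominal.

DMRs are called by Benjamini–Hochberg across all fitted clusters at
adjusted p ≤ 0.10, *inclusive* — the boundary convention follows the
threshold's statement "adjusted p ≤ 0.10". Expression and cis thresholds
(adjusted p < 0.05) and the cis gate (raw p < 0.05) are strict, following
their "< 0.05" statements. Direction is `hypo` when the first contrast
group (the knockout cell) is less methylated.

## Baseline subtraction, blacklist, subsets

* `subtract_baseline()` flags a treated-contrast DMR that either overlaps
  (≥ 1 bp) a called baseline-contrast DMR **or** shares its nearest gene —
  the union criterion, since either relation marks the signal as
  constitutive rather than treatment-dependent. Flagged calls are retained
  in the full table and excluded from `dmr_calls()`.
* `detect_strain_blacklist()` slides windows (default 1 Mb window, 0.5 Mb
  step) over a strain-informative SNP panel and flags windows where KO
  samples match the alternate strain at ≥ `match_frac` (default 0.9) while
  WT samples stay at ≤ 1 − `match_frac`; overlapping flagged windows merge.
  Only the *outcome* of such screening (a multi-megabase excluded block) is
  externally specified; the window rule is this package's operationalization
  and is fully parameterized.
* `subset_near_genes()` restricts to clusters within 25 kb (inclusive) of a
  supplied gene list and re-runs BH *within the subset*, the standard way
  to gain power for a hypothesis-driven gene set.
* Nearest gene: minimum distance from cluster midpoint to gene body, ties
  broken lexicographically — determinism again.

## Annotation

Gene context uses overlap with precedence promoter > 5′UTR > 3′UTR > exon >
intron > intergenic. The promoter is `promoter_bp` (default 2,000) upstream
of the strand-aware TSS; UTRs are the exonic portions outside the thick
(CDS) interval of the BED12 gene model. Island context is driven by the gap
(bases strictly between intervals) to the nearest CpG island: 0 = island,
1–3,000 = shore, > 3,000 = distant. The 3,000 bp shore band was chosen so
the "distant" category matches the > 3,000-base convention this pipeline is
built around, rather than the 2 kb shore / 4 kb shelf convention used
elsewhere.

## Expression stage

Raw intensities undergo classical rank-mean quantile normalization
(`limma::normalizeQuantiles`, tie-averaged) and `log2(x + 1)`; the offset
avoids log of zero and is configurable. Each probe is fit with a cell-means
model over the four genotype × treatment cells; the requested cell
difference is tested with a t statistic on the pooled within-cell variance
(df = N − 4). Pairwise cell contrasts were chosen over an omnibus ANOVA F
because the scientific comparisons are pairwise (KO vs WT within each
treatment). Probes significant in the baseline (saline) contrast are
flagged and excluded from the headline list; constant probes get p = 1 and
a `degenerate` flag.

## cis methylation–expression scan

Clusters passing the raw-p gate are paired with all coordinate-bearing
probes within `window_bp` (default 1 Mb) *midpoint to midpoint* — midpoints
avoid ambiguity for long clusters or probes. Methylation is the response
and expression the predictor (the association model "fits methylation to
expression"), with genotype as an additive covariate so a shared genotype
effect on both molecules is not mistaken for a cis link; the scan runs on
the HDM-treated samples, matching the contrast that produced the gate.
The expression coefficient's sign defines the association sign; BH runs
across all tested pairs.

Enrichment statistics use exact binomial tails: negative-direction
enrichment vs 0.5 (one-sided), nominal raw-p < 0.05 enrichment vs 0.05
(one-sided), and sign balance among significant pairs vs 0.5 (two-sided),
plus the same one-sided tail for hypomethylation among DMR calls. A
Shapiro–Wilk p for the coefficient distribution is reported for context
only and gates nothing.

## The synthetic-data generator

`simulate_dataset()` emulates the data structure the analysis assumes:

* sites laid out in well-separated slots along one synthetic chromosome
  ("chrS"; anchors far apart relative to `max_gap_bp`, so distinct slots
  cannot merge by adjacency), planted clusters of 3–8 sites spaced
  20–150 bp;
* logit-scale latent structure
  $\operatorname{logit}(p_{is}) = b_i + u_{c(i)s} + e_{is} + \delta_c$,
  with a shared Gaussian $(cluster, sample)$ latent $u$ and site noise $e$
  split so the within-cluster latent correlation is `within_cluster_rho`;
* negative-binomial depths floored at 1; binomial methylated counts;
* a contiguous alternate-strain block with a genome-wide informative SNP
  panel (KO match rate 0.98 inside, 0.02 background);
* expression probes at raw intensity scale with planted KO-HDM-specific
  log2 shifts and planted cis links of both signs.

Two generator design decisions deserve emphasis because they define what
"recovering the truth" means:

* **Effects are planted on the estimand scale.** The beta regression
  estimates the *marginal* effect — the difference in logit of the
  group-mean proportion. Under a Gaussian per-sample latent, a shift
  applied directly on the latent logit is recovered attenuated (by
  marginalization, ≈ 7% at the default latent spread, more after boundary
  shrinkage), so the generator instead solves per cluster, by quadrature
  and root finding, for the latent shift whose marginal logit-of-mean
  difference equals `effect_logit`. Planting the quantity the estimator
  estimates is the right construction for validating the estimator; the
  residual finite-sample compression from boundary shrinkage (a few
  percent at n = 20) remains visible in the recovery checks, as it should.
* **cis links are linear on the latent logit.** A proportion-scale link
  collapses for clusters with extreme baselines (the logistic squashes
  their dynamic range), making planted pairs undetectable by construction
  rather than by statistical difficulty. The logit link matches the scale
  of the association model and keeps planted strength comparable across
  clusters. `cis_slope` is therefore in log2-expression units per logit
  of methylation; the default (3, with residual SD 0.5) encodes a strong,
  near-deterministic link appropriate for a recovery benchmark.

Defaults describe the emulated study: 10 animals per genotype × treatment
cell, 2,000 CpG sites in 200 clusters, 5 treatment-specific DMRs at
`effect_logit` 1.5, mean depth 30 (dispersion 5), baseline logit spread
1.2, latent correlation 0.95 with total latent SD 0.6 (sample-to-sample
spread of roughly 5–15 percentage points of methylation — variably
methylated regions; a latent spread much smaller than this is undetectable
as correlation at depth 30, and one much larger is unrealistic for
replicate animals), 400 probes, 20 planted cis pairs, and a 14 Mb
contaminated block on a 60 Mb chromosome.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: read-level artifacts (bisulfite conversion failure,
mapping bias, strand asymmetries), genome-wide baseline bimodality and
island/shore methylation topography, probe-level hybridization artifacts
and batch structure, correlated depth between neighbouring sites, and any
trans regulation. Results on real data additionally depend on alignment and
methylation-extraction choices that sit upstream of this package's inputs.

## Problem sizes and reproducibility

The validation suite works at deliberately modest sizes — panels of ≤ 50
sites × 8 samples against a brute-force clustering oracle, a 21×21×11
likelihood grid for 100 clusters, 2,000 null clusters for type-I error, 10
replicate studies for power and realized FDP, two studies of 220 clusters
for effect recovery, and two for cis recovery — sizes at which the
brute-force oracles are exact and the whole suite runs in minutes on one
CPU. `scripts/acceptance.R` recomputes the same quantities from a single
`--seed`, which drives every random draw; two runs with the same
configuration and seed produce byte-identical outputs (the run report
carries the seed and a configuration hash).

## Interfaces

The package is a library, not a shell tool: stage functions take and
return tibbles and chain with the pipe, `pipeline_config()` +
`run_pipeline()` orchestrate the whole analysis with a machine-readable
run report, and `autoplot()` methods cover the main result types. Coverage
files may be read as 1-based (bismark dialect, the default) or 0-based via
the `dialect` argument; all internal coordinates are 0-based half-open.

## Known limitations

* The Wald test, even calibrated, is approximate; clusters with very few
  usable samples are skipped rather than tested exactly.
* No dispersion sharing across clusters (no empirical-Bayes shrinkage of
  $\phi$); each cluster is fit independently.
* The blacklist detector assumes the contamination is genotype-linked and
  contiguous at the window scale; mosaic or shared contamination is not
  modelled.
* Beta-regression coefficients for near-boundary clusters are compressed
  by the boundary shrinkage; effect sizes for clusters near 0% or 100%
  methylation are conservative.
* The cis scan tests pairs marginally; it does not model linkage between
  overlapping windows or multiple probes per transcript.
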