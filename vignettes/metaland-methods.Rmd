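---
title: "Models and methods behind metaland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

metaland analyses a two-landscape metapopulation design: four regional
populations, two from fragmented and two from continuous landscapes,
with bulk RNA-seq providing both expression counts and — through SNPs
called from the aligned reads — genotype information for the same
individuals. This vignette explains each model, the tunable parameters
that matter, the synthetic-data generator that stands in for a real
study, and the numerical and design choices a maintainer should know
about.

## SNP calling and genotype scoring

SNPs enter the analysis as per-(SNP, individual) reference/alternate
read depths. Three order-independent filters define the retained panel:

* **biallelic**: both alleles observed in the pooled reads (the input
  is biallelic by construction, so this reduces to "ref seen and alt
  seen");
* **coverage**: at least `min_individuals_per_pop` (default 10)
  individuals with depth ≥ `min_base_depth` (default 1) in *every*
  population;
* **MAC**: pooled minor allele count at least
  `ceiling(mac_fraction × N)` over the N sampled individuals — 9 at
  N = 174 with the default 5%.

Genotypes are scored directly from read counts: heterozygous when at
least 3 reads support *each* allele, homozygous when a single allele is
seen with ≥ 10 reads, otherwise missing. The MAC filter counts allele
copies over these scored genotypes (two per called individual); whether
it should instead count reads is unspecified upstream, and the
genotype-copy interpretation is the package's recorded choice. Base
quality filtering is assumed to have happened before the count matrix
and is represented only by the `min_base_depth` knob.
`threshold_robustness_scan()` re-derives landscape frequency
differences under depth thresholds 1..10 and reports their pairwise
Spearman correlations, the standard robustness display for this filter.

## Allele-frequency differentiation

`fisher_pairwise()` tests each SNP's 2×2 table of group allele copies
with a two-sided Fisher exact test. `landscape_permutation_test()`
permutes *individual* landscape labels — not population blocks: with
four populations, block permutation admits only three distinct
pairings — and uses the absolute difference in genotype-derived allele
frequency as its statistic, with the add-one estimator
p = (1 + #{perm ≥ obs}) / (1 + B). Both feed Benjamini–Hochberg FDR
(the FDR procedure is a package choice; none is prescribed upstream).

Two numerical facts matter here. First, the add-one estimator never
returns p below 1/(1+B), so B bounds the attainable significance.
Second, with ~15 individuals per population the frequency-difference
statistic is discrete, and the tie-inclusive `≥` counting makes null
p-values visibly *superuniform* (conservative): at the 5% level the
null rejection rate sits near 3%, and a Kolmogorov–Smirnov test
against the uniform rejects even though the test is valid. The test
suite therefore asserts validity (empirical CDF below nominal at every
level) rather than exact uniformity.

`diversity_ranking()` repeatedly draws 10 individuals per population
and counts SNPs segregating within the draw, with the allele-detection
read threshold configurable between 1 and 3; `genotype_dissimilarity()`
is the fraction of jointly-called SNPs with different calls.

## Bayesian clustering of populations by expression

Expression is TMM-normalized, log2-CPM transformed, and each gene
standardized to zero mean and unit variance (the unbiased n−1 SD — a
recorded knob, as the convention is not prescribed). For every set
partition of the populations (all 15 of them for four labels), the
score is the sum over clusters and genes of the Normal–Gamma log
marginal likelihood with prior precision p ~ Exp(1) = Gamma(1, 1) and
mean m | p ~ N(0, 1/p):

log ML = lnΓ(αn) − lnΓ(α0) + α0 ln β0 − αn ln βn + ½ ln(κ0/κn) − (n/2) ln 2π,

with κn = κ0+n, αn = α0+n/2, βn = β0 + ½Σ(xi−x̄)² + κ0 n (x̄−μ0)²/(2κn).
The closed form is verified in the tests against direct 2-D numerical
integration over (m, p) to 6 decimals. Ties in the ranking go to the
partition with fewer blocks (the coarser model). Scores are reported in
natural log; their absolute magnitude scales with the data and is not
meaningful across data sets. Note that adding an uninformative gene
shifts different partitions by slightly different amounts (the
zero-vector evidence depends on block sizes), so only clear-cut
rankings are invariant to such padding.

## Dual differential expression

The NB-GLM stage is a self-contained implementation, not a call-out:
per gene, a negative-binomial GLM with log link, one mean per
population and offsets log(library size × TMM factor) is fitted by
IRLS; the landscape contrast (mean of fragmented population means −
mean of continuous population means) is tested by a likelihood-ratio
test against χ²(1), with the null model fitted on an orthonormal basis
of the contrast's null space. Gene-wise dispersions maximize the
Cox–Reid adjusted profile likelihood on φ ∈ [10⁻⁴, 4] and are then
moderated toward a lowess trend on abundance by a log-scale weighted
average with weights residual-df : `prior_df` (default 10). This is a
deliberate simplification of weighted-APL empirical Bayes; under the
generator's null it delivers a type-I error of ≈ 0.06 at α = 0.05 over
2000 genes, inside the intended 0.03–0.07 band, and recovers a planted
log2 effect of 1 with median error below 0.2 at n = 15/population.

The permutation stage works on log2(TMM-CPM + 0.5) — the +0.5 prior
avoids log 0; the offset convention is a package choice. Its statistic
is the absolute fragmented-vs-continuous mean difference *gated by a
consistency condition*: both fragmented population means must lie
strictly above, or strictly below, both continuous ones; otherwise the
gene is declared non-significant outright (p = 1). Null replicates
permute individual labels freely (whether population structure should
be preserved under the null is unspecified upstream; free permutation
is the recorded assumption), and permuted replicates violating
consistency contribute statistic 0, which makes the test conservative.
A gene is landscape-DE only when the LRT *and* the permutation test
both give FDR < α — an intersection that is monotone in α.

## Within-population heterogeneity (VB-GMM)

Per gene, standardized values are fitted with univariate Bayesian
Gaussian mixtures for K = 1..5 by mean-field variational Bayes:
symmetric Dirichlet(1) on weights and Normal–Gamma(0, 1, 1, 1) on each
component — chosen to match the partition model's prior family, since
"uninformative" is not quantified upstream. Responsibilities are
initialized from k-means under a caller-supplied seed (one restart by
default), updates iterate until the ELBO changes by less than 10⁻⁶
(cap 500 iterations), and the ELBO — the variational surrogate for the
marginal likelihood — selects K, with empty components pruned before
comparison. Exactness anchor: at K = 1 the variational family contains
the true posterior, so the ELBO equals the Normal–Gamma evidence
exactly, which the tests assert.

Selection behaviour worth knowing: on unimodal standardized data at
n ≈ 50, K = 1 wins essentially always; on well-separated bimodal data
(component means ±2, component SD 0.5, n = 60 — ~8 within-component
SDs apart) K = 2 wins essentially always. At ~4 within-component SDs
and n = 60 the evidence is genuinely ambivalent — the per-point
likelihood gain (≈ 0.11 n nats) barely covers the complexity penalty
(≈ 1.5 ln n) — so selection hovers near 50–65% and no threshold-style
guarantee is possible there. The generator's mixture genes separate
components by `mixture_delta` biological SDs on the log scale;
low-expression genes add counting noise on top, so their detected
fraction is lower than for directly simulated Gaussians — the same
caveat that applies to real low-coverage genes.

## Kinship-aware cis-eQTL

Relatedness between individuals i and j is the mean over
jointly-called SNPs of 1 − |dosage_i − dosage_j|/2 — the central
modelling assumption of this module, as no formula is prescribed
upstream — with unit diagonal and a 10⁻⁶ ridge for positive
definiteness; pairs sharing no SNP are imputed with their
population-pair mean. Each SNP is paired with its nearest gene
(midpoint distance on the same scaffold, ties to the lower start
coordinate, 1-based positions). Fits are per population, using that
population's kinship block (GLS by Cholesky whitening; with the
identity it reduces to OLS exactly), under additive (0/1/2), dominance
(0/1/1) and recessive (0/0/1) codings, and only where all three
genotype classes occur in the population. FDR is computed within each
population across tested pairs (the FDR scope is a recorded
assumption). A record is accepted iff the SNP is
landscape-differentiated, FDR < 0.05 in at least one population, and
the slope sign agrees in every population with a defined fit. An
optional sex covariate is available (`sex_covariate = TRUE`, default
off).

## Enrichment and concordance

`binomial_category_test()` is the exact upper binomial tail
P(X ≥ k | n, rate). The canonical worked case — 4 of 7 category genes
significant at a genome-wide rate of 0.11 — gives 0.0039; note this
uses the rate *as printed to two decimals*, the unrounded 1841/16667
gives 0.00395. `fraction_test()` is the one-sided hypergeometric
(Fisher) over-representation test. Concordance analyses filter genes
with strict `logCPM > 1` in both data sets and strict
`|log2 ratio| > 1`, then correlate two per-gene landscape contrasts
(Pearson by default; Spearman by flag — the correlation statistic is a
flagged assumption), with `landscape_delta(..., exclude_population=)`
supporting leave-one-population-out recomputation so the two contrasts
use disjoint individuals. For flight-response versus baseline
comparisons the primary display is the 2×2 direction-agreement table
with its Fisher p; the correlation p-value is withheld unless
explicitly forced.

## The synthetic-data generator

`simulate_study()` emulates the study design the analyses assume: four
populations (two per landscape), 15 individuals each by default, an
ancestral allele frequency uniform on (0.05, 0.95), Balding–Nichols
Beta drift along a star tree with per-population F = 0.05 (an optional
internal branch per landscape is available), binomial(2) genotypes,
Poisson read depths (mean 20) with binomial allele sampling, and NB
expression counts with mean L·q·exp(effects) and gene-wise dispersion
uniform on (0.05, 0.4). Defaults plant 500 landscape-shifted SNPs
(total shift 0.2), 200 landscape-DE genes at 1 log2 unit with random
sign, 50 sex genes, 20 cis-eQTL pairs at β = 1 per alternate allele
(natural log), and 100 mixture genes with a latent Bernoulli(0.5)
component independent of population (heterogeneity was found largely
unassociated with population or sex, so the generator does not couple
them). Library sizes are log-uniform over (10⁶, 2×10⁷), emulating the
>10-fold spread of unnormalized libraries without modelling lanes.
Allele-frequency spectrum parameters are free knobs, not calibrated to
any particular study. One global seed is expanded into per-stage
substreams so stages can be regenerated independently, and identical
seeds give byte-identical studies.

What the generator does *not* emulate: read-level errors (genotype
scoring at high depth is exact by construction), mapping bias, isoform
structure, batch effects, or linkage disequilibrium beyond the drift
model. Passing tests therefore demonstrate correctness of the
statistical machinery under the assumed model, not robustness to
artefacts real data may carry.

## Problem sizes and numerical choices

The test-suite and reproduction-script runs use deliberately desk-scale
configurations: global-null calibration at 10⁴ SNPs and 2000 genes with
10³ permutations, effect recovery at 200–400 genes, selection-rate
estimates over 100 seeded replicates, and demo pipelines at a few
hundred SNPs/genes — sizes chosen so a full run completes in minutes on
one CPU while keeping Monte-Carlo error well inside the asserted
margins. Other numerical choices: IRLS with a log-likelihood
convergence criterion and linear-predictor clamping at ±30; dispersion
optimization on the log scale; permutation weights applied in batched
matrix products (200 permutations per multiply); `fisher.test`
p-values clamped to [0, 1] before FDR (they can exceed 1 by floating
error); zero-variance genes dropped before standardization; and
Cholesky-based GLS rather than explicit inversion.

## Known limitations

* The NB-GLM dispersion moderation is simpler than weighted-APL
  empirical Bayes; its calibration is verified by simulation rather
  than by theory, and very small sample sizes (< 5 per population) are
  untested territory.
* The permutation tests' add-one, tie-inclusive p-values are
  conservative on discrete statistics (see above).
* The eQTL module fits one SNP at a time; no variance-component
  (REML) mixed model, trans-effects, or LD-aware multiple testing.
* Partition enumeration is limited to 12 populations (Bell numbers
  explode); no MCMC over partitions.
* GO/KEGG-style enrichment works on user-supplied gene→category maps
  only; no ontology databases are bundled or queried.
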