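---
title: "Architecture-matched permutation tests for pathway-based GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architecture-matched permutation tests for pathway-based GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathperm)
```

## The problem

A candidate pathway — here, the motivating case is a set of estrogen-metabolism
genes studied in relation to primary open-angle glaucoma (POAG) — may carry
many weak genetic signals that no single SNP test survives multiple-testing
correction for. A pathway-level test asks instead whether the *aggregate* of
nominally significant association signals inside the pathway is larger than
expected for a random gene set of comparable structure.

The difficulty is linkage disequilibrium (LD): SNPs inside an LD block are
correlated, so a pathway rich in large blocks produces clusters of correlated
small p-values that a naive SNP-counting null would misread as signal. The
test implemented here therefore works on *features*, not SNPs, and matches its
permutation null on the pathway's LD architecture.

## The statistic

Per-SNP two-sided p-values come from an additive logistic model per study,

$$\operatorname{logit} P(y_i = 1) = \beta_0 + \beta g_i + \gamma^\top x_i,$$

with dosage $g_i \in \{0,1,2\}$ and covariates $x_i$ (age, site, and sex in
gender-combined analyses), combined across studies by fixed-effect
inverse-variance weighting: $w_s = 1/\mathrm{se}_s^2$,
$\hat\beta = \sum_s w_s \hat\beta_s / \sum_s w_s$,
$\mathrm{se} = (\sum_s w_s)^{-1/2}$. A sample-size-weighted z-combination is
available as an alternative (`sample_size_weighted_z()`); the inverse-variance
mode is the default because it yields combined odds ratios, not only p-values.

The pathway's SNPs (every genotyped SNP within a member gene's transcript span
± 50 kb, a closed interval, deduplicated across overlapping genes) are
decomposed against reference-panel LD blocks into

* **simple features** — SNPs in no block, significant iff their own p < α;
* **complex features** — block intersections with ≥ 2 pathway SNPs,
  significant iff *any* member p < α (α = 0.05 by default).

The observed statistic is the number of significant features. The null is
built by drawing, many times, a random feature set *matched on architecture*:
the same number of simple features and, for each complex-feature size in the
pathway's multiset of block sizes, one genome-wide block of the same size
(without replacement within a draw). The empirical p-value is the
strict-exceedance fraction

$$p = \#\{\text{null count} > \text{observed}\} / n_{\mathrm{perm}},$$

computed as the exact ratio (6 exceedances in 1,000 draws report p = 0.006).
Zero exceedances are displayed as "<0.001" at 1,000 permutations, and values
above 0.99 as ">0.99"; the stored values remain exact.

## Design choices where the design was open

Several components admit more than one reasonable construction. The choices
made here, and why:

* **Block detection** is greedy contiguous agglomeration: walking each
  chromosome in position order, a SNP joins the current block when its
  r² (genotype-dosage correlation squared, from the reference panel) with
  *any* member is at or above the threshold (default 0.8). This is
  deterministic, order-independent, and simple enough to verify against
  hand-traced cases and simulated ground truth; confidence-interval block
  definitions would add dependence on an external haplotype-phasing stack.
  Because block definitions depend on the reference panel and threshold, two
  analyses using different LD sources will legitimately report different
  simple/complex feature counts for the same gene set.
* **Empirical p estimator** is k/N, not (k+1)/(N+1). The raw ratio reproduces
  the printed arithmetic convention of feature-permutation software; the
  positively biased estimator is available via `estimator = "plus_one"`.
* **Pool composition**: null draws sample features genome-wide *including
  the tested pathway's own features* (a random gene set drawn from the
  genome can land on them). This choice is driven by calibration: when the
  tested pathway is a non-negligible fraction of the genome — unavoidable
  at desk scale, where a 23-gene pathway occupies ~10% of a ~5,000-SNP
  genome — a pool that excludes the pathway produces null counts centred on
  an independent finite-pool estimate with shrunken (hypergeometric)
  spread, and the test rejects a global null far too often (we measured
  ~17% at the nominal 5% threshold in 200 end-to-end replicates). Retaining
  the pathway's features makes the null draws co-vary with the observed
  count and restores near-nominal behavior; in the published operating
  regime (a pathway of hundreds of SNPs against hundreds of thousands) the
  two pool definitions are practically indistinguishable. For a strongly
  associated pathway, self-overlap slightly *raises* the null bar, i.e. the
  choice is conservative for power, never anti-conservative.
  `exclude_pathway_from_pool = TRUE` / `exclude_snps` restore strict
  exclusion.
* **Size matching** is exact-first on the block-size multiset. If a size
  class is exhausted, the nearest available size within ±1, then ±2, is used
  (both equidistant classes pooled, sampled uniformly) and the deviation is
  recorded on the result; `size_match = "strict"` turns exhaustion into an
  error.
* **Demotion rule**: when a block's intersection with the pathway leaves a
  single SNP, that SNP is counted as a simple feature — "SNPs not in any LD
  block" is interpreted relative to the mapped set.
* **Gene-level drill-down** (`investigate()`) reruns the matched-null test
  per gene with that gene's own architecture against the same pool, using a
  per-gene seed substream (`seed + 7919 * gene index`), so any subset of
  genes reproduces identically.
* **X-chromosome rule**: male-only and gender-combined analyses drop
  X-linked SNPs from the pathway, the pool, and the genotype set; female-only
  analyses retain them. Males are hemizygous on X and coded 0/2 (allele-count
  doubling), one consistent convention for a model that never actually fits
  X SNPs outside female strata.
* **Stratification**: cases split into high-pressure (IOP at diagnosis
  ≥ 22 mmHg) and normal-pressure (< 22 mmHg) subtypes; the boundary value 22
  belongs to the high-pressure side. Cases with no recorded IOP remain in the
  overall analysis and are excluded from both subtypes, which is why subtype
  case counts need not add up to the overall count. Controls are shared
  across outcome strata.
* **Multiple-testing accounting**: the per-SNP Bonferroni threshold is
  α/(n_SNPs × n_strata) with n_strata defaulting to 3 (overall and the two
  pressure subtypes); the multiplier is configurable because the appropriate
  stratification count is a judgement call.

## The synthetic-data generator

All validation runs on synthetic data, so what the generator does (and does
not) emulate determines what the tests can show.

**Haplotypes.** Each chromosome carries LD blocks interleaved with singleton
SNPs. Within a block, every haplotype draws a latent tag allele with
frequency $p_0$ and copies it to each member SNP with an error (flip)
probability $\varepsilon$. The pairwise correlation between members is then

$$r = \frac{p_0 (1 - p_0)(1 - 2\varepsilon)^2}{q(1-q)}, \qquad
  q = p_0 + \varepsilon (1 - 2 p_0),$$

so given a target marginal frequency $q$ (drawn per block from `maf_range`)
and a target $r^2$, `flip_rate_for_r2()` solves for $\varepsilon$ in closed
loop. This gives exact 0/1 allele support and an analytically checkable
LD level — the reason this scheme was chosen over thresholded multivariate
normals. Diploid genotypes are sums of two haplotypes.

**Cohorts** are fresh draws from the same population model, not resamples of
the panel. Disease status follows the logistic model above with configurable
SNP effects (optionally restricted to one gender) and covariate effects;
subjects are retained by rejection sampling conditional on status until the
configured case and control counts are hit exactly, mirroring fixed-margin
case-control designs. For efficiency, status is decided from the causal SNPs'
haplotypes and covariates alone, and the remaining genome is drawn only for
retained subjects, conditionally on the causal blocks' tags — an exact
factorization of the joint draw, not an approximation. Cases receive an
IOP-at-diagnosis value (normal, mean 24.5 mmHg, SD 4.5, floored at 8) with a
24% missingness rate, so roughly 70% of classified cases fall in the
high-pressure subtype, matching the case mix the stratified analyses assume.

**LD level vs detection threshold.** The generator's default within-block
r² is 0.9 while block detection thresholds at 0.8. The gap is deliberate: if
the population within-block correlation sits exactly at the detection
threshold, the realized pairwise r² in a finite panel straddles it and
membership becomes a coin flip — stray true-block members are then assigned
as "simple" features whose p-values co-move with their block's feature.
Because gene windows cluster such correlated features while matched null
sets scatter over independent regions, this detection-generation interaction
inflates the permutation test's null rejection rate severely (we measured
16% at a nominal 5% with r² = threshold = 0.8, against 5.5–7% in every
configuration without the interaction). With the 0.9/0.8 gap, blocks are
recovered essentially intact (Jaccard ≥ 0.9 against ground truth at ≥ 500
haplotypes) and calibration is restored. The same reasoning applies to real
panels: the detection threshold should sit clearly below the LD level one
intends to treat as "one block".

**Annotations.** Genes tile contiguous runs of genotyped SNPs, so every gene
window contains at least one SNP; the designated pathway takes 23 genes
spread over 15 chromosomes with two X-linked members, the shape the analysis
scripts exercise.

**Not emulated**: recombination-rate variation and block-boundary decay,
population structure and admixture, genotyping error and missingness,
imputation uncertainty, and strand ambiguity (cohorts share one allele
frame). Passing tests therefore certify the statistical machinery — not
robustness to stratification artefacts or imperfect LD reference panels.

## Validation studies and their problem sizes

The package's own studies, run by the test suite and mirrored in
`analysis/`, use sizes chosen to keep a full multi-replicate study on one
CPU while leaving every structural property intact:

* a genome of ~5,000 SNPs (15 chromosomes × 43 blocks of 2–8 SNPs plus 35%
  singletons), reference panels of 600–1,000 haplotypes; the tested 23-gene
  pathway covers a few hundred SNPs, i.e. a few percent of the genome —
  large enough for a finely resolved feature count, small enough that the
  null pool dwarfs the tested set, as it does at full scale;
* **calibration**: 200 end-to-end replicates of a global-null study (two
  cohorts of 750 cases/750 controls each, meta-analyzed, 1,000 permutations)
  — the pathway test's rejection rate at the permuted-p 0.05 threshold must
  sit within the binomial 95% band around 0.05;
* **dimorphism recovery**: 50 replicates with ten pathway SNPs carrying
  |log OR| = log 1.3 in women only — the female-stratum permuted p must fall
  below 0.05 in at least 80% of replicates while the male stratum exceeds
  0.05 in at least 90%;
* the worked analysis in `analysis/` uses cohorts of 976/1,140 and
  2,132/2,290 cases/controls, the sizes of the two collections the package's
  stratified report emulates.

The score-test scan (`assoc_scan(method = "score")`) makes these studies
feasible: it fits the covariate-only null model once and computes all per-SNP
efficient scores in matrix algebra, reporting one-step effect estimates
`U/V` with `se = V^{-1/2}`. It is exact under the null and first-order
equivalent to the per-SNP Wald fit (`method = "wald"`, the default for
single-SNP use) at moderate effects; the suite checks their agreement.
Likewise, when every block-size class is plentiful, the permutation null is
drawn as a sum of per-class hypergeometric counts — distributionally
identical to the explicit feature sampler (also verified in the suite) and
much faster; the explicit sampler runs whenever fallback could occur.

## Degenerate inputs and numerical conventions

Monomorphic SNPs and separation-failing fits are flagged, excluded from
feature construction, and counted in messages; a SNP flagged in any study
that measures it is dropped from the meta-analyzed set, while a SNP absent
from a study passes through as the remaining studies' result. Monomorphic
SNPs get r² = 0 in the LD map. Features whose members all lack p-values are
dropped (with a count); partially missing features use their available
members. Coordinates are 1-based inclusive throughout; BED export converts
to 0-based half-open. Wald p-values are floored at the smallest positive
double rather than reported as 0. All empirical p-values are exact ratios;
ties in feature counts cannot be mishandled because the exceedance is
strict.

## Known limitations

* Adjacent blocks and singletons within a gene are correlated at
  sub-threshold r², while matched null features are drawn from unrelated
  regions; with many tests (23 genes × 3 outcomes × genders) occasional
  very small gene-level p-values arise by chance more often than a nominal
  reading suggests. The pathway-level test, whose calibration is verified
  directly, is the primary inference; gene drill-downs are descriptive.
* Feature counts depend on the LD reference and r² threshold; they are
  comparable within one analysis, not across LD sources.
* The fixed-effect combination assumes a shared effect across cohorts; no
  heterogeneity statistic is computed.
* The generator's allele-frequency spectrum is uniform over `maf_range` —
  conventional, not calibrated to any array's spectrum.
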