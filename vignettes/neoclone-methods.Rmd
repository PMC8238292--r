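---
title: "Methods: subclonal loss and response to neoadjuvant ADT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subclonal loss and response to neoadjuvant ADT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoclone)
```

`neoclone` tests whether tumors that respond to intense neoadjuvant
androgen deprivation are those carrying, before treatment, a subclonal
population of cells made vulnerable by a somatic copy-number loss. This
vignette records the models, the defaults, and the design choices made
where the design was genuinely open.

## The CCF model

For a somatic SNV in a tumor of purity $\rho$ with local tumor total copy
number $C_t$ and mutation multiplicity $m$ (mutated copies per mutated
cell), the expected variant allele frequency when a fraction $\phi$ of
tumor cells carry the mutation is

$$E[\mathrm{VAF}] \;=\; \frac{\rho\, m\, \phi}{\rho C_t + 2(1-\rho)}.$$

`estimate_ccfs()` inverts this map. $m$ is not identifiable from a single
VAF, so it is estimated by the standard convention: round the inverted
map evaluated at $\phi = 1$ and clip to $[1, \text{major CN}]$. A Wilson
score interval on the VAF is pushed through the same linear map; the
Wilson interval was preferred over Wald for its behaviour at extreme
VAFs. Estimates are clipped to $[0, 1.5]$ and values above 1 flagged
rather than silently truncated at 1, since CCFs slightly above 1 are a
useful diagnostic for purity or copy-number misspecification. A variant
with zero depth has no defined VAF and propagates `NA`; a locus with
$C_t = 0$ at full purity is an error, since no DNA is present to carry
the variant.

## Clonal clustering

Dirichlet-process clustering of CCFs is standard in subclonal
reconstruction but is stochastic and heavier than needed for a
qualitative pre/post comparison of clonal makeup. `cluster_ccfs()`
instead fits finite binomial mixtures: component $k$ has a cluster CCF
$\phi_k$, and variant $i$ contributes a likelihood
$\mathrm{Bin}(\mathrm{alt}_i \mid \mathrm{depth}_i, a_i \phi_k)$ with
$a_i = \rho m_i / (\rho C_{t,i} + 2(1-\rho))$ — the same forward map as
the estimator, so read depth weights variants automatically. The EM
M-step maximizes each component's weighted log-likelihood exactly (the
function is concave in $\phi_k$; Newton steps with an `optimize()`
fallback), and the log-likelihood is asserted non-decreasing every
iteration. $K$ is selected by BIC over $1..k_{\max}$ (default 6, ample
for bulk samples at this depth). Initialization is k-means++-style
seeding on the point CCF estimates under a caller-supplied seed, making
results reproducible; with at least five variants per component planted
clones at CCF 1.0 and 0.4 are recovered within 0.05 at depth 200 (the
test suite checks this across 100 seeds).

Longitudinal matching (`match_longitudinal()`) is greedy nearest-CCF
one-to-one linking, ties broken in favor of larger clusters. With at
most ~6 clusters per sample an optimal assignment would change nothing
in practice; greediness is transparent and order-free after the distance
sort. A matched pair is *stable* when $|\Delta\phi| \le \delta$ with
$\delta = 0.1$ by default — the CCF resolution one can expect at
depth ~100 — and clones present on only one side are *extinct* or
*emerging*. The orthogonal, SNV-free view (`compare_segment_pairs()`)
matches copy-number segments across timepoints by reciprocal overlap
(default 0.5) and reports the fraction of matched loss segments whose
copy-number fraction moved by more than 0.25; both thresholds are
configurable, since no numeric criterion exists for "clonal shift" in
segment space.

## Segment subclonality and the rescue rule

A segment is a loss when its total copy number is below the rounded
sample ploidy or it shows LOH (minor copy number zero) — so a
copy-neutral LOH event counts as a loss, the more inclusive reading.
Copy-number fractions classify segments as clonal ($\ge 0.9$), subclonal
($0.1$–$0.9$) or absent ($\le 0.1$); a loss at $\le 0.1$ is *rescued* to
subclonal when an overlapping loss at $> 0.1$ exists in another sample
of the same patient, which protects real low-burden subclones from the
detection floor without admitting noise seen only once. Samples with
unclear purity/ploidy solutions are excluded outright: their fractions
are not interpretable. Segments above 4 total copies are flagged so
downstream analyses consider losses only.

## FFPE deamination control

Formalin fixation deaminates cytosine, which surfaces as low-VAF C>T
calls (G>A on the reverse strand). `ffpe_transition_test()` computes,
per matched FF/FFPE pair and per VAF bin (defaults $[0.01, 0.10)$ and
$[0.10, 0.25)$, closed-left), the fraction of SNVs that are C>T/G>A, and
runs a one-sided paired t-test (FFPE > FF). Pairs with no SNVs in a bin
are dropped from that bin with a warning; all-zero differences give
$p = 1$ by convention, and an exactly constant nonzero shift resolves by
its sign rather than erroring. Pooling is per patient; the alternative
(per sample) changes nothing when each patient has one aliquot pair.
Under artifact-free simulations the test's type I error at nominal 0.05
stays within $[0.02, 0.08]$ over 200 replicate cohorts, and power
exceeds 0.8 at an artifact load that triples the low-VAF deamination
fraction across 8 pairs (both are asserted in the test suite).

## Expression and prioritization

`log_cpm()` applies median-of-ratios size factors and then
$\log_2((\text{count} + 0.5)/(L + 1)\cdot 10^6)$ with $L$ the **mean
corrected library size**, common to all samples. Using each sample's own
corrected total instead would undo the normalization: a block of
genuinely up-regulated genes inflates one group's totals and drags every
other gene's apparent expression down there (we measured a $-0.2$ logFC
bias on null genes and a false-discovery proportion of 0.12 under that
variant; with the common denominator the realized FDP is ~0.04 at BH
0.05). The prior count of 0.5 stabilizes zeros; it is not scale-free, so
log-CPM is invariant to rescaling a sample only up to ~0.005 at typical
counts even though the size factors absorb the rescaling exactly.

`de_test()` is a per-gene Welch t-test on log-CPM — simple,
dependency-free, and calibration-testable; moderated or count-model
alternatives are deliberately out of scope. Genes are pre-filtered
(CPM > 1 in at least half of the smaller group) and excluded from both
testing and the BH denominator. Candidate filtering uses strict
thresholds logFC > 1, FDR < 0.05, logCPM > 3.

Prioritization intersects, across the selected best responders, the
per-patient sets of genes overlapped (any overlap, ≥ 1 bp — no overlap
fraction is defensible without a gene-length model) by a pre-treatment
subclonal or rescued loss and by no post-treatment loss at fraction
> 0.1 — the same 0.1 floor serving as the operational definition of
"not detectable". Requiring the subclonal class in *every* selected
patient (rather than at least one) is the strict reading and is the
implemented default; the selection of patients is a caller-visible
argument. Survivors are ranked by descending logFC, ties by ascending
FDR; a candidate missing from the expression universe is kept, ranked
last, and flagged, since absence of evidence at the RNA level should not
silently delete a genomically qualified gene.

## FISH prevalence and response correlation

Cells without a centromere (control) signal fail hybridization QC;
among passing cells, zero target signals is a deep deletion — the
centromere requirement guards against sectioning artifacts in which no
hybridization occurred at all. Prevalences carry Wilson intervals, and
samples under the minimum cell count (default 50) are flagged rather
than dropped. The response correlation is Spearman's rank correlation of
pre-treatment deep-deletion prevalence against residual tumor volume: a
scatter with a monotone but not necessarily linear relationship is
exactly the setting rank correlation is for. The p-value is an exact
permutation p for small n — full enumeration for $n \le 8$, the exact
null distribution of the rank statistic for $n \le 10$ without ties —
and asymptotic otherwise; at the cohort sizes in question asymptotic
p-values would not be trustworthy.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with planted ground truth: per patient a pre-treatment biopsy
(FF + FFPE aliquots) and a post-treatment sample; 2–3 clones per tumor
(one clonal), purities uniform on $[0.3, 0.9]$; SNV reads are binomial
draws at Poisson depth (mean 80) under the CCF forward model with
$C_t = 2$, $m = 1$; FFPE aliquots gain new C>T/G>A calls at uniform VAF
in $[0.01, 0.10]$ at a configurable rate per true SNV (default 0.2) —
injecting new calls rather than perturbing true ones, since deamination
creates artifacts at positions that were never somatic. Copy-number
segments are a neutral 1+1 background broken by subclonal single-copy
losses over random genes (Poisson rate 3 per sample); the planted
sensitivity gene receives a subclonal loss (fraction 0.3–0.6) in the
pre-treatment samples of the best responders only, and the background
loss sampler excludes the planted locus so noise cannot contradict the
declared truth. Expression is negative-binomial (dispersion 0.1) with
log-normal gene means and the planted gene up-regulated post-treatment
by the configured logFC (default 2). Residual volume follows
$v = v_{\max}(1 - \text{prevalence})^k \cdot \mathrm{lognormal}$ with
$v_{\max} = 10$ cc, $k = 6$ and noise sd 0.4 — a monotone decreasing
relationship is all the data support, so the exponent and noise are
explicit knobs; deep-deletion prevalence ranges over $[0.02, 0.30]$,
matching the observation that biallelic loss tops out near 30% of cells
even in extreme responders. FISH cell tables draw per-cell states from
the same prevalence, depleted post-treatment in proportion to response.
Identical seeds give byte-identical output files.

What the generator does **not** emulate: genomic context (trinucleotide
signatures, realistic coordinates), multi-region sampling of the
pre-treatment tumor (one biopsy per timepoint), structural variants,
correlated gene expression, or purity/ploidy estimation error. Passing
tests therefore demonstrate that the chain recovers planted truth under
its own model assumptions — not that those assumptions hold in real
tumors.

## Trial design search

`simon_search()` enumerates every two-stage design $(r_1, n_1, r, n)$
with $n \le n_{\max}$ (default 60) and evaluates exact binomial
operating characteristics; no branch-and-bound, exactness over speed at
this scale. "Reject the null" means strictly more than $r$ total
responses. Ties, which the classical treatment leaves implicit, are
broken explicitly: the optimal design minimizes expected sample size
under $p_0$ with smaller $n$ as tie-break; the minimax design minimizes
$n$ with smaller expected size as tie-break. The search treats the
historical response rate as exactly 0.05 where the protocol language
says "approximately 5%", because that value reproduces the design the
trial actually used and is the natural reading of the calculation.

## Problem sizes and numerical conventions

The test suite validates calibration at desk scale: 100 seeds for clone
recovery, 200 artifact-free cohorts (8 patients, 60 SNVs each) for the
FFPE type I error, 50 expression simulations of 1,000 genes for DE
calibration, 50 end-to-end cohorts at the default 12 patients / 2,000
genes for planted-gene recovery, and 100 cohorts (reduced to 200 genes
and 20 SNVs, which do not enter the correlation) for the
prevalence–volume association. These sizes were chosen so the full suite
runs in a few minutes while keeping Monte Carlo error well below the
asserted margins. Numerical conventions: binomial mixture success
probabilities are clamped to $[10^{-9}, 1 - 10^{-9}]$; EM stops at a
log-likelihood gain below $10^{-8}$ or 200 iterations; VAF bins are
closed-left/open-right; BH adjustment is `p.adjust`'s implementation,
verified against the textbook cumulative-minimum construction.

## Known limitations

- The DE engine is a two-group Welch t-test; designs with covariates or
  paired structure are out of scope.
- Multiplicity estimation assumes the rounded-map convention; subclonal
  copy number under the variant (mutation on the lost allele) is not
  modelled.
- Clonal clustering is per sample; joint multi-sample clustering would
  share information across timepoints but is deliberately not attempted.
- The FISH model ignores probe efficiency differences and nuclear
  truncation; prevalences are of scored signals, not of cells in tissue.
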