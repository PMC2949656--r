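---
title: "Profiling familial breast tumours with apocrine differentiation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling familial breast tumours with apocrine differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apocrine)
```

# Scope

`apocrine` re-implements, as a tested and reusable library, the statistical
workflow used in cohort studies of familial breast cancer where a small
molecular-apocrine subgroup (androgen-receptor-driven, often arising on a
germline *PTEN*-mutant background, as in Cowden disease) must be detected
and characterised against the intrinsic-subtype backdrop. The stages are:

1. **Probe-set filtering** of a log2 expression matrix (intensity floor,
   chi-square variance test, robust coefficient of variation).
2. **Unsupervised clustering** of samples and genes (Ward linkage on
   1 − Pearson correlation) with branch extraction and cluster-vs-label
   association tests.
3. **Nearest-centroid intrinsic-subtype assignment** (luminal A, luminal B,
   basal-like, normal-like, HER2) against published centroid tables.
4. **Supervised signature derivation** for a two-group contrast: per-probe
   Welch *t*, local false-discovery-rate screening, random-forest
   permutation-importance selection of a fixed-size probe signature.
5. **Hypergeometric gene-set and signature-overlap testing**.
6. **Two-component PCA** with Gaussian-mixture (model-based) confirmation of
   visually identified groups, including cross-projection of one cohort's
   samples onto another cohort's signature genes.
7. **Array-CGH calling** on replicate-spotted BAC clones, with a per-arm
   genomic perturbation rate.
8. **Immunohistochemistry scoring** (0/1/2 bands, marker-specific
   positivity) and chi-square/Fisher contingency analysis.

Upstream normalisation (RMA for expression; spatial normalisation and
breakpoint segmentation for aCGH) is out of scope: the package consumes
normalised matrices and clone-level intensities.

# Statistical models and conventions

## Probe filtering

A probe is retained by the intensity filter when it is not a control probe
and its 90th-percentile log2 intensity is at least 10 (both configurable).
All percentiles in the package — here and for the rCV window below — use
linear interpolation between order statistics (R's default quantile type 7);
the convention is recorded in the filter report.

For clustering, probes are then screened for variability. With
$\mathrm{Var}(P)$ the unbiased (n−1 denominator) sample variance of probe
$P$ across the $n$ samples and $\mathrm{Var}_{med}$ the median of those
variances over all probes in the filtered input, the statistic

$$ S(P) = (n-1)\,\mathrm{Var}(P) / \mathrm{Var}_{med} $$

is referred to $\chi^2_{n-1}$. Because the downstream selection targets
*high*-variability probes (the companion criterion demands an rCV above its
95th percentile), the default p-value is the upper tail; a `two_sided` flag
exposes the literal "different from the median" reading. Using the median of
variances rather than the (unknown) true variance slightly inflates the
statistic under a pure null — with $n = 74$ the fraction of null probes
below $p < 0.01$ sits near 1.2% rather than 1.0% — which is inherent to the
procedure, not a defect of the implementation; the calibration check allows
for this through its binomial tolerance.

The robust coefficient of variation orders the values, removes exactly one
minimum and one maximum occurrence (also under ties), and divides the sample
standard deviation of the remainder by its mean; a zero trimmed mean flags
the probe as undefined and excludes it. Selection keeps probes with
variance-test $p < 0.01$ and rCV strictly between the collection's 95th
percentile and an upper cap of 10. The cap is interpreted on the plain ratio
scale (not percent); it is configurable because published descriptions of
this style of filter are ambiguous on the scale.

## Clustering

Dissimilarity is $1 - r$ with $r$ the Pearson correlation, giving a range of
$[0, 2]$; zero-variance items are an error rather than silently producing
`NA`. Ward linkage applies the Lance–Williams recurrence directly to the
dissimilarity *as given* — the historical default of the era's clustering
tools (`hclust` method `ward.D`) and the variant most faithful to classic
microarray workflows; the squared-dissimilarity dialect (`ward.D2`) is one
flag away. Cutting a tree at $k$ removes the $k-1$ highest merges and
renumbers clusters by the index of their first member so that runs are
bit-reproducible.

## Centroid subtype assignment

Probes are matched to centroid genes in the namespace the centroid file
declares (symbol, UniGene or Entrez); genes measured by several probes are
collapsed by the mean of the probe rows (the simplest convention; a
max-variance-probe rule would make assignments depend on cohort
composition). By default each matched gene is median-centred across the
cohort before correlating — the usual correction when single-channel
intensities are compared with centroids derived from two-colour ratios — and
the option can be switched off to expose sensitivity. Every sample is
assigned to the centroid with the largest Pearson correlation; exact ties
are flagged and resolved to the alphabetically first subtype. No minimum
correlation is demanded by default (an optional `min_r` labels weak samples
`unclassified`).

## Signature derivation

For a two-group contrast the per-probe Welch statistic is
$t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}$ with
Welch–Satterthwaite degrees of freedom and a two-sided Student p-value.
Groups smaller than four samples trigger a warning (the degrees of freedom
can drop below 2) but are permitted, because contrasts as small as 3 vs 2
are scientifically meaningful in rare-syndrome cohorts.

The local FDR is estimated on the probit scale: $z = \Phi^{-1}(p)$, mixture
$f(z) = \pi_0\varphi(z) + (1-\pi_0) f_1(z)$ with a theoretical N(0,1) null.
$\pi_0$ is estimated once from the fraction of p-values above ½
($\hat\pi_0 = \min(1, 2\,\overline{[p > 0.5]})$) and $f_1$ is a
Gaussian-kernel density re-estimated iteratively from the posterior non-null
weights; $\mathrm{lfdr}(z) = \pi_0\varphi(z)/f(z)$, clipped to $[0,1]$. This
matches the semantics of the kernel-based local-FDR estimators used in the
field without reproducing any specific package's internals. The screen that
defines the signature candidates is the Welch p-value threshold (default
0.01); the local FDR achieved at the screen boundary is *reported* alongside
(in well-powered designs it lands near the conventional 20% working level)
but is deliberately not used as the screen itself.

The screened probes are then ranked by a random forest (default 1,000
trees, $\sqrt{p}$ features per split) using **unscaled permutation
importance on out-of-bag samples**, which is more stable than impurity
importance when probes vastly outnumber samples; the top 200 (configurable)
form the signature. The forest is made invariant to which group is named
first by canonicalising labels to the sample partition before fitting, so
swapping group names changes only the reported directions. An optional
permutation p-value filter on the importances (against label-permutation
nulls) is available but off by default: the primary rule is top-$k$ by
importance, and the two readings of "importance with a p-value threshold"
are one flag apart.

## Gene-set and overlap testing

Over-representation uses the one-sided hypergeometric tail
$P(X \ge k)$ computed by log-sum-exp over log-binomial coefficients, exact
to 1e-10 relative error against direct summation wherever direct summation
is representable, and stable far beyond it (overlaps with p-values around
1e-50 arise routinely when two apocrine signatures are intersected). Set
members and the signature are intersected with the universe first. The
default universe is the annotated genes surviving the intensity filter,
overridable, because enrichment p-values are only meaningful relative to a
declared universe. Raw p-values are reported (as is conventional for these
tables), with a clearly-labelled Benjamini–Hochberg column added.

## PCA and model-based confirmation

PCA is covariance-based on the log2 data (no per-gene standardisation, so
strongly varying signature genes keep their weight), computed by SVD after
column centring; component signs are fixed by making each component's
largest-magnitude loading positive, which makes scores fully deterministic.
Group confirmation fits Gaussian mixtures by EM for each candidate component
count (default 1–5, chosen by BIC); the component count was left free
because the number of visually apparent groups varies by cohort.

## Array-CGH calling

Per clone and tumour, replicate spots are dropped when flagged invalid,
when the signal-to-noise ratio is below 3, or when an intensity is
non-positive; the clone is missing when no spot survives or when the log2
ratios of the surviving spots have a standard deviation above 0.1.
Otherwise the clone's value is the median linear Cy3/Cy5 ratio. Clones
missing in strictly more than half the tumours are excluded cohort-wide.

Status thresholds — gain above 1.2, loss below 0.8, amplicon above 2 — are
applied on the **linear ratio scale**, with strict inequalities. Although
such cut-offs are sometimes quoted against "log ratios", on a log2 scale
0.8 would sit above zero and could never describe a loss; the values are
standard linear-ratio cut-offs (equivalently log2 cut-offs of
$\log_2 1.2$, $\log_2 0.8$, $\log_2 2$), and a `literal_log` flag implements
the verbatim log-scale reading for comparison.

The genomic perturbation rate is the unweighted mean, over chromosome arms
with at least one informative (non-missing) clone, of the fraction of
informative clones called lost, gained or amplified. Amplicons count as
altered (they exceed the gain bound). A clone sitting exactly at the
centromere position is assigned to the q arm.

## Immunohistochemistry

Scores follow the three-band rule: 0 when no tumour cell stains, 1 for
1–10% positive cells, 2 for 11–100%, regardless of intensity. Positivity is
marker-specific: hormone receptors (ER, PR, AR) require score 2; the
apocrine and pathway markers (GGT1, GCDFP15, EGFR, PTEN) are positive from
score 1 (any staining above 1% of cells); ERBB2 follows the Herceptest
reading with only `+++` positive by default. `nd` readings drop out of the
denominators.

Association tests use the Pearson chi-square without continuity correction;
2×2 tables whose smallest expected count is **at most** 5 switch to the
two-sided Fisher exact test under the minimum-likelihood convention (sum of
all tables with probability no larger than the observed one). The boundary
is inclusive so that sparse-but-balanced tables such as a perfectly
separating 10/0 vs 0/10 split are handled exactly; r×c tables always use
the chi-square, with a warning when sparse.

# The synthetic cohort generator

Every stage is testable without any external download through generators
that carry their planted truth.

**Expression** (`generate_expression`): the default scenario emulates a
74-sample familial cohort measured on ~20,000 regular probes plus 100
AFFX-style control probes. Five intrinsic subtypes (default mixture 20%
basal, 15% HER2, 35% luminal A, 20% luminal B, 10% normal-like among
non-apocrine samples) each over-express a disjoint 100-probe block; five
molecular-apocrine samples — three flagged as Cowden-disease carriers —
over-express a further 84-probe block. Values are
`baseline + offsets + N(0, 0.5)` on the log2 scale with baselines uniform
on [9, 13] (structured probes on [10.5, 12.5] so they survive the intensity
filter). The block effect defaults to 2 log2 units, a strong but realistic
fold change of 4 for a defining expression block. A matching subtype
centroid set (the class mean expression over the class-block genes) and a
complete probe/sample annotation are emitted alongside the truth. What the
generator does **not** emulate: probe-level (PM/MM) structure,
batch/array effects, correlated co-expression beyond the planted blocks,
and intermediate or mixed phenotypes — so passing recovery tests shows the
pipeline's statistical machinery works at the cohort's signal-to-noise, not
that real tumours are this clean.

**aCGH** (`generate_acgh`): ~5,878 clones laid out evenly along 22
autosomes (megabase-resolution lengths and centromere positions via
`default_centromeres()`), four replicate spots per clone, spot ratios equal
to the planted clone ratio (0.5 loss / 1 normal / 1.5 gain / 3 amplicon by
segment) under multiplicative log-normal noise (default sd 0.05 on the log2
scale), 2% of spots given low signal-to-noise. The built-in scenario plants
mostly flat genomes with a few arm-level events plus one amplicon-bearing
tumour, echoing the low-perturbation profiles of germline-*PTEN* apocrine
tumours. Genomic waviness and GC artefacts are not modelled.

**IHC** (`generate_ihc`): per marker and group a positivity probability
(cohort-like defaults for Cowden / apocrine / control groups) generates
score-band-consistent percentages, scores and Herceptest readings.

# Problem sizes used by the checks

The automated checks run at the cohort's own scale where that is what the
claim is about, and scaled down where only correctness of a formula is at
stake: null calibrations use 10,000 probes at n = 74; branch-recovery runs
20 full-size (74 × 20,100) generator seeds; centroid accuracy uses 500
samples over 3,000 probes (assignment only touches the 500 centroid genes,
so the probe count is immaterial); Ward-vs-brute-force equivalence uses 100
random instances at n ≤ 8 where the O(n³) oracle is exact; aCGH recovery
uses twenty 500-clone genomes, with the full 5,878-clone layout exercised
separately. The deposited 74-tumour arrays of the motivating cohort
(ArrayExpress E-TABM-854) are never required; the one check that asserts
that cohort's published probe counts runs only when a local copy of the
accession is staged under `extdata/E-TABM-854/`.

# Known limitations

* The variance-test null fraction is slightly above nominal (see above);
  the filter is a screen, not an inference, so this is acceptable.
* The local-FDR estimator assumes a well-behaved unimodal alternative on
  the probit scale; pathological p-value distributions (e.g. point masses)
  are flagged degenerate and given lfdr 1.
* Random-forest selections are seed-reproducible but not sample-order
  invariant beyond what `randomForest` guarantees.
* aCGH calling is clone-wise: no segmentation is performed, so isolated
  noisy clones become isolated miscalls rather than being absorbed into
  segments. Normal-cell contamination, which biases ratios toward 1 and can
  mask losses, is not corrected.
* The Fisher/chi-square switch follows the inclusive expected-count rule
  described above; other conventions (mid-p, unconditional tests) are not
  offered.
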