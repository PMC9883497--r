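---
title: "Isoform-ratio co-expression signatures: models, parameters, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-ratio co-expression signatures: models, parameters, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfyar)
```

`nfyar` analyses the per-sample ratio of two splice isoforms of one gene —
in the motivating application, NF-YA long over NF-YA short
(NF-YAr = NF-YAl/NF-YAs) — as a continuous tumour marker. This vignette is
the package's own account of the methods: the models and their assumptions,
the tunable parameters with their defaults, what the synthetic data
generator does and does not emulate, and the numerical and design choices
made where the underlying analysis left the question open.

## 1. Feature construction

Expression is consumed as `log2(TPM + 1)` throughout; planted correlations
and Z scores are exact on that scale. `build_feature_matrix()` removes the
gene-level row of the isoform-bearing gene and appends three engineered
rows: `NFYA_long`, `NFYA_short`, and `NFYAr`.

Two decisions here have no canonical answer and are therefore explicit
parameters:

* **Denominator floor** (`denom_floor`, default 0.01 TPM). A ratio with a
  near-zero denominator is numerically meaningless; samples whose
  short-isoform abundance falls below the floor get a *missing* ratio and
  are excluded downstream, with the count reported. Missingness is
  auditable; silent pseudocounts are not.
* **Ratio transform** (`ratio_transform`, default `"log1p"`). The ratio row
  enters network construction like a gene, so by default it receives the
  same `log2(x + 1)` map as every gene, making Pearson correlations
  comparable across rows. Whether the original analyses transformed the
  ratio pseudo-gene is not documented; `"identity"` keeps it raw.

Capping of the ratio at 1 (`cap_ratio()`) applies **only** in the survival
stage, where heavy right-tail ratio values would otherwise dominate the
cutoff scan; network construction and scoring always see the uncapped
value.

## 2. Signed co-expression networks and module detection

The network model is the standard signed weighted one: Pearson correlation
`c_ij` across samples, adjacency `a_ij = ((1 + c_ij)/2)^β`, and topological
overlap

```
TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),  l_ij = Σ_u a_iu a_uj,
```

clustered by average linkage on `1 − TOM`. The soft-thresholding power β is
data-set specific; `pick_soft_threshold()` reproduces the usual scale-free
criterion (signed R² of `log10 p(k)` against `log10 k` over ten
connectivity bins, suggestion = smallest power reaching `r2_target`,
default 0.85). The cohorts motivating this package used β = 4 (breast) and
β = 7 (gastric); those are the defaults in `pipeline_config()`.

Module-detection defaults follow the conventional settings for TCGA-scale
cohorts: `min_module_size = 30`, eigengene `merge_cut_height = 0.25`,
`reassign_threshold = 0` (interpreted strictly as *no* post-hoc
reassignment of genes between modules), and single-block analysis up to
`max_block_size = 30000` genes, with a k-means split on correlation
profiles above that.

### The simplified tree cut

The reference implementation of module detection uses dynamic hybrid tree
cutting, an algorithm with many undocumented parameters. This package
deliberately substitutes a simpler, fully specified cut whose acceptance
surface is planted-truth recovery, not label-for-label parity:

1. **Static cut** at the `static_cut_quantile` (default 0.995) of the merge
   heights, yielding maximal subtrees.
2. **Recursive descent**: any subtree whose root height exceeds
   `cohesion_frac × max(height)` (default 0.9) is split at its root and its
   children re-examined. Loose background clusters — whose merges sit just
   below the tree top — dissolve into unassigned leaves; tight modules stop
   the recursion intact.
3. **Rider trimming** (`trim_frac`, default 0.3): within an accepted
   cluster, a member is kept only if it attaches below
   `median attach height + trim_frac × (max height − median attach
   height)`. This removes background genes that hitch-hike onto a module
   because topological overlap inflates their similarity to a large,
   well-connected module.
4. **No-background guard**: topological-overlap dissimilarity of
   uncorrelated genes sits near 1, so a dendrogram whose top merge stays
   below 0.8 contains no background at all; such a tree is cohesive as a
   whole and exempt from trimming. Without this guard, a block consisting
   purely of one module (as block-wise analysis can produce) would be
   shattered by thresholds that are relative to its own, compressed height
   scale.
5. Clusters below `min_module_size` are unassigned (label 0); surviving
   modules are merged while any two eigengenes are closer than
   `merge_cut_height`, then renumbered by decreasing size.

The module eigengene is the first right singular vector of the
gene-standardized module submatrix, unit norm, sign-oriented so its
correlation with the module's mean profile is nonnegative. Average-linkage
ties are resolved by `stats::hclust`'s deterministic merge order, so the
partition is reproducible and permutation-equivariant up to renumbering.

**Known limitation.** When one module dominates the matrix (say, thousands
of genes out of a few thousand), topological overlap raises the similarity
of *every* gene to that module, and a fraction of the background can
survive both the cohesion test and the trim. The tests show this does not
affect recovery of the planted member set (recall stays at 1) or the
cross-cohort signature, but detected module sizes can exceed planted sizes
in strongly unbalanced designs.

## 3. Cross-cohort signatures and median-Z scoring

The ratio-bearing module of each cohort is the module containing the
`NFYAr` feature (`find_ratio_module()`; a warning is raised if `NFYA_long`
does not share it, since the ratio is expected to be driven by the long
isoform). The cross-cohort signature is the plain set intersection of those
modules' gene sets after removing the engineered feature names — the
printed overlap of the motivating analysis includes the isoform features,
but a gene signature used for scoring cannot contain them, so they are
always stripped here.

Scores are median Z: genes are standardized over the cohort's samples using
the **sample** standard deviation (n − 1, the convention of the
surrounding ecosystem), zero-variance genes are dropped with a report, and
each sample receives the median of its Z scores over present signature
genes (even counts: mean of the middle two). Scores are by construction
invariant to signature genes absent from the matrix.

## 4. Survival dichotomization

`km_estimate()` and `logrank_test()` implement the product-limit estimator
and the standard one-degree-of-freedom log-rank chi-square; both are tested
to numerical identity against hand-worked tables and the `survival`
package. Event convention: 1 = progression, 0 = censored.

`scan_cutoffs()` emulates optimal-cutpoint web tools: candidates are
midpoints between consecutive distinct sorted marker values whose split
leaves both groups at least `min_group_frac × n` samples
(default 0.1 — permissive, because the motivating breast-cohort split was
markedly unbalanced). Each candidate is scored by the log-rank test of
`low = marker ≤ c` versus `high = marker > c`; the optimum minimizes p with
ties broken by larger statistic then smaller cutoff (an arbitrary but
deterministic order).

Two p values are reported deliberately:

* the **naive minimum** p over the scan, matching the emulated tools — and
  inheriting their multiple-testing optimism;
* a **permutation-adjusted** p (`n_permutations`, default 1000 in
  interactive use): the marker is permuted against the survival table and
  the minimum p recomputed, so the adjusted p is
  `(1 + #{permutation minima ≤ observed}) / (1 + B)`. Since the scan's
  minimum p is a monotone function of its maximum chi-square, the
  comparison is done on statistics directly. The adjusted p is valid for
  any B; the test suite uses B = 199 to stay within its runtime budget.

The published thresholds from the motivating TCGA analysis (ratio cutoffs
0.86 and 0.27; signature-score cutoffs 1.13 and −0.60) require the original
cohorts and are therefore shipped only as documented reference constants
(`reference_cutoffs()`), never recomputed.

## 5. RBP screen

Samples are split at the fourth quartile of the marker
(`quartile_groups()`: type-7 linear-interpolation quantile, boundary ties
all assigned high — the deterministic choice; the underlying analyses do
not specify tie handling). Each RNA-binding protein is tested by a
two-sided Wilcoxon rank-sum test: exact by enumeration when the smaller
group has ≤ 10 observations and the data are untied, otherwise the normal
approximation with tie and continuity corrections. Direction is assigned by
group medians (configurable in principle; "overexpression" was reported
without an effect measure), and tied medians are never significant.
Significance is per-cohort uncorrected p < 0.05, as is conventional for
this screen — a caveat, not an endorsement: with 21 cohorts the expected
number of spuriously "up" cohorts per null RBP is about
0.025 × 21 ≈ 0.5, which the null-calibration test verifies empirically.
Ranking sorts by the number of significantly up (or down) cohorts with ties
broken by the opposite count and then the identifier.

## 6. Deconvolution strata

The ensemble deconvolution used in the motivating work is replaced by a
documented, fully testable stand-in: per-sample non-negative least squares
(hand-written Lawson–Hanson active set) of the bulk expression on the
reference's cell-type columns over shared genes, normalized to the simplex.
This is a methodological substitution, not a claimed equivalence; the
downstream use is only *average* proportions per stratum, which the
mixture-recovery tests show the stand-in estimates accurately at the
simulated noise levels. Strata are marker deciles (type-7 boundaries, ties
to the lower decile) or subtype × within-subtype fourth-quartile groups
(subtypes with fewer than 8 samples stay whole, with a warning).

## 7. The synthetic world

`generate_cohort()` draws from a latent-factor log-normal model: per sample
a standard normal factor per module, gene `g` of module `m` having
`log2(TPM+1) = μ_g + λ f_m + ε`, `ε ~ N(0, σ)`, baselines
`μ_g ~ U(3, 8)`; background genes are independent noise. The first module
is the *ratio module*: the long isoform loads `+ratio_coupling` and the
short isoform `−ratio_coupling` on its factor, so the realized ratio tracks
the factor. Planted within-module correlation is `λ²/(λ² + σ²)` — 0.8 at
the defaults λ = 1, σ = 0.5 — which the tests verify by simulation.
Survival is exponential with hazard
`baseline_hazard × exp(β·1[f > 0])` (defaults 0.1 and β = 0.9) under
independent Uniform(0, 30) censoring; the true high-ratio label is defined
as `f > 0`, i.e. on the latent factor rather than the noisy realized ratio,
so ground truth is clean. One subtype ("ClaudinLow-like") is sampled with
weight `exp(1.5 f)` against unit weights for the others, enriching it among
high-factor samples. Defaults (600 genes, 300 samples, two 50-gene
modules) mirror the scale at which the recovery properties are asserted;
the cohort-pair generator defaults to the motivating 512- and 2508-gene
ratio modules sharing 158 genes.

What the generator does **not** emulate: TCGA marginal distributions, batch
effects, gene-length or library-size artifacts, real gene identifiers,
correlated censoring, or subtype-specific expression programs beyond the
single planted enrichment. A green test therefore establishes that the
implementation is correct *under the stated statistical model* — factor
modules, exponential hazards, Dirichlet mixtures — and says nothing about
robustness to real-data pathologies the model excludes.

## 8. Reproducibility

All generators take explicit integer seeds and fix the RNG kind, so equal
config + seed gives bit-identical output. `run_pipeline()` fans one global
seed out to per-stage seeds via a fixed counter scheme
(`seed × 1000 + stage offset`, reduced mod 2³¹ − 1) and records a manifest
with a content hash per stage, which the determinism tests compare across
runs. A failing stage aborts with its name while earlier stage outputs
remain on disk.
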