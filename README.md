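# nfyar

Splice-isoform ratios as continuous tumour markers: co-expression
signatures, prognostic stratification, and cell-type composition.

## The problem

The NF-Y transcription factor's regulatory subunit NF-YA is expressed as two
splice isoforms — NF-YA long (NF-YAl, which retains 28 exon-3 amino acids)
and NF-YA short (NF-YAs). In epithelial tumours with mesenchymal/EMT
features (notably the Claudin-low subtype of breast and gastric cancer), the
balance shifts towards the long form, making the per-sample ratio

    NF-YAr = NF-YAl / NF-YAs

a continuous marker of mesenchymal character. `nfyar` implements the full
downstream analysis of such a marker as a reusable, tested R pipeline:

1. **Feature construction** — replace the gene-level row with the two
   isoforms and the ratio, on the log2(TPM + 1) scale
   (`build_feature_matrix()`).
2. **Signed weighted co-expression networks** — adjacency
   `a_ij = ((1 + cor_ij)/2)^β`, topological overlap
   `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`, average-linkage
   clustering and module detection treating the ratio as a "normal" gene
   (`detect_modules()`, `pick_soft_threshold()`).
3. **Cross-cohort signatures** — intersect the ratio-bearing modules of
   several cohorts and score samples by the median Z across signature genes
   (`intersect_signatures()`, `score_samples()`).
4. **Prognostic dichotomization** — exhaustive log-rank cutoff scan of the
   (capped) marker against progression-free interval, with Kaplan–Meier
   curves and an honest permutation-adjusted p for the selection optimism of
   the minimum-p cutoff (`scan_cutoffs()`).
5. **Splicing-regulator screens** — rank RNA-binding proteins by the number
   of cohorts where their expression differs between fourth-quartile
   high-ratio samples and the rest (two-sided Wilcoxon rank-sum, exact by
   enumeration on small groups; `rbp_screen()`, `rank_rbps()`).
6. **Deconvolution strata** — estimate cell-type proportions by
   non-negative least squares against a reference and summarize mean
   compositions across marker deciles and subtype × high-ratio strata
   (`estimate_proportions()`, `decile_strata()`, `subtype_partition()`).

Because real cohort data (TCGA-scale expression, survival and single-cell
references) cannot ship with a package, `nfyar` includes a first-class
synthetic-cohort generator with planted ground truth for every stage:
latent-factor gene modules, isoforms coupled with opposite sign to the ratio
module's factor, subtype labels enriched for high ratio, exponential
progression times with a ratio-dependent hazard, RBPs with planted
directional coupling across many cohorts, and bulk mixtures with known
cell-type proportions (`generate_cohort()`, `generate_cohort_pair()`,
`generate_rbp_cohorts()`, `generate_mixture_samples()`). Every analysis
claim in the test suite is checked against this planted truth or against an
independent oracle (hand-computed tables, `survival::survdiff`,
`wilcox.test`, closed-form factor-model correlations).

## Worked example

```r
library(nfyar)

cfg      <- generator_config(seed = 7)           # 600 genes, 300 samples,
coh      <- generate_cohort(cfg)                 # two planted 50-gene modules
features <- build_feature_matrix(coh$expression, coh$samples)
modules  <- detect_modules(features, network_params(power = 4))
modules
#> <nfyar_modules> 603 genes, 2 modules (+ 501 unassigned)
glance(modules)
#> # A tibble: 1 × 5
#>   n_genes n_modules n_unassigned largest_module mean_var_explained
#>     <int>     <int>        <int>          <int>              <dbl>
#> 1     603         2          501             52              0.806
find_ratio_module(modules)
#> [1] 1
```

Both planted modules are recovered (52 members = 50 genes plus the
`NFYA_long` and `NFYAr` features riding the same latent factor), the 500
background genes land in the unassigned module 0, and the ratio feature sits
in module 1 together with the long isoform — the configuration the analysis
expects. Scoring and survival stratification continue from there:

```r
sig  <- names(modules$labels)[modules$labels == find_ratio_module(modules)]
head(score_samples(setdiff(sig, c("NFYA_long", "NFYA_short", "NFYAr")),
                   zscore_matrix(features)), 3)
#> # A tibble: 3 × 2
#>   sample  score
#>   <chr>   <dbl>
#> 1 S0001   2.00
#> 2 S0002  -1.04
#> 3 S0003  -0.734

ratio <- isoform_features(features)
scan_cutoffs(setNames(ratio$capped_ratio, ratio$sample), coh$survival,
             n_permutations = 199)
#> <nfyar_cutoff> optimal cutoff 0.8991 (n_low = 133, n_high = 167)
#>   log-rank chi-square = 20.614, naive p = 5.62e-06,
#>   permutation-adjusted p = 0.005 (199 permutations)
```

The generator plants a log hazard ratio of 0.9 on high-factor samples, so
the scan finds a strongly separating cutoff; the permutation-adjusted p
accounts for scanning all admissible splits. `plot_km_curves()`,
`autoplot()` on a module partition, `plot_rbp_grid()` and `plot_strata()`
produce the corresponding figures, and `tidy()`/`glance()` methods return
tibbles for downstream work. `run_pipeline(pipeline_config(seed = 1))`
chains every stage and records a manifest of stage hashes for
reproducibility.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the complete pipeline (cohort-pair generation, feature construction,
module detection in both cohorts, cross-cohort signature, sample scoring,
survival cutoff scans for the ratio and the signature score, the 21-cohort
RBP screen, and deconvolution stratum summaries) from the given seed and
writes the JSON report to `--out`.

## Documentation

The methods vignette (`vignettes/isoform-ratio-pipeline.Rmd`) describes the
model assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and known
limitations of the simplified algorithms (tree cut, single-reference NNLS
deconvolution).
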