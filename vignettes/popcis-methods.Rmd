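---
title: "Ancestry-differentiated cis-eQTL mapping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-differentiated cis-eQTL mapping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcis)
```

## The scientific problem

Some diseases are markedly more prevalent in one ancestry than in others;
ovarian clear cell adenocarcinoma in the Japanese population is the
motivating case for this package. When that is so, germline variants whose
allele frequencies are enriched in the susceptible ancestry, and which
regulate nearby genes, are candidate susceptibility loci. `popcis`
implements this reasoning as a three-step discovery funnel over candidate
SNPs:

1. **Variant QC** (`qc_filter()`): exclude SNPs with imputation accuracy
   r² < 0.25, minor allele frequency < 0.1, or Hardy–Weinberg equilibrium
   p < 10⁻⁴. All three are strict-inequality exclusions, so a variant
   sitting exactly on a threshold passes.
2. **Cross-population differentiation** (`pop_diff_records()`,
   `select_differential_snps()`): for each surviving SNP, tabulate ref/alt
   allele counts per population (a 2 × K table), test homogeneity with a
   Pearson chi-square on K − 1 degrees of freedom, and select SNPs with
   p < 0.001 whose alt-allele frequency in the *target* ancestry is a
   strict extremum (maximum or minimum) across populations. The extremum
   clause operationalizes "preferentially prevalent in" the target
   ancestry; either allele may be the enriched one.
3. **cis association** (`assign_cis_pairs()`, `regress_pair()`,
   `bh_adjust()`): pair each selected SNP with every annotated gene on the
   same chromosome within the cis window, regress expression on additive
   alt-allele dosage (0/1/2, intercept, no covariates), and control the
   false discovery rate at 0.05 with a single Benjamini–Hochberg
   adjustment across *all* pairs of the run.

A validation arm (`quantile_normalize()`, `ranksum_test()`,
`dichotomize_by_median()`, `km_fit()`, `logrank_test()`, `cox_fit()`)
mirrors the downstream clinical analyses: rank-based differential
expression between tissue groups and median-dichotomized survival
comparison of candidate genes.

## Key parameters

| parameter | default | units | notes |
|---|---|---|---|
| `r2_min` | 0.25 | — | imputation r²; absent r² is treated as directly genotyped and passes |
| `maf_min` | 0.1 | — | computed on the pooled analysis sample |
| `hwe_p_min` | 1e-4 | — | see *HWE scope and test choice* |
| `window` | 1,000,000 | bp | SNP to nearest gene boundary, inclusive; 0 inside the gene body |
| `p_threshold` | 0.001 | — | differentiation selection, strict |
| `alpha` | 0.05 | — | FDR level of the cis stage |

### The cis window

The worked example that ships with the package (`ovcca_example()`) lists
eight reported SNP–gene pairs; three of them lie 640–723 kb from their
gene, which contradicts a nominal "within 500 kb" rule. Rather than guess
how those distances were measured, the window is an explicit parameter
with a 1 Mb default that reproduces all printed pairs; `window = 5e5`
restores the stricter rule. Distances are measured from the SNP position
to the nearest gene boundary in 1-based coordinates (BED input is
converted at the boundary by `read_gene_annotation()`).

### HWE scope and test choice

HWE is a *within-population* equilibrium. In a pooled multi-ancestry
sample, allele-frequency differentiation itself depresses heterozygosity
(the Wahlund effect), so a pooled HWE filter preferentially removes
exactly the ancestry-differentiated SNPs the funnel is built to find: at
the drift levels used in our planted simulations (F = 0.25 across three
populations of 200), pooled screening at p < 10⁻⁴ would discard roughly
half of them. `run_funnel()` therefore screens HWE within each population
(a variant fails if any single population does), while standalone
`qc_filter()` keeps the conventional pooled default for single-population
data.

The test itself defaults to the Pearson chi-square with 1 df. When any
expected genotype count is below 5 the chi-square tail is anticonservative
at the extreme threshold 10⁻⁴; `hwe_test(method = "exact")` provides the
conditional (Levene–Haldane) exact test, and `method = "auto"` — the
funnel's choice — switches to it precisely in that small-count regime.

### Differentiation test

The 2 × K test uses *allele* counts (2N per population), not genotype
counts, matching the convention of reporting "frequencies of alternative
alleles"; the degrees of freedom are K − 1. No continuity correction is
applied (counts here are hundreds per cell). Degenerate tables — a
population with no called samples, or a variant monomorphic in every
population — are flagged and skipped with a recorded reason instead of
receiving a fabricated statistic.

### Regression and FDR

`regress_pair()` is ordinary least squares with an intercept on
pairwise-complete observations; pairs with fewer than 3 complete
observations or a constant dosage/expression vector are excluded from the
FDR set with a logged reason rather than assigned p = 1. A perfect fit
reports the smallest positive double rather than p = 0. BH adjustment is
applied once, globally, across all tested pairs of a run — the simpler
and more conservative convention compared with per-SNP adjustment.
Regression pools all analysis samples (the intersection of genotype,
expression, and panel sample sets, computed once and logged); this is the
plainest reading of a structure-agnostic cis scan, and it is also where
population stratification can induce associations between differentiated
SNPs and structured expression — visible in simulations as significant
pairs beyond the planted ones.

## The synthetic-data generator

`simulate_genotypes()` draws from the Balding–Nichols model: each SNP has
an ancestral frequency p ~ U(`ancestral_freq_range`), each population
draws its own frequency from Beta with mean p and variance F·p(1 − p),
and individuals draw genotypes binomially — so within-population HWE holds
by construction and per-SNP differentiation is tunable through F
(`fst_background` = 0.01 for the many, `fst_differentiated` = 0.25 for
the planted few, mirroring a funnel in which a small minority of
candidate SNPs is strongly drifted). When `target_population` is set, the
most drifted subpopulation frequency of each differentiated SNP (the one
farthest from p, hence always the maximum or minimum of the set) is
assigned to the target population. This makes the planted SNPs
*ancestry-enriched*, not merely differentiated, while leaving the
Balding–Nichols marginals untouched; without it, an exchangeable model
would put the target at an extremum only two-thirds of the time and no
selection rule keyed to target enrichment could recover planted SNPs
reliably.

Expression is additive: each gene is the sum of β × dosage over its
configured cis effects plus Gaussian noise (`noise_sd`, default 1 —
effects are therefore expressed in residual-SD units). Survival times are
exponential with hazard `baseline_hazard · exp(log_hazard · expression)`
under independent exponential censoring. Imputation r² is U(0.2, 1.0), so
about 6% of simulated SNPs fail the r² filter and the filter is
exercised; `low_r2_fraction` can force an exact share below 0.25.

`planted_funnel_config()` bundles the study conditions used by the
end-to-end tests: 935 SNPs on a 10 kb grid, three populations (CEU, CHB,
JPT) of 200 samples, four differentiated SNPs enriched in JPT, each with
a true cis effect of β = 1 on its nearest gene. Its ancestral frequencies
are drawn from (0.25, 0.75) — the input SNPs emulate array-genotyped
common cis-eQTL candidates, and this keeps the planted causal variants
polymorphic in every subpopulation under strong drift (the generic
`sim_config()` default remains (0.1, 0.9) so the MAF filter has work to
do in QC-focused tests).

What the generator does **not** emulate: linkage disequilibrium between
SNPs (every SNP drifts and segregates independently), admixed
individuals, and probe-level microarray noise. Passing the recovery tests
therefore demonstrates correctness of the pipeline's statistics under
idealized structure, not robustness to LD-induced redundancy or batch
artefacts in real arrays.

## Survival machinery

`km_fit()` is the product-limit estimator over distinct event times, with
the median defined as the earliest event time at which the curve reaches
0.5 or below ("not reached" = `NA` otherwise). `logrank_test()` sums
observed-minus-expected events with hypergeometric variance.
`cox_fit()` maximizes the Breslow partial likelihood by Newton–Raphson,
declaring convergence when the largest score component drops below 10⁻⁸
(at most 50 iterations); standard errors come from the inverse observed
information, and runs that diverge — as under perfect separation — are
flagged `converged = FALSE` with a warning instead of being returned
silently. Breslow tie handling is the simplest consistent choice and is
what the test suite cross-checks against an independent implementation.
`ranksum_test()` enumerates the exact rank-sum distribution when the
combined sample is ≤ 20 and untied, and otherwise uses the normal
approximation with midranks, tie-corrected variance, and continuity
correction. Median dichotomization sends ties (including the median
sample itself at odd n) to the "low" group so group sizes are
deterministic.

Quantile normalization replaces each sample's values by the mean of the
cross-sample order statistics at the same rank, tied values receiving the
mean of their tied reference values. Batch-effect correction beyond
quantile normalization (e.g. empirical-Bayes batch adjustment) is
deliberately out of scope; users combining platforms should apply their
preferred correction before the clinical-arm functions.

## Numerical conventions and degenerate inputs

- Missing dosage is `NA`, never 0, and is excluded pairwise everywhere.
- Multi-allelic VCF records are rejected by name (the model is biallelic).
- Monomorphic variants are in exact HWE (chi2 = 0, p = 1) and undefined
  for FST (skipped).
- `bh_adjust()` keeps ties in stable input order; q-values are capped at
  1 and are monotone in p.
- All generators are pure functions of `(config, seed)` and restore the
  caller's RNG state.

## Problem sizes used by the test suite

The package's statistical guarantees are re-derived at test time at these
sizes, chosen to give tight Monte-Carlo bounds while keeping the default
suite around two minutes: null calibration with 10,000 regressions at
n = 100; FDR control over 200 replicates × 1,000 tests with 10% non-null
effects (β = 0.8, σ = 1); slope recovery over 500 replicates at n = 200;
simulator fidelity at F = 0.1 with 5,000 SNPs × 3 × 200 samples;
end-to-end planted recovery over 100 replicate funnels; and oracle
equivalence against an established survival implementation on 20 random
datasets (coefficients within 10⁻⁴) plus a 10⁵-draw permutation null at
n = 30. The permutation comparison uses n = 30 because at n = 10 with
discrete dosages the t approximation error (up to ~0.03) exceeds
Monte-Carlo resolution — a limitation of the analytic p-value worth
remembering for very small samples.

## Known limitations

- No LD modelling: selection and FDR behaviour under correlated SNPs is
  untested.
- The regression has no covariates (no PEER factors, no principal
  components); pooled-sample cis scans on structured data can pick up
  stratification-induced associations, as the planted simulations show.
- trans-eQTL scans, conditional multi-SNP models, and haplotype-level
  differentiation are out of scope.
- The clinical arm consumes already-coded (time, event) records; it does
  not compute intervals from calendar dates.
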