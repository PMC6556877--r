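---
title: "Estimating adipose cell-type composition from bulk RNA-seq and using it downstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating adipose cell-type composition from bulk RNA-seq and using it downstream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipodecon)
```

## The problem

Subcutaneous adipose tissue is a mixture of cell types — adipocytes
dominate, with variable fractions of macrophages, microvascular
endothelial cells (MVEC) and CD4+ T cells. Bulk RNA-seq of a biopsy
measures the average transcriptome of that mixture, so any analysis
of bulk adipose expression (differential expression with obesity
traits, co-expression modules, eQTL mapping) is confounded by
between-sample differences in cellular composition. `adipodecon`
estimates the relative proportions of the four cell types per sample
by ν-support-vector regression against a marker signature matrix,
and provides the downstream analyses in which those proportions are
either the phenotype (heritability, phenotype association) or a
covariate/interaction term (expression scans, eQTL models).

## The deconvolution model

A bulk profile $y$ (one sample, linear TMM-scale expression) is
modelled as a non-negative combination of reference cell-type
profiles, $y \approx B w$, where $B$ is the signature matrix
(genes × cell types) and $w \ge 0$, $\sum_j w_j = 1$ are relative
proportions. Estimation follows the published support-vector
deconvolution strategy:

1. **Signature construction** (`build_signature()`). Starting from
   replicated pure-cell reference profiles, each pair of cell types
   is compared per gene with Welch t-tests on $\log_2(x+1)$ values
   and Benjamini–Hochberg correction within the pair; genes at
   $q \le 0.30$ in any pair are candidates. The permissive default
   keeps the false-negative rate low — the regression step below
   reselects the informative genes per sample anyway. For each
   per-type count $G \in [50, 150]$, the union of the top-$G$ genes
   per type by fold change forms a candidate matrix, and the $G$
   minimising the 2-norm condition number $\kappa$ (ratio of extreme
   singular values) is kept: low $\kappa$ means the cell-type columns
   are distinguishable and the regression is stable.
2. **ν-SVR fit** (`deconvolve_sample()`). The mixture is z-scored
   over the genes it shares with the signature; the signature
   submatrix is standardized *globally* (one mean and one standard
   deviation across the whole submatrix). The global choice is
   deliberate: per-column scaling would erase the relative magnitudes
   of the cell-type columns, which are exactly what maps regression
   coefficients to proportions. A linear-kernel ν-SVR is fitted for
   each ν in {0.25, 0.50, 0.75} (regularization constant fixed at 1);
   ν controls the fraction of genes acting as support vectors, so the
   grid amounts to asking for sparser or denser marker support. The ν
   whose reconstruction has the lowest RMSE wins; negative
   coefficients are truncated at zero and the rest normalised to the
   simplex. Estimates are therefore *relative* to the cell types in
   the signature, never absolute tissue fractions.
3. **Deconvolution p value** (`permutation_p()`,
   `deconvolve_cohort()`). Each sample's fit correlation is compared
   with a null distribution obtained by deconvolving gene-permuted
   versions of the *whole* mixture vector;
   $p = (1 + \#\{r_\text{null} \ge r\})/(1 + n_\text{perm})$ with
   1,000 permutations by default, and samples failing $p < 0.01$ are
   flagged. Two implementation points matter for calibration. First,
   every sample gets its own null: null widths differ substantially
   between samples, and a shared null (as in the original tool)
   over-rejects in the far tail. Second, the
   permutation must rearrange the full expression vector, not just
   the values already on signature genes — each null draw must also
   resample *which* values land on the signature, otherwise the null
   variance is understated. Because per-sample nulls are expensive,
   `deconvolve_cohort()` stops a sample's permutations as soon as
   enough exceedances have accumulated to prove failure at the
   threshold; the pass/fail decision is provably identical to the
   full run's, and passing samples always complete all permutations.

The ν-SVR solver itself is a compact sequential-minimal-optimization
routine (C++) for the standard ν-SVR dual with a linear kernel. A
dedicated solver is used because deconvolution workloads refit the
same signature thousands of times (mixtures, permutations): the
kernel matrix $Q = XX^\top$ depends only on the signature and is
precomputed once. The solver is cross-checked against an independent
ν-SVR implementation (e1071/libsvm) in the test suite, which asserts
agreement of the weight vectors across random instances.

## The synthetic data model

All analyses run against synthetic data whose structure mirrors the
study design the methods assume:

* **Reference panel** (`generate_reference_panel()`): background
  genes share a log-normal abundance (log2 mean 5, sd 2); each cell
  type gets 50 disjoint marker genes raised by +3 log2 units
  (8-fold); replicates are mean-preserving log-normal perturbations
  with a 10% coefficient of variation. These values are fixed,
  documented stand-ins — real reference cells differ on many more
  genes and often far more than 8-fold on canonical markers.
* **Cohorts** (`generate_cohort()`): proportions are Dirichlet with
  concentration (30, 2, 5, 0.5) for (adipocyte, macrophage, MVEC,
  CD4+ T), giving adipocyte-dominated samples with marginal ranges
  like those reported for population adipose biopsies (adipocytes
  roughly 0.7–0.99, macrophages up to ~0.2, CD4+ T mostly below 1%);
  expression is the exact convex mixture of panel means plus
  multiplicative Gaussian noise; phenotypes with a requested Pearson
  coupling $r$ to a cell type are built as
  $r\,z + \sqrt{1-r^2}\,\varepsilon$ on the inverse-normal transform
  $z$ of the proportion, so the target correlation is exact in
  expectation.
* **Twins** (`generate_twin_pairs()`): bivariate normal pairs with
  correlation $a^2 + c^2$ (MZ) and $a^2/2 + c^2$ (DZ).
* **Genotypes** (`generate_genotypes()`): Hardy–Weinberg dosages from
  two binomial haplotypes, optional LD chains; `plant_eqtl()` rewrites
  one gene so that, on a Gaussian latent scale, it carries a main
  effect per allele and/or an interaction effect per allele per SD of
  the (inverse-normalised) cell proportion, with the residual
  rescaled so the planted coefficients are directly recoverable.

What passing tests on these data do **not** show: robustness to
sequencing chemistry and batch structure, to reference cells
mismatched to the tissue (the usual cause of samples failing the
deconvolution p value in post-mortem or mixed-depot cohorts),
to correlated replicate noise, or to expression distributions far
from log-normal. The generator makes marker structure clean by
construction; real signatures are noisier and benefit from larger
reference collections.

## Mixture benchmarking

`run_mixture_benchmark()` reproduces the standard in silico
benchmark: draw mixing proportions as normalized uniforms (rows of
$M$), synthesise ground-truth mixtures $S = CM^\top$ from held-out
replicate profiles $C$ (so the mixtures carry replicate-level noise
that the signature has not seen), optionally add scaled Gaussian
noise or spike a contaminant profile, deconvolve, and report the mean
absolute deviation (mAD) per cell type. The printed noise formula in
the source material mixes additive and multiplicative terms
inconsistently; this package's default is the multiplicative reading
$y_1 = y_0(1 + s\,x)$, $x \sim N(0,1)$ — "10% noise" distorts each
value by 10% on average — with the literal additive form available
via `add_noise(..., formula = "additive")` for comparison. Negative
values are clipped at zero. "Accurate under contamination" is
operationalised as per-type mAD not exceeding the contaminant
fraction.

## Downstream analyses

* **Phenotype association** (`cell_phenotype_association()`): linear
  model of the trait on the proportion plus covariates, reporting the
  partial correlation from the slope t statistic. The proportion is
  inverse-normal transformed by default — proportions are bounded and
  skewed, and the interaction models use the same normalisation — so
  the estimate matches the generator's coupling definition exactly;
  `transform = "none"` gives the raw-scale analysis (expect mild
  attenuation of planted couplings when comparing against the
  transformed target).
* **Dual-model expression scan** (`dual_model_expression_scan()`):
  per gene, expression on BMI with and without a cell-proportion
  covariate, Bonferroni threshold 0.05 divided by the number of genes
  actually scanned, and a summary of how many BMI associations are
  lost once composition is adjusted for. Family structure is handled
  by GLS with an exchangeable within-family correlation (moment
  estimate of the intraclass correlation from OLS residuals,
  closed-form block whitening); a full REML mixed model is out of
  scope and the approximation is shared by all association functions
  here.
* **Twin heritability** (`fit_ace()`): maximum likelihood on
  standardized pairs under the ACE expectations above, optimized over
  the smooth box parameterization $s = a^2 + c^2$, $t = a^2/s$ so the
  non-negativity constraints are plain bounds; boundary solutions are
  reported as-is, with no model pruning to AE/CE.
* **cis-eQTL scan** (`cis_scan()`): per gene–SNP OLS on
  inverse-normal expression with covariates residualized out,
  cis-windows of TSS ± 1 Mb (inclusive; the window is configurable),
  MAF ≥ 5% filtering, per-gene eigenMT correction (effective number
  of tests = smallest number of leading eigenvalues of the SNP
  correlation matrix reaching 99% of the trace), and
  Benjamini–Hochberg across genes at 5% FDR. Latent expression
  factors (`latent_factors()`) are top principal components of the
  inverse-normal expression matrix; PCs are used instead of a
  probabilistic factor model because the two capture near-identical
  composition/batch structure in population data and PCs are
  deterministic.
* **Interaction eQTLs** (`interaction_scan()`): per pair, expression
  on genotype, inverse-normalised cell proportion, and their product,
  with the Wald t test of the product term and plain Bonferroni over
  the number of tests executed (eigenMT is applied only to the main
  scan). At 49,219,795 tests the threshold is 1.01 × 10⁻⁹.
* **Genetic risk scores** (`compute_grs()`, `grs_association()`):
  weighted allele scores with effect alleles resolved against REF/ALT
  (mismatches skipped with a warning), associated with traits or
  proportions under the same family GLS.

## Numerical choices and degenerate inputs

* TMM normalization implements the weighted trimmed-mean definition
  (M trim 0.30, A trim 0.05, reference = sample with upper quartile
  closest to the mean); it matches edgeR's implementation to machine
  precision in the tests. Samples with zero counts are an error named
  by sample; genes at zero in either sample drop out of the trim.
* The inverse-normal transform uses Blom offsets with averaged ties;
  all-constant input is an error (ranks undefined).
* k-means expression outliers (k = 2, 10 restarts, fixed seed): the
  strictly smaller cluster is the outlier set; ties and
  non-separable inputs return no outliers with a warning.
* Rank-deficient signature candidates get $\kappa = \infty$ and are
  never selected; fold-change ties break lexicographically by gene id
  so selection is deterministic.
* All generators are bit-reproducible given a seed; per-purpose
  streams are derived from the master seed so stages stay independent.
* SMO stopping tolerance is 1e-3 (matching the reference libsvm
  default) with an iteration cap; a mixture constant across signature
  genes is rejected rather than z-scored into NaNs.

## Problem sizes in the shipped checks

The packaged tests and the acceptance script run the full published
benchmark shapes where they are cheap (1,000 mixtures; 500 null
samples × 1,000 permutations; 400 + 400 twin pairs × 50 replicates;
100 cohorts of n = 766; 25 interaction replicates at n = 720) and
smaller fixtures (600-gene panels, tens of samples) for unit-level
properties. The held-out pure-replicate check sits at the edge of its
≥ 99% criterion under the generator's noise settings; the test
asserts the strict criterion and can fail for some held-out draws —
an inherent property of the synthetic conditions (the ν-SVR estimate
matches a non-negative least-squares oracle there), not of the
estimator.

## Known limitations

Relative proportions only; four cell types (no pre-adipocytes or
mesenchymal stem cells, whose absence plausibly inflates adipocyte
estimates on real data); GLS approximation instead of REML mixed
models; PCs instead of probabilistic latent factors; no read-level
simulation (alignment, GC, insert size are upstream of this package's
inputs).
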