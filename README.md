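# adipodecon

Cell-type deconvolution of bulk adipose-tissue RNA-seq, and the
analyses that depend on the estimated composition.

Subcutaneous adipose tissue is a mixture of adipocytes, macrophages,
microvascular endothelial cells (MVEC) and CD4+ T cells in proportions
that vary substantially between people and track obesity traits. Bulk
RNA-seq averages over that mixture, so composition confounds
differential expression, co-expression and eQTL analyses — and is
itself a phenotype worth studying. `adipodecon` is aimed at
transcriptomics/statistical-genetics analysts working with population
adipose (or similar solid-tissue) RNA-seq cohorts.

## What it computes

**Deconvolution.** A bulk profile *y* is modelled as a non-negative
convex combination of cell-type signature profiles, *y ≈ Bw* with
*w ≥ 0*, Σ*w* = 1. The signature matrix *B* is built from replicated
pure-cell reference profiles: pairwise Welch t-tests at a permissive
FDR (q ≤ 0.30), then per-type fold-change ranking with the per-type
gene count *G* chosen to minimise the condition number
κ = σ_max/σ_min. Proportions are estimated by linear-kernel
ν-support-vector regression (ν ∈ {0.25, 0.50, 0.75}, keeping the
minimum-RMSE fit), with negative coefficients truncated and the rest
renormalised; a per-sample permutation p value (1,000 gene
permutations, threshold p < 0.01) flags samples the signature cannot
explain. Estimates are relative, not absolute, fractions.

**Benchmarking.** In silico mixtures S = CMᵀ with known uniform
proportions, scaled Gaussian noise y₁ = y₀(1 + s·x), contaminant
spiking, and mean-absolute-deviation (mAD) accuracy metrics.

**Downstream.** Phenotype–composition association (partial
correlations under exchangeable-family GLS), a dual-model BMI
expression scan (with/without macrophage adjustment), ACE twin
heritability by maximum likelihood (h² = a²), cis-eQTL scanning with
eigenMT effective-test correction, genotype × cell-proportion
interaction eQTLs with Bonferroni control, and weighted genetic risk
scores.

**Synthetic data.** Generators for every input — replicated reference
panels with planted markers, Dirichlet-mixture cohorts with
phenotype couplings, MZ/DZ twin pairs, Hardy–Weinberg genotypes with
plantable main/interaction eQTL effects — so the whole pipeline runs
and is testable without controlled-access human data.

## Worked example

```r
library(adipodecon)

panel <- generate_reference_panel(seed = 1)   # 4 cell types, 50 markers each
sig   <- build_signature(panel)
sig
#> signature_matrix: 200 genes x 4 cell types
#>   kappa = 2.847 | q = 0.3 | top-G per type = 50

cohort <- generate_cohort(panel, n = 50, seed = 7,
  phenotype_couplings = list(android_gynoid_ratio =
                               list(cell_type = "macrophage", r = 0.36)))
res <- deconvolve_cohort(cohort$expression, sig, n_perm = 200, seed = 7)
head(res[, c("sample", "adipocyte", "macrophage", "MVEC", "CD4T",
             "pearson_r", "p_value")])
#>   sample adipocyte macrophage   MVEC    CD4T pearson_r p_value
#> 1  S0001     0.784     0.0276 0.1681 0.01985     0.990 0.00498
#> 2  S0002     0.770     0.0735 0.1222 0.03471     0.990 0.00498
#> 3  S0003     0.839     0.0569 0.1045 0.00000     0.994 0.00498
#> 4  S0004     0.861     0.0460 0.0912 0.00155     0.985 0.00498
#> 5  S0005     0.738     0.0790 0.1627 0.02053     0.991 0.00498
#> 6  S0006     0.889     0.0634 0.0475 0.00000     0.994 0.00498
attr(res, "failed_fraction")
#> [1] 0
```

Every sample deconvolves with a near-perfect fit correlation and the
smallest achievable permutation p (all 200 null fits are worse), so
none is flagged. Accuracy against the generating truth:

```r
evaluate_mad(cohort$true_proportions,
             as.matrix(res[, colnames(cohort$true_proportions)]))$per_type
#>  adipocyte macrophage       MVEC       CD4T
#>     0.0128     0.0053     0.0106     0.0047
```

Mean absolute errors of 0.5–1.3 percentage points per cell type. The
planted macrophage–body-fat-distribution coupling (generating
r = 0.36) is recovered within sampling error of this small cohort:

```r
cell_phenotype_association(cohort$true_proportions, cohort$phenotypes,
                           "android_gynoid_ratio", "macrophage")
#>                  trait  cell_type     r   beta      p  n covariates
#> 1 android_gynoid_ratio macrophage 0.294 0.0569 0.0385 50
```

Twin heritability of a trait simulated at a² = 0.30, c² = 0.10:

```r
fit_ace(generate_twin_pairs(400, 400, a2 = 0.30, c2 = 0.10,
                            e2 = 0.60, seed = 7))
#> ACE estimate (400 MZ, 400 DZ pairs):
#>   a2 (h2) = 0.357  c2 = 0.000  e2 = 0.643  logLik = -2236.93
```

A single draw of 800 pairs carries this much sampling noise (the c²
component sits on its boundary here); averaged over replicate
simulations the estimator is unbiased, which is what the acceptance
checks assert.

`run_pipeline(out_dir, seed)` wires the stages — simulate, signature,
deconvolve, benchmark, associate, heritability, eQTL — into one run
directory with a JSON manifest of parameters, seeds and output
checksums; reruns with the same seed are bit-identical.

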