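---
title: "Inferring and controlling population structure from RNA-seq genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and controlling population structure from RNA-seq genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnapopstruct)
```

## The problem

Bulk RNA-seq read sets carry germline genetic variation, and variant calls
made from them can substitute for genotyping arrays when estimating the
latent genetic structure of a cohort. Expression studies that ignore this
structure risk confounded associations: if the trait of interest (say, sex
or disease status) is unevenly distributed across ancestry groups, genes
whose expression differs between groups for purely genetic or environmental
reasons masquerade as trait-associated. `rnapopstruct` implements the
post-variant-calling half of that workflow: it consumes genotype calls (a
multi-sample VCF), applies array-style quality control, computes genetic
principal components from the RNA-seq-derived genotypes ("RG-PCs"),
quantifies how faithfully they reproduce the structure seen in a paired
genotyping array, and measures how much including them as covariates
deflates test statistics in differential expression.

Upstream read processing (trimming, alignment, GATK variant calling) is out
of scope; the package starts from the VCF.

## Genotype model and quality control

Genotypes are alternate-allele dosages in {0, 1, 2}, with a single `NA`
sentinel for missing calls. Half-calls (`./1`) are conservatively treated as
missing, phased and unphased calls are equivalent, and records with a
non-`PASS`/`.` FILTER are skipped at read time — variant callers emit
hard-filter flags, and an explicit policy beats an implicit one.

`filter_variants()` applies the canonical filters in a fixed order
(autosomal SNP, duplicate, palindromic, excluded region, call rate, MAF,
optional HWE), counting each removed variant once at the first rule that
claims it, so the per-rule counts always add up. Default thresholds are the
ones that work well for genotype-PC estimation from RNA-seq calls:
MAF strictly greater than 0.05, per-variant missingness at most 0.1,
per-sample missingness at most 0.2 ("more than 20% missing" removes a
sample, so exactly 20% is kept), HWE disabled. The excluded region defaults
to the extended HLA interval, chr6:25,000,000–34,000,000 on GRCh38,
half-open; the MHC's long-range LD and extreme polymorphism otherwise
dominate the leading PCs. Palindromic (A/T, C/G) SNPs are removed because
their strand is undecidable from alleles alone.

The Hardy–Weinberg test is the two-sided conditional exact test: given the
genotype total and minor-allele count, the p-value sums the probabilities of
all heterozygote counts no more probable than the observed one. It is
validated against full enumeration for every configuration with up to 50
genotypes.

LD pruning uses sliding windows measured in *variant count* (window 1000,
step 50, r² ceiling 0.05) — the interpretation matching the printed
parameter triplet. Within a window, the member of an offending pair with
the lower MAF is removed; ties remove the later-positioned variant. The
exact tie-breaking of reference pruning binaries is not documented anywhere
authoritative, so this package fixes its own rule and tests it as stated,
including the directly assertable post-condition that no kept pair sharing
a window exceeds the threshold.

## Harmonization and concordance

Two genotype sources for the same individuals rarely agree on strand or
allele order. `match_variants()` keys on (chromosome, position) only and
then classifies each shared site as `direct`, `swap` (allele order
exchanged; dosage recodes d → 2 − d), `flip` (opposite strand; dosages
unchanged), `flip_swap`, or `unmatched`. Palindromic sites are categorically
`ambiguous_palindromic` even if upstream QC missed them. Concordance is
genotype-level — a heterozygote matches a heterozygote regardless of phase —
and its denominator counts only variants non-missing in *both* sources;
that denominator choice is a fixed convention of this package.

`intersect_with_panel()` restricts a callset to sites present (up to
flip/swap) in a reference panel of well-characterised SNPs, the standard
remedy when MAF and LD filtering alone leave too many noisy RNA-seq calls
for the leading PCs to reflect ancestry.

## PCA, comparison of PC sets, and the GRM

Dosages are standardized with the binomial convention
z = (g − 2p)/sqrt(2p(1 − p)), frequencies estimated from the cohort itself,
and missing entries mean-imputed to exactly 0 — the standard choice for
genotype PCA, harmless at the missingness levels that survive QC.
`compute_pcs()` eigendecomposes (1/m)ZZᵀ exactly (dense, at desk scale) and
returns principal-component *scores* (eigenvectors scaled by
sqrt(n·eigenvalue)); downstream correlation analyses are scale-invariant,
but the convention is fixed and documented. Signs follow a deterministic
rule (largest-magnitude loading made positive), so repeated runs are
bit-identical. Joint PCA of two cohorts harmonizes the shared variants,
stacks the samples and re-estimates frequencies on the merged cohort rather
than projecting one cohort onto the other's axes.

Agreement between an RG-PC set and an array PC set is summarized three
ways:

* a Spearman correlation matrix (t-approximation p-values; exact
  permutation adds nothing at cohort sizes in the hundreds);
* canonical correlation analysis, computed from orthonormal bases of the
  two centered blocks (pivoted QR, then SVD of the cross-product), which
  makes the result invariant to any invertible re-mixing of either block;
* Wilks' Lambda sequential tests, Λ_k = Π_{i≥k}(1 − R²_ci), with
  Bartlett's chi-square approximation −(n − 1 − (p+q+1)/2)·ln Λ_k on
  (p−k+1)(q−k+1) degrees of freedom. Bartlett is the simplest standard
  form and is adequate at these n; Rao's F would change nothing material.

"Proportion of shared variance" is operationalized as the **redundancy
index**: for variate i, Rd_i = R²_ci times the mean squared correlation
between the explained block's columns and that block's i-th canonical
variate. The direction of interest is how much of the *array* PC variance
the RG-PC variates capture; the symmetric quantity is reported alongside,
because the literature uses the phrase loosely and no single formula is
canonical. This is the package's largest interpretive choice.

The genomic relationship matrix is GRM = ZZᵀ/m on the same standardized
matrix, giving the covariance structure of the polygenic random effect.

## Differential expression and the inflation metric m

Genes are filtered at CPM > 0.05 (strict) in at least 20% of samples, then
modelled per gene by ordinary least squares of log2-CPM — offset convention
log2((count + 0.5)/(libsize + 1)·10⁶) — on intercept, trait, nuisance
covariates and optionally the genetic PCs. A negative-binomial GLM engine
would be the classical choice for the DGE itself, but the quantity this
package is about — the systematic inflation metric — is engine-agnostic:
every analysis converts its two-sided p-value to a 1-df chi-square (z²
convention), and

m = median(chi² with PCs) / median(chi² without PCs)

on the identical gene set. m < 1 means the PCs absorbed stratification that
was inflating the unadjusted statistics; m ≈ 1 in an unconfounded design
means the adjustment costs nothing. Benjamini–Hochberg q-values support
FDR-threshold gene counts.

The mixed-model alternative (`reml_lmm()`, `lmm_scan()`) fits
y = Xβ + g + ε with g ~ N(0, σ²_g·GRM). The GRM is eigendecomposed once;
the restricted likelihood is profiled over the variance ratio on a coarse
log10 grid and refined by 1-D optimization (tolerance 1e-6), with the
σ²_g = 0 boundary always checked. Association scans estimate components
once under the null and test each variant by GLS with components fixed.
One ambiguity deserves a flag: descriptions of this analysis sometimes say
structure PCs enter "as random effects"; the conventional and identifiable
formulation uses them as fixed-effect covariates, which is what this
package does, deliberately. With GRM = I the model degenerates gracefully:
the two components are not separately identifiable, but total variance and
all Wald statistics provably match OLS, and the code keeps that contract.

## The synthetic cohort generator

Because the real cohorts behind this class of analysis are access-restricted,
every validation surface is exercised on synthetic data with known truth:

* **Genotypes** follow the Balding–Nichols model — ancestral frequency
  p ~ U(0.05, 0.95) per variant, per-population frequencies
  Beta(p(1−F)/F, (1−p)(1−F)/F), genotypes Binomial(2, p_k). It is the
  minimal structured-population model with a single interpretable
  differentiation parameter; default study conditions are K = 3
  subpopulations at F_ST = 0.1 with 100 samples each and 5000 variants.
  Alt alleles are drawn from non-complementary bases so no simulated site
  is palindromic; palindromic handling is tested on constructed fixtures
  instead, and this keeps the strand-flip fraction exactly controllable.
* **Paired views**: the array view covers a random 60% of variants with 1%
  missingness; the RNA-seq view covers a 20% "transcribed" subset with 5%
  base missingness (optionally scaled per sample to mimic depth), 2%
  dosage-level genotype errors (each error changes the genotype, so the
  expected mismatch rate per compared call is exactly the error rate), and
  10% of its variants reported on the opposite strand.
* **Expression**: negative-binomial counts with log-normal library-size
  factors, 10% of genes carrying per-population mean offsets (ancestry
  confounding) and 5% carrying a ±1 log2-unit sex effect; dispersion 0.3.
  `simulate_sex()` optionally imbalances the sex ratio across populations —
  the mechanism that makes unadjusted sex-DGE statistics inflate.

What the generator does **not** emulate: read-level errors and alignment
artefacts (errors here are dosage-level), LD within populations (variants
are independent given ancestry, so pruning on simulated data removes only
chance correlations), admixed individuals, rare-variant ascertainment, and
expression-genotype coupling (no eQTLs). Passing tests therefore
demonstrate the statistical machinery and its contracts, not robustness to
every artefact of real RNA-seq calling.

## Numerical and scale choices

Exact dense SVD/eigendecomposition everywhere (cohorts of hundreds of
samples and tens of thousands of variants; a randomized path behind the
same contract would only matter far beyond that scale). Test and
acceptance-script problem sizes — 300 samples, 5000 variants, 2000 genes,
50 mixed-model replicates — were chosen as the smallest sizes at which the
mechanisms of interest (structure recovery, CCA agreement, inflation
direction, variance-ratio recovery) are decisively resolved; everything
runs in seconds on one core. Degenerate inputs are contracts, not
afterthoughts: monomorphic variants error out of standardization by name,
zero-variance LD pairs are flagged not fatal, perfect canonical correlation
reports an underflow-flagged p-value, and an all-samples-removed filter is
an explicit "empty cohort" error.

## Limitations

RG-PCs are a pragmatic substitute for array genotyping, not a replacement:
transcribed-region ascertainment misses regulatory and rare variation, and
the package inherits that limit. The DGE engine is a linear model on
log2-CPM; if your scientific claim depends on negative-binomial small-count
behaviour rather than on stratification control, use a dedicated DGE
package and feed its statistics into `inflation_m()` — the metric only
needs chi-squares. Case/control-stratified HWE filtering and IBD-based
relative removal are out of scope, as is out-of-sample PC projection.
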