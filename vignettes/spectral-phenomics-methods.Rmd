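---
title: "Methods: from leaf spectra to mapped loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from leaf spectra to mapped loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectragwas)
library(dplyr)
```

Leaf reflectance between 400 and 2500 nm integrates pigment content, cell and
canopy structure, water status and dry matter. In a genetically structured
population these optical properties are heritable, which makes the spectrum a
high-dimensional phenotype for genome-wide association. The difficulty is
that neighbouring wavelengths are almost perfectly correlated while distant
ones are not: treating each of the 2101 bands as an independent trait wastes
power and makes multiple-testing correction meaningless, and compressing the
whole spectrum to a handful of fixed indices throws away genetic signal that
does not happen to sit under an index.

`spectragwas` implements a complete pipeline around a data-driven middle
ground: hierarchical spectral clustering with parallel analysis (HSC-PA),
which partitions the wavelength axis into segments that each behave like a
single latent trait, and then maps those segment scores with a mixed linear
model. This vignette states the model at each stage, the estimation choices,
and the rationale for the package defaults.

## 1. Reflectance calibration and gridding

Raw scans are radiance counts. Relative reflectance at wavelength $\lambda$
is

$$ R(\lambda) = R_{\text{panel}}(\lambda)\,
   \frac{L_{\text{leaf}}(\lambda) - L_{\text{dark}}(\lambda)}
        {L_{\text{panel}}(\lambda) - L_{\text{dark}}(\lambda)}, $$

computed by `compute_reflectance()`. Slightly negative values can occur in
noisy, low-signal regions; they are kept by default so that downstream
averages remain unbiased, with `clamp_negative = TRUE` available when a
physical range is required. `clip_and_grid()` restricts spectra to
400–2500 nm and linearly interpolates onto the integer-nanometre grid, so
every downstream function can assume 2101 aligned bands.

## 2. Quality control

`lof_scores()` screens samples with the local outlier factor computed on a
principal-component embedding of the spectra (default 10 components, $k=20$
neighbours). LOF compares each sample's local density with that of its
neighbours, so it flags isolated spectra without assuming a global
distribution — appropriate for field data where the bulk of variation
(genotype, environment) is real and multi-modal. `flag_outliers()` applies a
score threshold (default 1.5) and returns a tidy per-sample table.

## 3. Environmental adjustment and variance partitioning

Field spectra carry strong non-genetic structure. `fit_adjust()` fits, per
wavelength, the fixed-effects model

$$ y = \mu + \text{LN} + \text{REP} + \text{BA} + \text{LN:REP} +
   \text{LN:BA} + \text{DT} + \text{CT} + \text{DT:CT} + \text{MO} +
   \varepsilon $$

(line, replicate, planting square/batch, measurement date and time, and the
neighbour/monoculture factor), in exactly this declared order, and returns
the residuals as adjusted spectra together with the sequential (Type I)
percent sum of squares of every term. The design is orthonormalized by
sequential Gram–Schmidt so the partition is exact and the percentages sum to
100 at every wavelength. Treating the planting square `BA` as a factor is a
deliberate choice: it absorbs fine-scale spatial variation robustly, at the
cost of spending many degrees of freedom — in small simulated designs this
visibly lowers the residual share relative to what a smooth spatial model
would leave.

## 4. HSC-PA: hierarchical spectral clustering with parallel analysis

The segmentation answers one question recursively: *does this set of bands
carry more than one independent signal?*

* **Stopping rule — parallel analysis.** `parallel_analysis()` compares the
  correlation-matrix eigenvalues of the observed bands with the 95th
  percentile of eigenvalues from column-permuted copies of the data (100
  permutations by default). The retained dimension is the length of the
  leading run of observed eigenvalues exceeding their permutation quantile,
  with a floor of one. Permutation (rather than the classical
  normal-reference Horn procedure) keeps the null marginal distributions of
  the actual data.
* **Split rule — normalized spectral bipartition.** When more than one
  component is retained, `split_segment()` builds a similarity matrix of
  squared Pearson correlations between bands (squared, so anti-correlated
  bands that reflect one latent property are grouped together; absolute
  correlation is available via `similarity = "absolute"`), forms the
  symmetric normalized graph Laplacian, and splits by the sign of the
  Fiedler vector. On block-structured data this sign split attains the
  exhaustive minimum normalized cut (verified against a brute-force oracle
  in the test suite).
* **Recursion.** `run_hscpa()` applies this from the root (all 2101 bands)
  until each segment retains a single component, with safeguards
  `min_bands = 5` and `max_depth = 8`. Terminal segments need not be
  contiguous in wavelength: bands that co-vary are grouped wherever they
  sit.

`segment_phenotypes()` scores each terminal segment by its first principal
component, with the sign pinned so that loadings sum positive, standardized
to mean 0 and variance 1. These scores are the GWAS traits.

## 5. Association scans

`glm_scan()` is an ordinary-least-squares per-SNP scan (vectorized via QR
residualization against covariates). `mlm_scan()` fits the mixed model

$$ y = X\beta + g\alpha + u + \varepsilon,\qquad
   u \sim N(0, \sigma_g^2 K),\quad \varepsilon \sim N(0, \sigma_e^2 I) $$

with `kinship()` (VanRaden, or `method = "zhang"` with the mean diagonal
rescaled to 1). Variance components are estimated by REML profiled over
$\delta = \sigma_e^2/\sigma_g^2$ using the eigendecomposition of $K$
(EMMA-style), and by default the scan is P3D: $\delta$ is estimated once
under the null per phenotype and reused for every SNP, which makes the
whole-spectrum scan practical. With an identity kinship the MLM collapses
exactly to the GLM.

## 6. Multiple testing across correlated traits

Segment scores are correlated, so Bonferroni over segments is too harsh.
`phenospd_correlation()` estimates the phenotypic correlation matrix from
GWAS summary statistics via cross-trait LD-score-regression intercepts
(`ld_scores()` provides windowed LD scores), projects it to the nearest
positive semi-definite matrix, and `meff()` converts it to an effective
number of independent tests (default: eigenvalue participation ratio;
`nyholt` and `liji` are available). `significance_threshold()` is
$\alpha/M_{\text{eff}}$, `bh_fdr()` applies Benjamini–Hochberg within
phenotype, and `call_significant()` combines both. `candidate_genes()`
intersects significant SNPs with gene windows from a GFF3 annotation, and
`top_k_dynamic()`/`topk_overlap()` support rank-based comparisons between
scans.

## 7. The simulator and its defaults

`simulate_founders()` / `simulate_rils()` generate a multiparent RIL
population (default 26 founders, 12 chromosomes): each line is a
founder-mosaic with Poisson recombination followed by explicit selfing
generations, so residual heterozygosity decays as $0.5 \cdot (1/2)^g$.
`simulate_spectra()` builds spectra as

template + latent factors + causal SNP effects + environment + noise,

with these default choices:

* **Four latent factors** (pigment, structure, water, dry matter) with
  smooth wavelength loadings and score SD 0.020 reflectance units each —
  enough to give the spectrum a realistic low-rank backbone without
  swamping the noise floor.
* **Wavelength-dependent noise** rising toward the SWIR edges, mimicking
  detector behaviour.
* **Environmental level effects** drawn per level of each design term, so
  `fit_adjust()` faces exactly the structure it models.
* **Phytometer fraction 0.25**: a quarter of plants are genetically uniform
  testers (causal effects zeroed), planted into every square, which is what
  makes the planting-square effect estimable separately from genetics
  (`estimate_patch_effects()`).

Every simulation returns a `truth` record (planted effects, latent scores,
environmental contributions, noise profile) so that each pipeline stage can
be tested against known ground truth; the acceptance tests in
`tests/testthat/test-acceptance.R` do exactly that.

## End-to-end sketch

```{r pipeline, eval = FALSE}
founders <- simulate_founders(n_snps = 3000, seed = 11)
geno <- simulate_rils(founders, n_rils = 250, seed = 12)
sim <- simulate_spectra(geno, seed = 13)

design <- build_design(sim$metadata)
fit <- fit_adjust(sim$spectra, design)

tree <- run_hscpa(fit$adjusted, seed = 14)
phen <- segment_phenotypes(tree, fit$adjusted)

scan <- mlm_scan(phen, geno, kinship(geno))
m <- meff(direct_correlation(phen)$correlation)
hits <- dplyr::filter(call_significant(scan, meff_value = m), significant)
genes <- candidate_genes(unique(hits$snp), "annotation.gff3")
```
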