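# spectragwas

Leaf reflectance spectra as phenotypes for genome-wide association.

## Why

A leaf's reflectance between 400 and 2500 nm is shaped by its pigments,
internal structure, water content and dry matter — all heritable. The full
spectrum is therefore a rich, cheap, non-destructive phenotype for mapping
loci in structured populations such as multiparent recombinant inbred lines
(RILs). But the 2101 bands are neither one trait nor 2101 independent ones:
adjacent wavelengths are almost perfectly correlated, distant ones are not.

`spectragwas` implements the full path from raw radiance scans to candidate
genes, built around **hierarchical spectral clustering with parallel analysis
(HSC-PA)**: a recursive bipartition of the wavelength axis that stops exactly
where a single principal component suffices to describe a segment, yielding a
small set of data-driven spectral traits for mixed-model GWAS.

## The model

1. **Calibration** — relative reflectance
   `R = R_panel * (leaf − dark) / (panel − dark)`, clipped and interpolated
   to the integer 400–2500 nm grid (`compute_reflectance()`,
   `clip_and_grid()`).
2. **Quality control** — local outlier factor on a PCA embedding of the
   spectra (`lof_scores()`, `flag_outliers()`).
3. **Environmental adjustment** — per-wavelength fixed-effects model
   `y ~ LN + REP + BA + LN:REP + LN:BA + DT + CT + DT:CT + MO` (line,
   replicate, planting square, date, time, neighbour) fitted in declared
   order with an exact sequential (Type I) variance partition; residuals are
   the adjusted spectra (`build_design()`, `fit_adjust()`).
4. **HSC-PA** — per segment, permutation-based parallel analysis decides how
   many components the bands carry; if more than one, the segment is split
   by the sign of the Fiedler vector of the normalized Laplacian of the
   squared-correlation similarity graph; terminal segments are scored by
   their standardized first principal component (`run_hscpa()`,
   `segment_phenotypes()`).
5. **GWAS** — vectorized OLS scan (`glm_scan()`) and an EMMA-style REML
   mixed model with VanRaden kinship and P3D (`mlm_scan()`, `kinship()`).
6. **Post-hoc** — PhenoSpD effective number of tests from cross-trait
   LD-score-regression intercepts (`ld_scores()`, `phenospd_correlation()`,
   `meff()`), `alpha / Meff` thresholds, Benjamini–Hochberg FDR, top-k scan
   comparison, and candidate genes from a GFF3 annotation
   (`candidate_genes()`).

A multiparent RIL simulator with a complete truth record
(`simulate_founders()`, `simulate_rils()`, `simulate_spectra()`) makes every
stage testable without field data. See
`vignettes/spectral-phenomics-methods.Rmd` for the methods in detail.

## Worked example

Simulate a 26-founder MAGIC-style population, plant one causal SNP acting on
the 1300–1600 nm water band, and recover it:

```r
library(spectragwas)
library(dplyr)

founders <- simulate_founders(n_snps = 3000, seed = 11)
geno <- simulate_rils(founders, n_rils = 250, seed = 12)
geno
#> <genotype_matrix> 250 samples x 3000 SNPs over 12 chromosomes

maf <- pmin(colMeans(geno$dosages) / 2, 1 - colMeans(geno$dosages) / 2)
causal <- colnames(geno$dosages)[which(maf > 0.3)[1500]]   # "chr7_22226767"

sim <- simulate_spectra(
  geno,
  effects = effect_spec(snp = causal, lo = 1300, hi = 1600, effect = 0.015),
  seed = 13)
sim$spectra[1:3, 1:4]
#> # A tibble: 3 x 4
#>   sample   `400`  `401`  `402`
#>   <chr>    <dbl>  <dbl>  <dbl>
#> 1 RIL0001 0.0942 0.0808 0.0979
#> 2 RIL0002 0.0671 0.0569 0.0655
#> 3 RIL0003 0.0664 0.0624 0.0542
```

Adjust for the field design and inspect the variance partition at 1450 nm
(a water absorption feature):

```r
design <- build_design(sim$metadata)
fit <- fit_adjust(sim$spectra, design)
fit$variance |> filter(wavelength == 1450) |> arrange(desc(percent)) |> head(4)
#> # A tibble: 4 x 3
#>   wavelength term     percent
#> 1       1450 BA          30.5
#> 2       1450 residual    30.4
#> 3       1450 LN:BA       20.9
#> 4       1450 MO          12.9
```

Segment the spectrum, score the segments, and scan:

```r
tree <- run_hscpa(fit$adjusted, seed = 14)
tree
#> <segment_tree> 23 nodes, 12 terminal segments, levels 1-5

phen <- segment_phenotypes(tree, fit$adjusted)
scan <- mlm_scan(phen, geno, kinship(geno))

m <- meff(direct_correlation(phen)$correlation)
c(meff = m, threshold = significance_threshold(m))
#>       meff  threshold
#> 3.59399530 0.01391209

call_significant(scan, meff_value = m) |> filter(significant) |> arrange(p)
#> # A tibble: 3 x 5  (columns abridged)
#>   snp           phenotype effect        p    p_adj
#> 1 chr7_22226767 seg21      0.524 8.78e-18 2.63e-14
#> 2 chr7_22226767 seg19      0.434 9.70e-13 2.91e- 9
#> 3 chr7_22226767 seg20      0.392 1.72e-10 5.17e- 7
```

The only genome-wide significant SNP is the planted one, found through three
water-band segments. Classical indices are available alongside:

```r
spectral_indices(sim$spectra) |> head(3)
#> # A tibble: 3 x 7
#>   sample       NDWI  CIre   CCI ARDSI_Cab ARDSI_Cw ARDSI_Cm
#> 1 RIL0001 -0.00976   1.83 0.330     0.126  0.0111   -0.0956
#> 2 RIL0002 -0.000875  2.17 0.380     0.131 -0.00900  -0.0960
#> 3 RIL0003 -0.00405   2.21 0.456     0.131 -0.00818  -0.104
```

## Command line

A thin CLI over the same functions lives at `inst/cli/spectragwas.R`
(installed under `system.file("cli", "spectragwas.R", package =
"spectragwas")`):

```sh
Rscript spectragwas.R simulate --n-rils 250 --seed 1 --out-dir sim/
Rscript spectragwas.R adjust --spectra sim/spectra.csv \
    --metadata sim/metadata.tsv --out-dir adj/
Rscript spectragwas.R hscpa --adjusted adj/adjusted.csv --seed 1 --out-dir hscpa/
Rscript spectragwas.R gwas --model mlm --phenotypes hscpa/phenotypes.tsv \
    --vcf sim/genotypes.vcf --out assoc.tsv
Rscript spectragwas.R posthoc --assoc assoc.tsv --vcf sim/genotypes.vcf \
    --out-dir posthoc/
```

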