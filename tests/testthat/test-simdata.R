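test_that("simulate_founders enforces the founder allele-frequency range", {
  f2 <- simulate_founders(n_founders = 2, n_snps = 10, n_chrom = 1,
                          maf_range = c(0.5, 0.5), seed = 1)
  expect_true(all(colMeans(f2$alleles) == 0.5))

  f <- simulate_founders(n_founders = 26, n_snps = 1000, seed = 42)
  freq <- colMeans(f$alleles)
  expect_true(all(freq >= 0.1 - 1e-9 & freq <= 0.5 + 1e-9))
  expect_equal(nrow(f$map), 1000)
  # positions strictly increasing within chromosome
  by_chr <- split(f$map$pos, f$map$chrom)
  expect_true(all(vapply(by_chr, function(x) !is.unsorted(x, strictly = TRUE),
                         logical(1))))
})

test_that("simulate_founders is deterministic and validates maf_range", {
  a <- simulate_founders(n_founders = 6, n_snps = 50, seed = 9)
  b <- simulate_founders(n_founders = 6, n_snps = 50, seed = 9)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$map, b$map)
  expect_error(simulate_founders(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulate_founders(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(simulate_founders(n_founders = 1), "n_founders")
})

test_that("RILs without recombination or selfing copy founder haplotypes", {
  f <- simulate_founders(n_founders = 2, n_snps = 60, n_chrom = 2,
                         maf_range = c(0.5, 0.5), seed = 3)
  g <- simulate_rils(f, 25, crossovers_per_chrom = 0,
                     selfing_generations = 0, seed = 4)
  expect_true(all(g$dosages %in% 0:2))
  # per chromosome, each gamete is one founder haplotype verbatim, so the
  # dosage vector is the sum of two founder rows
  for (cc in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == cc)
    al <- f$alleles[, idx, drop = FALSE]
    combos <- rbind(al[1, ] + al[1, ], al[1, ] + al[2, ], al[2, ] + al[2, ])
    for (i in seq_len(nrow(g$dosages))) {
      hit <- apply(combos, 1, function(cmb) all(cmb == g$dosages[i, idx]))
      expect_true(any(hit))
    }
  }
})

test_that("heterozygosity halves per selfing generation", {
  f <- simulate_founders(n_founders = 8, n_snps = 80, n_chrom = 2,
                         maf_range = c(0.5, 0.5), seed = 5)
  for (gen in c(1, 3)) {
    g <- simulate_rils(f, 150, selfing_generations = gen, seed = 6)
    expected <- 0.5 * 0.5^gen
    n_cells <- length(g$dosages)
    se <- sqrt(expected * (1 - expected) / n_cells)
    # entries within a line/chromosome are correlated; inflate the binomial
    # SE by a generous factor before applying the 3-SE rule
    expect_lt(abs(heterozygosity(g) - expected), 3 * 10 * se + 0.01)
  }
})

test_that("simulate_rils is deterministic and validates inputs", {
  f <- simulate_founders(n_founders = 4, n_snps = 30, seed = 1)
  a <- simulate_rils(f, 10, seed = 2)
  b <- simulate_rils(f, 10, seed = 2)
  expect_identical(a$dosages, b$dosages)
  expect_error(simulate_rils(f, 0), "n_rils")
  expect_error(simulate_rils(f, 5, selfing_generations = -1),
               "selfing_generations")
})

test_that("degenerate spectra simulation returns the base template", {
  g <- small_genotypes(n_rils = 6, n_snps = 20)
  sim <- simulate_spectra(
    g,
    effects = effect_spec(latent_sd = c(pigment = 0, structure = 0,
                                        water = 0, dry_matter = 0)),
    env = env_design(sd = c(LN = 0, REP = 0, BA = 0, `LN:REP` = 0,
                            `LN:BA` = 0, DT = 0, CT = 0, `DT:CT` = 0,
                            MO = 0)),
    noise = rep(0, 2101), seed = 1)
  m <- as.matrix(sim$spectra[-1])
  tmpl <- spectral_template(400:2500)
  for (i in seq_len(nrow(m))) {
    expect_equal(unname(m[i, ]), tmpl, tolerance = 1e-12)
  }
  expect_identical(names(sim$spectra)[-1], as.character(400:2500))
})

test_that("a planted causal SNP shifts its band by twice the allele effect", {
  g <- small_genotypes(n_rils = 200, n_snps = 60, seed = 11)
  maf <- pmin(colMeans(g$dosages) / 2, 1 - colMeans(g$dosages) / 2)
  snp <- colnames(g$dosages)[which.max(maf)]
  e <- 0.05
  sim <- simulate_spectra(g, effects = effect_spec(snp, 1400, 1500, e),
                          phytometer_frac = 0, seed = 12)
  m <- as.matrix(sim$spectra[-1])
  band <- rowMeans(m[, colnames(m) %in% as.character(1400:1500)])
  d0 <- band[g$dosages[, snp] == 0]
  d2 <- band[g$dosages[, snp] == 2]
  diff <- mean(d2) - mean(d0)
  se <- sqrt(var(d0) / length(d0) + var(d2) / length(d2))
  expect_lt(abs(diff - 2 * e), 3 * se)
})

test_that("phytometers carry environment but no SNP effects", {
  g <- small_genotypes(n_rils = 120, n_snps = 40, seed = 21)
  snp <- colnames(g$dosages)[1]
  sim <- simulate_spectra(g, effects = effect_spec(snp, 800, 900, 0.5),
                          phytometer_frac = 0.25, seed = 22)
  phyto <- sim$metadata$phytometer
  expect_gt(sum(phyto), 0)
  expect_identical(sim$truth$phytometer, sim$metadata$sample[phyto])
  expect_true(all(sim$metadata$MO[phyto] == "tester"))
  # reconstruct the planted genetic part: phytometer rows must show none
  m <- as.matrix(sim$spectra[-1])
  j <- match("850", colnames(m))
  load850 <- spectragwas:::latent_loadings(850)
  lvec <- as.numeric(load850) * sim$truth$latent_sd[colnames(load850)]
  planted <- m[, j] - rowSums(sim$truth$env_contrib) -
    as.numeric(sim$truth$latent_scores[, colnames(load850)] %*% lvec)
  # remove template + noise: dosage-2 non-phytometers sit ~1 unit above
  # dosage-0; phytometers sit with the dosage-0 group regardless of dosage
  hi_phyto <- phyto & g$dosages[, snp] == 2
  lo <- !phyto & g$dosages[, snp] == 0
  hi <- !phyto & g$dosages[, snp] == 2
  skip_condition <- sum(hi_phyto) == 0 || sum(hi) == 0 || sum(lo) == 0
  expect_false(skip_condition)
  expect_gt(mean(planted[hi]) - mean(planted[lo]), 0.5)
  expect_lt(abs(mean(planted[hi_phyto]) - mean(planted[lo])), 0.1)
})

test_that("simulate_spectra is deterministic and validates effects", {
  g <- small_genotypes(n_rils = 8, n_snps = 20)
  a <- simulate_spectra(g, seed = 5)
  b <- simulate_spectra(g, seed = 5)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$metadata, b$metadata)
  expect_error(effect_spec("x", 300, 500, 1), "400")
  expect_error(effect_spec("x", 500, 400, 1), "400")
  expect_error(simulate_spectra(g, effects = effect_spec("nope", 500, 600, 1)),
               "not found")
  expect_error(simulate_spectra(g, noise = rep(0, 5)), "2101")
})

test_that("truth variance fractions are coherent", {
  g <- small_genotypes(n_rils = 60, n_snps = 20)
  sim <- simulate_spectra(g, seed = 31)
  fr <- truth_variance_fractions(sim$truth, wavelengths = c(550, 1600))
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
  sums <- tapply(fr$fraction, fr$wavelength, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-10)
  expect_error(truth_variance_fractions(sim$truth, wavelengths = 300),
               "grid")
})

test_that("VCF round trip reproduces the simulated dosage matrix", {
  g <- small_genotypes(n_rils = 12, n_snps = 30)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  back <- read_genotypes(path)
  expect_identical(back$samples, g$samples)
  expect_identical(back$map$snp, g$map$snp)
  expect_equal(unname(back$dosages), unname(g$dosages) + 0)
})
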