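# Simulation of a multiparent (MAGIC-like) recombinant inbred line panel and
# of structured leaf reflectance spectra with planted genetic, environmental
# and noise components, plus a truth record so downstream stages can be tested
# against known ground truth.

#' Simulate founder haplotypes for a multiparent population
#'
#' Draws binary founder haplotypes for `n_snps` biallelic SNPs spread evenly
#' over `n_chrom` chromosomes. Founder alleles are drawn independently per SNP
#' (no founder phylogeny) with the alternate-allele frequency among founders
#' constrained to lie inside `maf_range` by construction.
#'
#' @param n_founders Number of founder lines (default 26).
#' @param n_snps Total number of SNPs across all chromosomes.
#' @param n_chrom Number of chromosomes (default 12).
#' @param maf_range Length-2 numeric in (0, 0.5]: allowed range of the
#'   alternate-allele frequency among founders.
#' @param chrom_length Chromosome length in bp used to place SNP positions.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `founder_haplotypes`: a list with `alleles`
#'   (founders x SNPs binary matrix), `map` (tibble: snp, chrom, pos),
#'   `n_founders` and `maf_range`.
#' @examples
#' f <- simulate_founders(n_founders = 4, n_snps = 20, n_chrom = 2, seed = 1)
#' colMeans(f$alleles)
#' @export
simulate_founders <- function(n_founders = 26, n_snps = 1000, n_chrom = 12,
                              maf_range = c(0.1, 0.5), chrom_length = 2.5e8,
                              seed = 1L) {
  if (n_founders < 2) abort("n_founders must be >= 2")
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("maf_range must lie within (0, 0.5] with lo <= hi")
  }
  klo <- max(1L, as.integer(ceiling(maf_range[1] * n_founders - 1e-9)))
  khi <- as.integer(floor(maf_range[2] * n_founders + 1e-9))
  if (khi < klo) {
    abort("maf_range too narrow: no allele count attainable with this n_founders")
  }
  with_seed(seed, {
    per_chrom <- diff(round(seq(0, n_snps, length.out = n_chrom + 1)))
    map <- purrr::map_dfr(seq_len(n_chrom), function(cc) {
      nc <- per_chrom[cc]
      if (nc == 0L) return(tibble())
      pos <- sort(sample.int(chrom_length, nc))
      tibble(chrom = paste0("chr", cc), pos = pos)
    })
    map$snp <- paste0(map$chrom, "_", map$pos)
    m <- nrow(map)
    q <- runif(m, maf_range[1], maf_range[2])
    k <- pmin(pmax(as.integer(round(q * n_founders)), klo), khi)
    alleles <- matrix(0L, n_founders, m,
                      dimnames = list(paste0("F", seq_len(n_founders)), map$snp))
    for (j in seq_len(m)) {
      alleles[sample.int(n_founders, k[j]), j] <- 1L
    }
    structure(
      list(alleles = alleles,
           map = map[, c("snp", "chrom", "pos")],
           n_founders = n_founders, maf_range = maf_range, seed = seed),
      class = "founder_haplotypes"
    )
  })
}

# One meiotic product from a pair of haplotype vectors over one chromosome:
# Poisson-many crossovers at uniform positions, alternating source haplotype.
recombine_pair <- function(h1, h2, pos, crossovers) {
  n_x <- rpois(1L, crossovers)
  use_first <- runif(1) < 0.5
  if (n_x == 0L) return(if (use_first) h1 else h2)
  brk <- sort(runif(n_x, min(pos), max(pos)))
  seg <- findInterval(pos, brk)        # 0..n_x, alternates haplotype
  take1 <- (seg %% 2L == 0L) == use_first
  out <- h2
  out[take1] <- h1[take1]
  out
}

# A founder-mosaic gamete over one chromosome.
mosaic_gamete <- function(alleles_chr, pos, crossovers) {
  n_f <- nrow(alleles_chr)
  n_x <- rpois(1L, crossovers)
  brk <- if (n_x > 0L) sort(runif(n_x, min(pos), max(pos))) else numeric()
  seg <- findInterval(pos, brk) + 1L
  donors <- sample.int(n_f, n_x + 1L, replace = TRUE)
  alleles_chr[cbind(donors[seg], seq_along(pos))]
}

#' Simulate recombinant inbred lines from founder haplotypes
#'
#' Each line starts from two independent founder-mosaic gametes (an
#' approximation of the multiparent funnel) and is then selfed for
#' `selfing_generations` generations with explicit Poisson recombination, so
#' expected heterozygosity halves each generation.
#'
#' @param founders A `founder_haplotypes` object.
#' @param n_rils Number of inbred lines to simulate.
#' @param crossovers_per_chrom Mean crossovers per chromosome per meiosis.
#' @param selfing_generations Number of selfing generations (default 6).
#' @param seed Integer seed.
#' @return An object of class `genotype_matrix`: list with `dosages`
#'   (samples x SNPs, additive 0/1/2), `map` (tibble: snp, chrom, pos) and
#'   `samples`.
#' @export
simulate_rils <- function(founders, n_rils, crossovers_per_chrom = 1,
                          selfing_generations = 6, seed = 1L) {
  stopifnot(inherits(founders, "founder_haplotypes"))
  if (n_rils < 1) abort("n_rils must be >= 1")
  if (selfing_generations < 0) abort("selfing_generations must be >= 0")
  map <- founders$map
  chroms <- unique(map$chrom)
  idx_by_chrom <- split(seq_len(nrow(map)), factor(map$chrom, levels = chroms))
  samples <- sprintf("RIL%04d", seq_len(n_rils))
  m <- nrow(map)
  with_seed(seed, {
    dosages <- matrix(0L, n_rils, m, dimnames = list(samples, map$snp))
    for (i in seq_len(n_rils)) {
      for (cc in chroms) {
        idx <- idx_by_chrom[[cc]]
        pos <- map$pos[idx]
        ac <- founders$alleles[, idx, drop = FALSE]
        h1 <- mosaic_gamete(ac, pos, crossovers_per_chrom)
        h2 <- mosaic_gamete(ac, pos, crossovers_per_chrom)
        g <- 0L
        while (g < selfing_generations) {
          g1 <- recombine_pair(h1, h2, pos, crossovers_per_chrom)
          g2 <- recombine_pair(h1, h2, pos, crossovers_per_chrom)
          h1 <- g1; h2 <- g2
          g <- g + 1L
        }
        dosages[i, idx] <- h1 + h2
      }
    }
    structure(
      list(dosages = dosages, map = map, samples = samples,
           n_founders = founders$n_founders, seed = seed),
      class = "genotype_matrix"
    )
  })
}

#' Mean per-sample heterozygosity of a genotype matrix
#' @param genotypes A `genotype_matrix` object.
#' @return Fraction of (sample, SNP) entries with dosage 1.
#' @export
heterozygosity <- function(genotypes) {
  mean(genotypes$dosages == 1L)
}

#' Analytic base leaf-reflectance template
#'
#' A fixed smooth curve with the canonical features of a green-leaf spectrum:
#' chlorophyll absorption wells near 450 and 680 nm, a green reflectance bump,
#' the red-edge rise at 700-750 nm, a near-infrared plateau, and water
#' absorption wells near 1450 and 1940 nm with declining shortwave infrared.
#'
#' @param wavelengths Integer nm grid (default 400:2500).
#' @return Numeric reflectance values (unitless, positive).
#' @export
spectral_template <- function(wavelengths = grid_default()) {
  wl <- wavelengths
  r <- 0.08 + 0.42 * stats::plogis((wl - 720) / 15) +
    0.05 * exp(-(wl - 550)^2 / (2 * 30^2)) -
    0.035 * exp(-(wl - 450)^2 / (2 * 30^2)) -
    0.045 * exp(-(wl - 680)^2 / (2 * 22^2)) -
    0.16 * exp(-(wl - 1450)^2 / (2 * 60^2)) -
    0.25 * exp(-(wl - 1940)^2 / (2 * 90^2)) -
    0.12 * stats::plogis((wl - 2100) / 180)
  pmax(r, 0.01)
}

# Latent-factor loading profiles (max 1), one per leaf property axis.
latent_loadings <- function(wavelengths = grid_default()) {
  wl <- wavelengths
  norm1 <- function(x) x / max(x)
  cbind(
    pigment    = norm1(exp(-(wl - 550)^2 / (2 * 90^2)) * stats::plogis((740 - wl) / 12)),
    structure  = norm1(stats::plogis((wl - 705) / 12) * stats::plogis((1350 - wl) / 40)),
    water      = norm1(exp(-(wl - 1450)^2 / (2 * 90^2)) +
                         exp(-(wl - 1940)^2 / (2 * 110^2))),
    dry_matter = norm1(exp(-(wl - 2120)^2 / (2 * 260^2)) * stats::plogis((wl - 1450) / 60))
  )
}

#' Wavelength-dependent measurement-noise standard deviation profile
#'
#' Baseline noise with elevated values at the blue end and the far shortwave
#' infrared, mimicking detector signal-to-noise behaviour.
#'
#' @param wavelengths Integer nm grid.
#' @param base Baseline noise SD in reflectance units.
#' @return Numeric SD per wavelength.
#' @export
noise_profile <- function(wavelengths = grid_default(), base = 0.003) {
  wl <- wavelengths
  base + 0.004 * exp(-(wl - 400)^2 / (2 * 60^2)) +
    0.005 * exp(-(wl - 2500)^2 / (2 * 120^2))
}

#' Specify planted SNP effects and latent-factor scales for spectra simulation
#'
#' @param snp Character vector of causal SNP ids (matching the genotype map).
#' @param lo,hi Numeric vectors: affected wavelength band bounds in nm.
#' @param effect Numeric vector: per-allele effect in reflectance units.
#' @param latent_sd Named numeric: SDs of per-sample latent factor scores for
#'   the pigment, structure, water and dry-matter axes (reflectance units at
#'   the loading maximum).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(snp = character(), lo = numeric(), hi = numeric(),
                        effect = numeric(),
                        latent_sd = c(pigment = 0.020, structure = 0.020,
                                      water = 0.020, dry_matter = 0.020)) {
  causal <- tibble(snp = as.character(snp), lo = as.numeric(lo),
                   hi = as.numeric(hi), effect = as.numeric(effect))
  if (nrow(causal) > 0) {
    if (any(causal$lo < 400 | causal$hi > 2500 | causal$lo > causal$hi)) {
      abort("causal bands must lie within [400, 2500] nm with lo <= hi")
    }
    if (any(!is.finite(causal$effect))) abort("effect sizes must be finite")
  }
  structure(list(causal = causal, latent_sd = latent_sd), class = "effect_spec")
}

# Names and order of the environmental terms used throughout.
env_terms <- function() {
  c("LN", "REP", "BA", "LN:REP", "LN:BA", "DT", "CT", "DT:CT", "MO")
}

#' Environmental design for spectra simulation
#'
#' Factor level counts and per-term effect SDs for the measurement-technique
#' (LN), replicate (REP), spatial patch (BA), temporal (DT, CT) and maternal
#' origin (MO) terms, plus the LN:REP, LN:BA and DT:CT interactions. Effects
#' are drawn as independent Gaussian level effects and applied uniformly
#' across the spectrum.
#'
#' @param levels Named integer vector of level counts for LN, REP, DT, CT, MO
#'   (BA level count is set by the patch layout at simulation time).
#' @param sd Named numeric vector of per-term effect SDs (reflectance units).
#' @return An object of class `env_design`.
#' @export
env_design <- function(levels = c(LN = 2, REP = 2, DT = 4, CT = 3, MO = 26),
                       sd = c(LN = 0.008, REP = 0.004, BA = 0.006,
                              `LN:REP` = 0.002, `LN:BA` = 0.002,
                              DT = 0.004, CT = 0.003, `DT:CT` = 0.002,
                              MO = 0.003)) {
  lv <- c(LN = 2, REP = 2, DT = 4, CT = 3, MO = 26)
  lv[names(levels)] <- levels
  s <- setNames(rep(0, length(env_terms())), env_terms())
  s[names(sd)] <- sd
  structure(list(levels = lv, sd = s), class = "env_design")
}

#' Simulate leaf reflectance spectra with planted structure
#'
#' Builds per-sample spectra on the 400-2500 nm 1-nm grid as the sum of the
#' analytic base template, latent leaf-property factors, planted SNP effects
#' on contiguous wavelength bands, Gaussian environmental level effects and
#' wavelength-dependent noise. A configurable fraction of samples act as
#' phytometers: a single tester genotype interspersed in the patch layout,
#' whose SNP effects are zeroed while environmental draws are shared.
#'
#' @param genotypes A `genotype_matrix`; its rows define the sample set.
#' @param effects An `effect_spec` (default: no causal SNPs, default latent
#'   factor SDs).
#' @param env An `env_design`.
#' @param noise Numeric SD per wavelength (length 2101) or NULL for
#'   [noise_profile()].
#' @param phytometer_frac Fraction of samples used as phytometers; placed one
#'   (or more) per 2x2 patch.
#' @param seed Integer seed.
#' @return List with `spectra` (wide tibble), `metadata` (tibble of factors
#'   plus `phytometer`), and `truth` (class `truth_record`: the planted
#'   components, per-sample environmental contributions, latent scores, noise
#'   SD profile and seed).
#' @export
simulate_spectra <- function(genotypes, effects = effect_spec(),
                             env = env_design(), noise = NULL,
                             phytometer_frac = 0.25, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(effects, "effect_spec"), inherits(env, "env_design"))
  wl <- grid_default()
  p <- length(wl)
  n <- nrow(genotypes$dosages)
  samples <- rownames(genotypes$dosages)
  if (!is.null(noise)) {
    if (length(noise) != p) abort("noise SD profile must have length 2101")
    noise_sd <- as.numeric(noise)
  } else {
    noise_sd <- noise_profile(wl)
  }
  causal <- effects$causal
  if (nrow(causal) > 0 && !all(causal$snp %in% colnames(genotypes$dosages))) {
    abort("causal SNP ids not found in genotype matrix")
  }
  with_seed(seed, {
    # patch layout: 2x2 planting squares
    n_patch <- ceiling(n / 4)
    patch <- rep(seq_len(n_patch), each = 4, length.out = n)[sample.int(n)]
    n_phyto_per_patch <- phytometer_frac * 4
    phyto <- logical(n)
    for (pp in seq_len(n_patch)) {
      members <- which(patch == pp)
      k <- min(length(members), round(n_phyto_per_patch))
      if (k > 0) phyto[sample(members, k)] <- TRUE
    }
    lv <- env$levels
    meta <- tibble(
      sample = samples,
      LN = paste0("LN", sample.int(lv[["LN"]], n, replace = TRUE)),
      REP = paste0("R", 1L + as.integer(patch > n_patch / 2)),
      BA = sprintf("P%03d", patch),
      DT = paste0("D", sample.int(lv[["DT"]], n, replace = TRUE)),
      CT = paste0("T", sample.int(lv[["CT"]], n, replace = TRUE)),
      MO = ifelse(phyto, "tester",
                  paste0("M", sample.int(lv[["MO"]], n, replace = TRUE))),
      phytometer = phyto
    )
    # per-term Gaussian level effects -> per-sample scalar contributions
    sds <- env$sd
    level_key <- list(
      LN = meta$LN, REP = meta$REP, BA = meta$BA,
      `LN:REP` = paste(meta$LN, meta$REP, sep = ":"),
      `LN:BA` = paste(meta$LN, meta$BA, sep = ":"),
      DT = meta$DT, CT = meta$CT,
      `DT:CT` = paste(meta$DT, meta$CT, sep = ":"),
      MO = meta$MO
    )
    env_contrib <- vapply(env_terms(), function(tm) {
      key <- level_key[[tm]]
      lev <- unique(key)
      eff <- rnorm(length(lev), 0, sds[[tm]])
      eff[match(key, lev)]
    }, numeric(n))
    # latent leaf-property factors
    load <- latent_loadings(wl)
    lsd <- effects$latent_sd
    scores <- matrix(rnorm(n * ncol(load)), n, ncol(load),
                     dimnames = list(samples, colnames(load)))
    latent_part <- scores %*% (t(load) * lsd[colnames(load)])
    # planted SNP effects on bands, zeroed for phytometers
    genetic_part <- matrix(0, n, p)
    if (nrow(causal) > 0) {
      for (i in seq_len(nrow(causal))) {
        band <- wl >= causal$lo[i] & wl <= causal$hi[i]
        dos <- genotypes$dosages[, causal$snp[i]]
        dos[phyto] <- 0
        genetic_part[, band] <- genetic_part[, band] + dos * causal$effect[i]
      }
    }
    noise_part <- sweep(matrix(rnorm(n * p), n, p), 2L, noise_sd, "*")
    y <- matrix(spectral_template(wl), n, p, byrow = TRUE) +
      latent_part + genetic_part +
      rowSums(env_contrib) + noise_part
    dimnames(y) <- list(samples, as.character(wl))
    truth <- structure(
      list(causal = causal, latent_sd = lsd, latent_scores = scores,
           env_sd = sds, env_contrib = env_contrib,
           noise_sd = noise_sd, phytometer = samples[phyto],
           wavelengths = wl, seed = seed),
      class = "truth_record"
    )
    list(spectra = matrix_to_spectra(y), metadata = meta, truth = truth)
  })
}

#' Planted per-term variance fractions at given wavelengths
#'
#' Computes, from a truth record, the realized variance of each planted
#' component (environmental terms, latent factors + causal effects, noise) at
#' the requested wavelengths and returns them as fractions of the total.
#' Fractions are in `[0, 1]` and the non-residual ones sum to less than 1.
#'
#' @param truth A `truth_record` from [simulate_spectra()].
#' @param wavelengths Wavelengths (nm) at which to evaluate.
#' @return Tibble: wavelength, term, fraction. Terms are the environmental
#'   terms plus `residual` (latent + noise).
#' @export
truth_variance_fractions <- function(truth, wavelengths = c(550, 1000, 1600, 2200)) {
  stopifnot(inherits(truth, "truth_record"))
  load <- latent_loadings(truth$wavelengths)
  purrr::map_dfr(wavelengths, function(w) {
    j <- match(w, truth$wavelengths)
    if (is.na(j)) abort("wavelength outside simulated grid")
    env_var <- apply(truth$env_contrib, 2, var)
    resid_var <- sum((truth$latent_sd[colnames(load)] * load[j, ])^2) +
      truth$noise_sd[j]^2
    tot <- sum(env_var) + resid_var
    tibble(wavelength = w,
           term = c(colnames(truth$env_contrib), "residual"),
           fraction = c(env_var, resid_var) / tot)
  })
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Unphased diploid GT records, one pseudo-chromosome per simulated
#' chromosome, 1-based positions, REF=A ALT=T placeholders.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  gt_codes <- c("0/0", "0/1", "1/1")
  map <- genotypes$map
  body <- vapply(seq_len(nrow(map)), function(j) {
    gts <- gt_codes[genotypes$dosages[, j] + 1L]
    paste(c(map$chrom[j], map$pos[j], map$snp[j], "A", "T", ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=spectragwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write simulation metadata as TSV
#' @param metadata Metadata tibble from [simulate_spectra()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Write a truth record as structured text (JSON)
#' @param truth A `truth_record`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " SNPs over ", length(unique(x$map$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record> ", nrow(x$env_contrib), " samples, ",
      nrow(x$causal), " causal SNPs, ", length(x$phytometer),
      " phytometers, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
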