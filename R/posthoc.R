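# Multiple-testing machinery: windowed LD scores, cross-trait LD score
# regression intercepts as phenotypic correlations (PhenoSpD), the effective
# number of independent tests from the eigenvalues of that correlation
# matrix, Benjamini-Hochberg FDR, the top-k dynamic-threshold comparison,
# and candidate-gene windows from GFF3 annotation.

#' Windowed LD scores
#'
#' For each SNP, the sum of squared Pearson correlations with all SNPs within
#' `window_bp` on the same chromosome, self included (so every score is at
#' least 1).
#'
#' @param genotypes A `genotype_matrix`.
#' @param window_bp Window half-width in bp (default 1 Mb); 0 gives
#'   self-only scores of 1.
#' @return Tibble: snp, chrom, pos, ldscore.
#' @export
ld_scores <- function(genotypes, window_bp = 1e6) {
  map <- genotypes$map
  z <- standardize_cols(genotypes$dosages)
  n <- nrow(z)
  out <- numeric(nrow(map))
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    pos <- map$pos[idx]
    zc <- z[, idx, drop = FALSE]
    for (a in seq_along(idx)) {
      lo <- findInterval(pos[a] - window_bp, pos, left.open = TRUE) + 1L
      hi <- findInterval(pos[a] + window_bp, pos)
      r <- as.numeric(crossprod(zc[, lo:hi, drop = FALSE], zc[, a])) / (n - 1)
      self_zero <- sd(zc[, a]) == 0
      out[idx[a]] <- if (self_zero) 1 else sum(r^2) - r[a - lo + 1L]^2 + 1
    }
  }
  tibble(snp = map$snp, chrom = map$chrom, pos = map$pos, ldscore = out)
}

# Project a symmetric matrix to the nearest positive semidefinite correlation
# matrix (eigenvalue clipping + unit-diagonal rescale).
psd_correlation <- function(m) {
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)
  if (min(es$values) < -1e-10) {
    v <- pmax(es$values, 0)
    m <- es$vectors %*% (t(es$vectors) * v)
    m <- stats::cov2cor(m)
  }
  m
}

#' Phenotypic correlation matrix from GWAS summary statistics (PhenoSpD)
#'
#' For every trait pair, regresses the product of the two traits' per-SNP
#' z scores on the SNP LD score; the regression intercept estimates the
#' phenotypic correlation between the traits. The matrix is symmetrized,
#' clamped to `[-1, 1]`, given a unit diagonal and projected to the nearest
#' positive semidefinite correlation matrix before eigendecomposition.
#'
#' @param zscores Data frame: `snp` column plus one numeric z-score column
#'   per trait (shared SNP panel), or a SNPs x traits matrix.
#' @param ld Tibble from [ld_scores()] (or any data frame with `snp`,
#'   `ldscore`).
#' @return An object of class `pheno_correlation`: list with `correlation`
#'   (traits x traits), `eigenvalues`, `source` (`"ldsc-intercept"`).
#' @export
phenospd_correlation <- function(zscores, ld) {
  if (is.data.frame(zscores)) {
    snp <- as.character(zscores$snp)
    z <- as.matrix(zscores[setdiff(names(zscores), "snp")])
    rownames(z) <- snp
  } else {
    z <- as.matrix(zscores)
  }
  if (nrow(z) < 50) abort("PhenoSpD needs at least 50 SNPs")
  l <- ld$ldscore[match(rownames(z), as.character(ld$snp))]
  if (anyNA(l)) abort("LD scores missing for some SNPs")
  keep <- stats::complete.cases(z) & is.finite(l)
  z <- z[keep, , drop = FALSE]
  l <- l[keep]
  m <- nrow(z)
  b_means <- crossprod(z) / m                     # mean of Z1*Z2 per pair
  if (var(l) < 1e-12) {
    warn("constant LD scores; using mean cross-trait z product as correlation")
    corr <- b_means
  } else {
    a_means <- crossprod(z, z * l) / m            # mean of Z1*Z2*L per pair
    slope <- (a_means - b_means * mean(l)) / (mean(l^2) - mean(l)^2)
    corr <- b_means - slope * mean(l)
  }
  corr <- pmin(pmax((corr + t(corr)) / 2, -1), 1)
  diag(corr) <- 1
  corr <- psd_correlation(corr)
  structure(
    list(correlation = corr,
         eigenvalues = eigen(corr, symmetric = TRUE, only.values = TRUE)$values,
         source = "ldsc-intercept"),
    class = "pheno_correlation"
  )
}

#' Phenotypic correlation matrix computed directly from phenotype values
#'
#' Companion to [phenospd_correlation()] for when the phenotypes themselves
#' are at hand rather than only summary statistics.
#'
#' @param phenotypes Data frame: `sample` plus numeric trait columns.
#' @return A `pheno_correlation` with source `"direct"`.
#' @export
direct_correlation <- function(phenotypes) {
  m <- as.matrix(phenotypes[setdiff(names(phenotypes), "sample")])
  corr <- psd_correlation(cor(m))
  structure(
    list(correlation = corr,
         eigenvalues = eigen(corr, symmetric = TRUE, only.values = TRUE)$values,
         source = "direct"),
    class = "pheno_correlation"
  )
}

#' @export
print.pheno_correlation <- function(x, ...) {
  cat("<pheno_correlation> ", ncol(x$correlation), " traits (source: ",
      x$source, "), Meff(spd) = ", round(meff(x), 2), "\n", sep = "")
  invisible(x)
}

#' Effective number of independent tests from a trait correlation matrix
#'
#' Default `"spd"` is the participation ratio of the eigenvalues,
#' \eqn{(\sum_i \lambda_i)^2 / \sum_i \lambda_i^2}: equal to the trait count
#' for uncorrelated traits and 1 for perfectly correlated traits.
#' `"nyholt"` and `"liji"` are the classical alternatives.
#'
#' @param corr A `pheno_correlation`, or a correlation matrix.
#' @param method `"spd"`, `"nyholt"` or `"liji"`.
#' @return The effective test count (between 1 and the trait count).
#' @export
meff <- function(corr, method = c("spd", "nyholt", "liji")) {
  method <- match.arg(method)
  if (inherits(corr, "pheno_correlation")) {
    lam <- corr$eigenvalues
  } else {
    m <- psd_correlation(as.matrix(corr))
    lam <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  }
  lam <- pmax(lam, 0)
  M <- length(lam)
  switch(method,
         spd = sum(lam)^2 / sum(lam^2),
         nyholt = 1 + (M - 1) * (1 - var(lam) / M),
         liji = sum(as.numeric(lam >= 1) + (lam - floor(lam))))
}

#' Multiple-testing significance threshold from an effective test count
#' @param meff_value Effective number of independent tests (>= 1).
#' @param alpha Family-wise alpha (default 0.05).
#' @return `alpha / meff_value`.
#' @export
significance_threshold <- function(meff_value, alpha = 0.05) {
  if (meff_value < 1) abort("meff_value must be >= 1")
  alpha / meff_value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, applied per
#' phenotype across all SNPs.
#'
#' @param pvalues Numeric p values in (0, 1].
#' @return Adjusted p values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1))) {
    abort("p values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Rank SNPs by minimum p and apply the top-k dynamic threshold
#'
#' SNPs are ranked by their minimum p value across all supplied phenotypes
#' (and models); the p value of the k-th ranked SNP becomes a dynamic,
#' method-specific exploratory threshold, and every (SNP, phenotype)
#' association at or below it is returned. Ties at rank k are broken by
#' (chromosome, position) for determinism, with all tied SNPs retained in
#' the ranking report.
#'
#' @param results Association tibble (as from [glm_scan()] / [mlm_scan()]):
#'   columns snp, chrom, pos, phenotype, p (model optional).
#' @param k Number of top unique SNPs (default 50).
#' @return List of class `topk_report`: `ranking` (tibble snp, chrom, pos,
#'   min_p, rank), `threshold`, `passing` (all associations with
#'   `p <= threshold`).
#' @export
top_k_dynamic <- function(results, k = 50) {
  ranking <- results |>
    dplyr::filter(is.finite(.data$p)) |>
    dplyr::group_by(.data$snp, .data$chrom, .data$pos) |>
    dplyr::summarise(min_p = min(.data$p), .groups = "drop") |>
    dplyr::arrange(.data$min_p, .data$chrom, .data$pos) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (nrow(ranking) < k) abort("fewer unique SNPs than k")
  threshold <- ranking$min_p[k]
  passing <- dplyr::filter(results, is.finite(.data$p), .data$p <= threshold)
  structure(list(ranking = ranking, threshold = threshold, passing = passing),
            class = "topk_report")
}

#' @export
print.topk_report <- function(x, ...) {
  cat("<topk_report> dynamic threshold p <= ",
      format(x$threshold, digits = 3), "; ",
      nrow(x$passing), " passing associations\n", sep = "")
  invisible(x)
}

#' Overlap between two top-k SNP sets
#' @param a,b `topk_report` objects or character vectors of SNP ids.
#' @param k Number of top SNPs compared (default 50).
#' @return Tibble: n_shared, k, percent.
#' @export
topk_overlap <- function(a, b, k = 50) {
  ids <- function(x) if (inherits(x, "topk_report")) head(x$ranking$snp, k) else head(x, k)
  shared <- length(intersect(ids(a), ids(b)))
  tibble(n_shared = shared, k = k, percent = 100 * shared / k)
}

#' Candidate genes within a window of significant SNPs
#'
#' Extracts gene features from a GFF3 annotation whose span intersects
#' `[pos - window_bp, pos + window_bp]` around each SNP (inclusive at both
#' boundaries), optionally filtered to a whitelist of gene ids (e.g. genes
#' with transcript evidence in the tissue of interest). Distance is 0 for a
#' SNP inside the gene, otherwise base pairs to the nearest gene edge.
#'
#' @param snps Character vector of SNP ids in `chr<chrom>_<pos>` form.
#' @param gff_path GFF3 file with `gene` features.
#' @param window_bp Window half-width (default 100 kb).
#' @param whitelist Optional character vector of gene ids to keep.
#' @return Tibble: snp, gene_id, chrom, start, end, strand, annotation,
#'   distance.
#' @export
candidate_genes <- function(snps, gff_path, window_bp = 1e5, whitelist = NULL) {
  gff <- rtracklayer::import(gff_path)
  genes <- gff[gff$type == "gene"]
  parsed <- parse_snp_ids(snps)
  known <- parsed$chrom %in% as.character(GenomicRanges::seqnames(genes))
  if (any(!known)) {
    warn(paste0("skipping ", sum(!known), " SNP(s) on unknown chromosome(s)"))
    parsed <- parsed[known, , drop = FALSE]
  }
  if (nrow(parsed) == 0) {
    return(tibble(snp = character(), gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  annotation = character(), distance = integer()))
  }
  windows <- GenomicRanges::GRanges(
    parsed$chrom,
    IRanges::IRanges(pmax(1L, parsed$pos - as.integer(window_bp)),
                     parsed$pos + as.integer(window_bp))
  )
  hits <- GenomicRanges::findOverlaps(windows, genes)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  g <- genes[si]
  gene_id <- as.character(g$ID %||% g$gene_id %||% g$Name)
  ann <- if (!is.null(g$description)) as.character(g$description) else
    if (!is.null(g$Note)) as.character(g$Note) else NA_character_
  pos <- parsed$pos[qi]
  st <- GenomicRanges::start(g)
  en <- GenomicRanges::end(g)
  dist <- pmax(0L, pmax(st - pos, pos - en))
  out <- tibble(
    snp = parsed$snp[qi], gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = st, end = en,
    strand = as.character(GenomicRanges::strand(g)),
    annotation = ann, distance = as.integer(dist)
  )
  if (!is.null(whitelist)) out <- dplyr::filter(out, .data$gene_id %in% whitelist)
  out
}

parse_snp_ids <- function(snps) {
  m <- regmatches(snps, regexec("^(.+)_([0-9]+)$", snps))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) abort("SNP ids must be of the form chr<chrom>_<pos>")
  tibble(snp = snps,
         chrom = vapply(m, `[`, character(1), 2L),
         pos = as.integer(vapply(m, `[`, character(1), 3L)))
}

#' Significance calls combining FDR adjustment and the Meff threshold
#'
#' An association is called significant when its Benjamini-Hochberg adjusted
#' p value (computed per phenotype) falls below `alpha / Meff`.
#'
#' @param results Association tibble with snp, phenotype, p columns.
#' @param meff_value Effective number of independent traits.
#' @param alpha Family-wise alpha (default 0.05).
#' @return `results` with `p_adj`, `threshold` and `significant` columns.
#' @export
call_significant <- function(results, meff_value, alpha = 0.05) {
  thr <- significance_threshold(meff_value, alpha)
  results |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::mutate(p_adj = bh_fdr(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(threshold = thr, significant = .data$p_adj < thr)
}
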