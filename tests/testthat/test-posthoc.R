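make_scan_tibble <- function(snp, chrom, pos, phenotype, p, model = "GLM") {
  tibble::tibble(snp = snp, chrom = chrom, pos = pos, effect = 0, se = 1,
                 stat = 0, p = p, model = model, phenotype = phenotype)
}

test_that("ld_scores match closed-form cases", {
  # two perfectly correlated SNPs in one window score 2 each
  dos <- cbind(chr1_100 = c(0, 1, 2, 0, 2, 1, 0, 2),
               chr1_200 = c(0, 1, 2, 0, 2, 1, 0, 2),
               chr2_100 = c(2, 0, 1, 2, 0, 1, 2, 0))
  rownames(dos) <- paste0("S", 1:8)
  g <- structure(list(dosages = dos,
                      map = tibble::tibble(snp = colnames(dos),
                                           chrom = c("chr1", "chr1", "chr2"),
                                           pos = c(100L, 200L, 100L)),
                      samples = rownames(dos)), class = "genotype_matrix")
  ld <- ld_scores(g)
  expect_equal(ld$ldscore[1:2], c(2, 2), tolerance = 1e-12)
  expect_equal(ld$ldscore[3], 1, tolerance = 1e-12)  # single-SNP chromosome
  # window 0 -> all self-only
  expect_equal(ld_scores(g, window_bp = 0)$ldscore, rep(1, 3))
})

test_that("independent SNPs score near the finite-sample noise floor", {
  set.seed(18)
  n <- 200
  m <- 60
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  colnames(dos) <- paste0("chr1_", seq_len(m) * 10)
  rownames(dos) <- sprintf("S%03d", seq_len(n))
  g <- structure(list(dosages = dos,
                      map = tibble::tibble(snp = colnames(dos), chrom = "chr1",
                                           pos = seq_len(m) * 10L),
                      samples = rownames(dos)), class = "genotype_matrix")
  ld <- ld_scores(g)
  expected <- 1 + (m - 1) / (n - 1)       # E[r^2] = 1/(n-1) under the null
  se <- sqrt(m - 1) * sqrt(2) / (n - 1) / sqrt(m)  # rough per-score spread
  expect_lt(abs(mean(ld$ldscore) - expected), 3 * se + 0.02)
})

test_that("phenospd intercepts estimate phenotypic correlation", {
  set.seed(19)
  m <- 2000
  ld <- tibble::tibble(snp = paste0("chr1_", 1:m),
                       ldscore = runif(m, 1, 6))
  # duplicated trait: product Z^2 has intercept ~ 1 under the null
  z1 <- rnorm(m)
  zs <- tibble::tibble(snp = ld$snp, a = z1, b = z1, c = rnorm(m))
  pc <- phenospd_correlation(zs, ld)
  expect_equal(dim(pc$correlation), c(3L, 3L))
  expect_equal(pc$correlation["a", "b"], 1, tolerance = 0.1)
  expect_lt(abs(pc$correlation["a", "c"]), 3 / sqrt(m) * 3)
  expect_identical(pc$source, "ldsc-intercept")
  # constant LD scores fall back with a warning
  ld_const <- dplyr::mutate(ld, ldscore = 2)
  expect_warning(pc2 <- phenospd_correlation(zs, ld_const), "constant LD")
  expect_equal(pc2$correlation["a", "b"], 1, tolerance = 0.1)
  expect_error(phenospd_correlation(zs[1:10, ], ld), "50")
})

test_that("direct and summary-statistic correlation modes agree", {
  # independent (unstructured) SNPs, but with a position layout that
  # identifies the regression intercept: chr1 packs 750 SNPs into one LD
  # window (chance LD pushes those scores well above 1) while chr2 spaces
  # its SNPs beyond the window (scores anchored at exactly 1). Putting all
  # SNPs into one shared window instead would give every SNP the same
  # score, and the intercept would be a long extrapolation with variance
  # that does not shrink with the SNP count.
  set.seed(20)
  n <- 150
  m <- 1500
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  colnames(dos) <- c(paste0("chr1_", 1:750), paste0("chr2_", (1:750) * 2e6))
  rownames(dos) <- sprintf("S%03d", seq_len(n))
  g <- structure(list(dosages = dos,
                      map = tibble::tibble(
                        snp = colnames(dos),
                        chrom = rep(c("chr1", "chr2"), each = 750),
                        pos = c(1:750, (1:750) * 2e6)),
                      samples = rownames(dos)), class = "genotype_matrix")
  f <- rnorm(n)
  phen <- tibble::tibble(sample = g$samples,
                         t1 = f + rnorm(n, sd = 0.6),
                         t2 = f + rnorm(n, sd = 0.6),
                         t3 = rnorm(n))
  res <- glm_scan(phen, g)
  z <- res |>
    dplyr::transmute(snp, phenotype, z = stat) |>
    tidyr::pivot_wider(names_from = phenotype, values_from = z)
  pc_ld <- phenospd_correlation(z, ld_scores(g))
  pc_dir <- direct_correlation(phen)
  expect_lt(max(abs(pc_ld$correlation - pc_dir$correlation)), 0.15)
})

test_that("meff closed forms and bounds hold", {
  expect_equal(meff(diag(7)), 7, tolerance = 1e-12)
  expect_equal(meff(matrix(1, 5, 5)), 1, tolerance = 1e-12)
  expect_equal(meff(matrix(c(1, .5, .5, 1), 2)), 4 / 2.5, tolerance = 1e-12)
  # bounds on random PSD correlation matrices
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 6), 40, 6)
    cm <- stats::cor(x)
    for (meth in c("spd", "nyholt", "liji")) {
      v <- meff(cm, method = meth)
      expect_gte(v, 1 - 1e-9)
      expect_lte(v, 6 + 1e-9)
    }
  }
})

test_that("significance thresholds follow alpha / Meff", {
  expect_equal(significance_threshold(5.0), 0.01)
  expect_equal(signif(significance_threshold(999.9), 3), 5.00e-5)
  expect_equal(significance_threshold(1), 0.05)
  expect_error(significance_threshold(0.5), ">= 1")
})

test_that("bh_fdr matches hand values and the brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(22)
  for (i in 1:20) {
    p <- runif(sample(1:20, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("top_k_dynamic ranks by min p and applies the threshold", {
  res <- make_scan_tibble(
    snp = rep(paste0("chr1_", 1:6 * 10), each = 2),
    chrom = "chr1", pos = rep(1:6 * 10L, each = 2),
    phenotype = rep(c("a", "b"), 6),
    p = c(.001, .5, .002, .003, .9, .004, .05, .06, .7, .8, .0005, .9))
  tk <- top_k_dynamic(res, k = 3)
  expect_equal(tk$ranking$snp[1:3], c("chr1_60", "chr1_10", "chr1_20"))
  expect_equal(tk$threshold, 0.002)
  expect_true(all(tk$passing$p <= 0.002))
  # k = 1: threshold is the global minimum
  tk1 <- top_k_dynamic(res, k = 1)
  expect_equal(tk1$threshold, min(res$p))
  # stripe behaviour: one SNP significant for many phenotypes
  stripe <- make_scan_tibble(
    snp = c(rep("chr2_5", 10), paste0("chr2_", 1:9 * 100)),
    chrom = "chr2", pos = c(rep(5L, 10), 1:9 * 100L),
    phenotype = c(paste0("ph", 1:10), rep("ph1", 9)),
    p = c(rep(1e-6, 10), seq(0.1, 0.9, by = 0.1)))
  tks <- top_k_dynamic(stripe, k = 2)
  expect_equal(sum(tks$passing$snp == "chr2_5"), 10)
  # monotone in k
  counts <- vapply(2:6, function(k) nrow(top_k_dynamic(res, k)$passing),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(top_k_dynamic(res, k = 50), "fewer")
})

test_that("topk_overlap reports shared fractions", {
  a <- paste0("chr1_", 1:50)
  b <- c(paste0("chr1_", 1:42), paste0("chr9_", 1:8))
  ov <- topk_overlap(a, b, k = 50)
  expect_equal(ov$n_shared, 42L)
  expect_equal(ov$percent, 84)
})

test_that("candidate_genes matches interval arithmetic and the oracle", {
  genes <- tibble::tibble(
    gene_id = paste0("G", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(200001L, 150000L, 50000L, 400000L, 90000L),
    end = c(210000L, 160000L, 60000L, 410000L, 95000L),
    strand = c("+", "-", "+", "-", "+"))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff(genes, gff)
  # boundary: gene at [200001, 210000], window 100 kb
  out_100k <- candidate_genes("chr1_100000", gff, window_bp = 1e5)
  expect_false("G1" %in% out_100k$gene_id)     # 200001 > 200000
  out_100k1 <- candidate_genes("chr1_100001", gff, window_bp = 1e5)
  expect_true("G1" %in% out_100k1$gene_id)
  # SNP inside a gene has distance 0
  inside <- candidate_genes("chr1_155000", gff, window_bp = 1e5)
  expect_equal(inside$distance[inside$gene_id == "G2"], 0L)
  # centered SNP picks exactly the 3 genes in range; matches the oracle
  cen <- candidate_genes("chr1_155000", gff, window_bp = 1e5)
  expect_setequal(cen$gene_id, c("G1", "G2", "G3"))
  orc <- oracle_genes("chr1_155000", genes, 1e5)
  expect_setequal(cen$gene_id, orc$gene_id)
  expect_equal(dplyr::arrange(cen, gene_id)$distance,
               dplyr::arrange(orc, gene_id)$distance)
  # whitelist filtering and unknown chromosomes
  wl <- candidate_genes("chr1_155000", gff, window_bp = 1e5,
                        whitelist = c("G2"))
  expect_identical(wl$gene_id, "G2")
  expect_warning(none <- candidate_genes("chrX_1000", gff), "unknown")
  expect_equal(nrow(none), 0L)
  expect_error(candidate_genes("badid", gff), "chr<chrom>_<pos>")
})

test_that("significance calls combine BH with the Meff threshold", {
  res <- make_scan_tibble(
    snp = paste0("chr1_", 1:4), chrom = "chr1", pos = 1:4 * 10L,
    phenotype = "ph1", p = c(1e-6, 0.002, 0.04, 0.9))
  calls <- call_significant(res, meff_value = 5, alpha = 0.05)
  expect_equal(calls$threshold, rep(0.01, 4))
  expect_identical(calls$significant, calls$p_adj < 0.01)
  expect_true(calls$significant[1])
  expect_false(calls$significant[4])
})
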