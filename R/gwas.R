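# Genotype input, kinship, and native association scans: per-SNP ordinary
# least squares (GLM) and an EMMA-style mixed linear model (MLM) with REML
# variance components estimated via the eigendecomposition of the kinship
# matrix, reused across SNPs (P3D) by default.

#' Read a VCF into an additive genotype matrix
#'
#' Dosage is the alternate-allele count per sample (0/1/2); missing genotypes
#' are imputed with the per-SNP mean dosage. Multi-allelic records are
#' skipped with a message. SNP ids are rebuilt as `chr<chrom>_<pos>`.
#'
#' @param vcf_path Path to a VCF file with GT fields.
#' @return A `genotype_matrix` (list: `dosages`, `map`, `samples`).
#' @export
read_genotypes <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    message("skipping ", sum(multi), " multi-allelic record(s)")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1")] <- 2
  if (anyNA(dos)) {
    mu <- rowMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 1]]
  }
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  chrom_id <- sub("^chr", "", chrom)
  map <- tibble(snp = paste0("chr", chrom_id, "_", pos),
                chrom = paste0("chr", chrom_id), pos = pos)
  dosages <- t(dos)
  colnames(dosages) <- map$snp
  structure(
    list(dosages = dosages, map = map, samples = rownames(dosages)),
    class = "genotype_matrix"
  )
}

#' Genomic kinship matrix from additive dosages
#'
#' `"vanraden"`: centered cross-product of dosages scaled by
#' \eqn{2\sum_j p_j(1-p_j)}. `"zhang"`: the same centered cross-product with
#' a mean-diagonal rescaling in the style of GAPIT's kinship (documented
#' approximation; the exact published rescaling constant is not available).
#'
#' @param genotypes A `genotype_matrix`.
#' @param method `"vanraden"` (default) or `"zhang"`.
#' @return Symmetric samples x samples matrix of class `matrix`.
#' @export
kinship <- function(genotypes, method = c("vanraden", "zhang")) {
  method <- match.arg(method)
  g <- genotypes$dosages
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) abort("kinship needs at least 2 polymorphic SNPs")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(g, 2L, 2 * p, "-")
  k <- tcrossprod(z)
  k <- switch(method,
              vanraden = k / (2 * sum(p * (1 - p))),
              zhang = {
                k0 <- k / (2 * sum(p * (1 - p)))
                k0 / mean(diag(k0))
              })
  (k + t(k)) / 2
}

# Coerce a phenotypes argument (tibble with sample + numeric columns) into a
# named list of aligned numeric vectors.
phenotype_columns <- function(phenotypes, samples) {
  stopifnot(is.data.frame(phenotypes), "sample" %in% names(phenotypes))
  idx <- match(samples, as.character(phenotypes$sample))
  if (anyNA(idx)) abort("phenotype table missing genotyped samples")
  cols <- setdiff(names(phenotypes), "sample")
  lapply(setNames(cols, cols), function(cn) as.numeric(phenotypes[[cn]][idx]))
}

scan_result_tibble <- function(map, effect, se, stat, p, model, phenotype) {
  tibble(snp = map$snp, chrom = map$chrom, pos = map$pos,
         effect = unname(effect), se = unname(se), stat = unname(stat),
         p = unname(p), model = model, phenotype = phenotype)
}

#' General linear model association scan
#'
#' Per SNP, ordinary least squares of the phenotype on an intercept, the
#' optional covariates, and the additive dosage, with a two-sided t test on
#' the dosage coefficient. Monomorphic SNPs are returned with missing
#' statistics.
#'
#' @param phenotypes Data frame: `sample` column plus one or more numeric
#'   phenotype columns (each scanned separately).
#' @param genotypes A `genotype_matrix`.
#' @param covariates Optional numeric matrix / data frame of per-sample
#'   covariates (aligned to the genotype samples by a `sample` column if
#'   present, otherwise by row order).
#' @return Tibble: snp, chrom, pos, effect, se, stat, p, model, phenotype.
#' @export
glm_scan <- function(phenotypes, genotypes, covariates = NULL) {
  g <- genotypes$dosages
  n <- nrow(g)
  x0 <- covariate_matrix(covariates, rownames(g))
  q0 <- ncol(x0)
  phen <- phenotype_columns(phenotypes, rownames(g))
  qx <- qr.Q(qr(x0))
  rg <- g - qx %*% crossprod(qx, g)
  gss <- colSums(rg^2)
  mono <- gss < 1e-10
  df <- n - q0 - 1L
  if (df < 1) abort("not enough samples for the requested model")
  purrr::map_dfr(names(phen), function(pn) {
    y <- phen[[pn]]
    if (any(!is.finite(y))) abort("phenotype values must be finite")
    ry <- y - qx %*% crossprod(qx, y)
    gy <- as.numeric(crossprod(rg, ry))
    beta <- ifelse(mono, NA_real_, gy / gss)
    rss <- sum(ry^2) - ifelse(mono, 0, beta^2 * gss)
    se <- sqrt(pmax(rss, 0) / df / gss)
    stat <- beta / se
    p <- 2 * pt(-abs(stat), df)
    p[!mono & stat == 0] <- 1
    scan_result_tibble(genotypes$map, beta, ifelse(mono, NA_real_, se),
                       stat, p, "GLM", pn)
  })
}

covariate_matrix <- function(covariates, samples) {
  n <- length(samples)
  if (is.null(covariates)) return(matrix(1, n, 1))
  if (is.data.frame(covariates)) {
    if ("sample" %in% names(covariates)) {
      idx <- match(samples, as.character(covariates$sample))
      if (anyNA(idx)) abort("covariate table missing genotyped samples")
      covariates <- covariates[idx, setdiff(names(covariates), "sample"), drop = FALSE]
    }
    covariates <- as.matrix(covariates)
  }
  if (nrow(covariates) != n) abort("covariates must have one row per sample")
  cbind(1, covariates)
}

# REML log-likelihood profile in delta = sigma_e^2 / sigma_g^2 on the rotated
# model (K = U diag(d) U').
reml_profile <- function(log_delta, d, ystar, xstar) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  xtw <- xstar * w
  xwx <- crossprod(xtw, xstar)
  beta <- solve(xwx, crossprod(xtw, ystar))
  r <- ystar - xstar %*% beta
  nq <- length(ystar) - ncol(xstar)
  rss <- sum(r^2 * w)
  -0.5 * (nq * log(rss / nq) + sum(log(d + delta)) +
            determinant(xwx, logarithm = TRUE)$modulus)
}

#' Mixed linear model association scan (EMMA-style REML, P3D)
#'
#' Variance components (genetic and residual) are estimated once by REML on
#' the null model through the eigendecomposition of the kinship matrix, then
#' reused for every SNP (P3D); each SNP is tested by generalized least
#' squares with a Wald t test. With `p3d = FALSE`, the variance ratio is
#' re-estimated per SNP. With an identity kinship, results collapse to the
#' GLM scan.
#'
#' @inheritParams glm_scan
#' @param K Samples x samples kinship matrix (e.g. from [kinship()]).
#' @param p3d Reuse null-model variance components for all SNPs (default
#'   TRUE).
#' @return Tibble as in [glm_scan()] (model tag `"MLM"`) with the estimated
#'   narrow-sense heritability of the null model in the `h2` attribute.
#' @export
mlm_scan <- function(phenotypes, genotypes, K, covariates = NULL, p3d = TRUE) {
  g <- genotypes$dosages
  n <- nrow(g)
  if (!all(dim(K) == n)) abort("kinship dimensions do not match samples")
  K <- (K + t(K)) / 2 + diag(1e-6, n)
  ek <- eigen(K, symmetric = TRUE)
  if (min(ek$values) < -1e-6) abort("kinship matrix is not positive semidefinite")
  d <- pmax(ek$values, 1e-10)
  u <- ek$vectors
  x0 <- covariate_matrix(covariates, rownames(g))
  xstar0 <- crossprod(u, x0)
  gstar <- crossprod(u, g)
  gss_raw <- apply(g, 2L, var)
  mono <- gss_raw < 1e-12
  q0 <- ncol(x0)
  df <- n - q0 - 1L
  phen <- phenotype_columns(phenotypes, rownames(g))
  h2_out <- numeric(0)
  res <- purrr::map_dfr(names(phen), function(pn) {
    y <- phen[[pn]]
    ystar <- as.numeric(crossprod(u, y))
    opt <- optimize(reml_profile, interval = c(-12, 12), d = d,
                    ystar = ystar, xstar = xstar0, maximum = TRUE)
    delta0 <- exp(opt$maximum)
    h2_out[[pn]] <<- 1 / (1 + delta0)
    fit_one <- function(j, delta) {
      w <- 1 / (d + delta)
      xs <- cbind(xstar0, gstar[, j])
      xtw <- xs * w
      xwx <- crossprod(xtw, xs)
      xwy <- crossprod(xtw, ystar)
      beta <- tryCatch(solve(xwx, xwy), error = function(e) NULL)
      if (is.null(beta)) return(c(NA_real_, NA_real_))
      rss <- sum((ystar - xs %*% beta)^2 * w)
      sigma2 <- rss / df
      vb <- sigma2 * solve(xwx)[q0 + 1L, q0 + 1L]
      c(beta[q0 + 1L], sqrt(vb))
    }
    if (p3d) {
      w <- 1 / (d + delta0)
      xtw0 <- xstar0 * w
      a00 <- crossprod(xtw0, xstar0)
      a0y <- crossprod(xtw0, ystar)
      gw <- gstar * w
      a0g <- crossprod(xstar0, gw)              # q0 x m
      ggw <- colSums(gstar * gw)                # g' W g
      gy <- as.numeric(crossprod(gw, ystar))
      a00_inv <- solve(a00)
      tmp <- a00_inv %*% a0g                    # q0 x m
      schur <- ggw - colSums(a0g * tmp)         # g'Wg - g'WX (X'WX)^-1 X'Wg
      beta_g <- (gy - as.numeric(crossprod(tmp, a0y))) / schur
      ywy <- sum(ystar^2 * w)
      rss0 <- ywy - as.numeric(crossprod(a0y, a00_inv %*% a0y))
      rss <- rss0 - beta_g^2 * schur
      sigma2 <- pmax(rss, 0) / df
      se <- sqrt(sigma2 / schur)
      beta_g[mono] <- NA_real_
      se[mono | schur < 1e-10] <- NA_real_
      stat <- beta_g / se
      p <- 2 * pt(-abs(stat), df)
    } else {
      out <- vapply(seq_len(ncol(g)), function(j) {
        if (mono[j]) return(c(NA_real_, NA_real_))
        ystar_j <- ystar
        optj <- optimize(reml_profile, interval = c(-12, 12), d = d,
                         ystar = ystar_j, xstar = cbind(xstar0, gstar[, j]),
                         maximum = TRUE)
        fit_one(j, exp(optj$maximum))
      }, numeric(2))
      beta_g <- out[1, ]
      se <- out[2, ]
      stat <- beta_g / se
      p <- 2 * pt(-abs(stat), df)
    }
    scan_result_tibble(genotypes$map, beta_g, se, stat, p, "MLM", pn)
  })
  attr(res, "h2") <- h2_out
  res
}

#' Genomic-control inflation factor
#'
#' Ratio of the median association chi-square statistic to its null
#' expectation. Reported, never used to correct p values.
#'
#' @param p Numeric vector of p values.
#' @return Lambda (1 under the null).
#' @export
lambda_gc <- function(p) {
  p <- p[is.finite(p)]
  median(stats::qchisq(p, df = 1, lower.tail = FALSE)) / stats::qchisq(0.5, df = 1)
}
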