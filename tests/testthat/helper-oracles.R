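# Independent oracle implementations and fixture generators used across the
# test files. The oracles are deliberately written with different algorithms
# and code paths than the package implementations.

# ---- local outlier factor: direct double-loop implementation -------------
oracle_lof <- function(points, k) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  kdist <- numeric(n)
  for (i in seq_len(n)) kdist[i] <- sort(d[i, ])[k]
  neigh <- lapply(seq_len(n), function(i) {
    setdiff(which(d[i, ] <= kdist[i] + 1e-12), i)
  })
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (o in neigh[[i]]) s <- s + max(kdist[o], d[i, o])
    lrd[i] <- length(neigh[[i]]) / s
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(lrd[neigh[[i]]]) / length(neigh[[i]]) / lrd[i]
  }
  out
}

# ---- simple-regression closed form (intercept + slope) -------------------
oracle_ols <- function(y, g) {
  n <- length(y)
  gc <- g - mean(g)
  yc <- y - mean(y)
  beta <- sum(gc * yc) / sum(gc^2)
  rss <- sum((yc - beta * gc)^2)
  df <- n - 2
  se <- sqrt(rss / df / sum(gc^2))
  stat <- beta / se
  list(beta = beta, se = se, stat = stat, p = 2 * stats::pt(-abs(stat), df))
}

# ---- Benjamini-Hochberg step-up, from the definition ---------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (r in seq(m, 1)) {
    running <- min(running, p[o[r]] * m / r)
    adj[o[r]] <- min(running, 1)
  }
  adj
}

# ---- exhaustive minimum normalized cut over all 2-partitions -------------
# Returns the best partition of band ids (list(left, right), left holds the
# smallest id) for similarity matrix S.
oracle_min_ncut <- function(S, band_ids) {
  p <- nrow(S)
  stopifnot(p <= 12)
  vol <- rowSums(S)
  best <- NULL
  best_cost <- Inf
  # enumerate subsets containing band 1 (avoids double counting); mask bits
  # give the membership of bands 2..p, and the all-ones mask (empty right
  # side) is excluded
  for (mask in 0:(2^(p - 1) - 2)) {
    inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(p - 1) - 1))))
    cut <- sum(S[inA, !inA, drop = FALSE])
    cost <- cut * (1 / sum(vol[inA]) + 1 / sum(vol[!inA]))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- inA
    }
  }
  a <- band_ids[best]
  b <- band_ids[!best]
  if (min(b) < min(a)) list(left = b, right = a) else list(left = a, right = b)
}

# ---- brute-force candidate-gene interval intersection --------------------
oracle_genes <- function(snps, genes, window_bp) {
  out <- list()
  for (s in snps) {
    pos <- as.integer(sub("^.*_", "", s))
    chrom <- sub("_[0-9]+$", "", s)
    lo <- max(1, pos - window_bp)
    hi <- pos + window_bp
    for (i in seq_len(nrow(genes))) {
      if (genes$chrom[i] != chrom) next
      if (genes$end[i] >= lo && genes$start[i] <= hi) {
        d <- if (pos >= genes$start[i] && pos <= genes$end[i]) 0L else
          min(abs(pos - genes$start[i]), abs(pos - genes$end[i]))
        out[[length(out) + 1]] <- tibble::tibble(
          snp = s, gene_id = genes$gene_id[i], distance = as.integer(d))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(snp = character(), gene_id = character(),
                          distance = integer()))
  }
  dplyr::bind_rows(out)
}

# ---- fixture generators --------------------------------------------------

# Block-correlated band data via a latent-factor construction: bands in one
# block share a block factor (within-block correlation rho_w); a global
# factor adds between-block correlation rho_b.
make_block_data <- function(n, sizes, rho_w = 0.95, rho_b = 0, seed = 1) {
  stopifnot(rho_w > rho_b)
  p <- sum(sizes)
  set.seed(seed)
  g <- rnorm(n)
  x <- matrix(rnorm(n * p), n, p) * sqrt(1 - rho_w)
  col <- 0
  for (b in seq_along(sizes)) {
    f <- rnorm(n)
    for (j in seq_len(sizes[b])) {
      col <- col + 1
      x[, col] <- x[, col] + sqrt(rho_w - rho_b) * f + sqrt(rho_b) * g
    }
  }
  colnames(x) <- as.character(seq_len(p))
  x
}

# Rank-r factor data at a given per-band signal-to-noise ratio: each factor
# loads 1 on its own disjoint block of bands.
make_factor_data <- function(n, p, n_factors = 1, snr = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  blocks <- if (n_factors == 1) list(seq_len(p)) else
    split(seq_len(p), cut(seq_len(p), n_factors, labels = FALSE))
  for (b in seq_len(n_factors)) {
    s <- rnorm(n)
    x[, blocks[[b]]] <- x[, blocks[[b]]] + sqrt(snr) * s
  }
  colnames(x) <- as.character(seq_len(p))
  x
}

# Wide spectra tibble from a plain matrix with integer band names.
as_spectra_tbl <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  dplyr::bind_cols(tibble::tibble(sample = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# Minimal GFF3 writer for gene features.
write_toy_gff <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end,
                     ifelse(is.na(genes$strand), "+", genes$strand),
                     genes$gene_id))
  writeLines(lines, path)
  path
}

# Small deterministic genotype_matrix-like fixture via the simulator.
small_genotypes <- function(n_rils = 40, n_snps = 120, seed = 7) {
  fo <- simulate_founders(n_founders = 8, n_snps = n_snps, n_chrom = 3,
                          seed = seed)
  simulate_rils(fo, n_rils, seed = seed + 1L)
}
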