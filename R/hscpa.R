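# Hierarchical spectral clustering with parallel analysis (HSC-PA): recursive
# bipartition of the wavelength set, guided at each node by Horn-style
# parallel analysis on the band-correlation spectrum. A node whose data are
# adequately described by a single principal component becomes a terminal
# segment; terminal PC1 scores serve as GWAS phenotypes.

as_band_matrix <- function(x) {
  if (is.data.frame(x)) x <- spectra_to_matrix(x)
  stopifnot(is.matrix(x))
  x
}

# Eigenvalues of the band-correlation matrix of standardized Z, computed from
# whichever Gram matrix is smaller (identical nonzero spectrum).
eig_corr <- function(z) {
  n <- nrow(z); p <- ncol(z)
  g <- if (p <= n) crossprod(z) else tcrossprod(z)
  pmax(eigen(g / (n - 1), symmetric = TRUE, only.values = TRUE)$values, 0)
}

#' Parallel analysis: how many principal components exceed a permutation null
#'
#' Compares the eigenvalues of the band-correlation matrix, rank by rank,
#' against the stated percentile of eigenvalues from null datasets of the
#' same shape obtained by independently permuting each band across samples.
#' The retained count is the length of the leading run of observed
#' eigenvalues exceeding their null percentile, with a floor of 1.
#'
#' @param values Samples x bands matrix (or wide spectra tibble).
#' @param n_null Number of permutation replicates (default 100).
#' @param quantile Null percentile in (0, 1] (default 0.95).
#' @param seed Integer seed for the permutations.
#' @return Integer `n_retained` (>= 1) with attributes `observed` and
#'   `null_quantile` (the per-rank eigenvalue series).
#' @export
parallel_analysis <- function(values, n_null = 100, quantile = 0.95, seed = 1L) {
  m <- as_band_matrix(values)
  if (nrow(m) < 3) abort("parallel analysis needs at least 3 samples")
  if (ncol(m) < 2) abort("parallel analysis needs at least 2 bands")
  s <- apply(m, 2L, sd)
  if (any(s == 0)) {
    warn(paste0("dropping ", sum(s == 0), " constant band(s) before parallel analysis"))
    m <- m[, s > 0, drop = FALSE]
    if (ncol(m) < 2) return(structure(1L, observed = NA_real_, null_quantile = NA_real_))
  }
  z <- standardize_cols(m)
  obs <- eig_corr(z)
  n <- nrow(z)
  p <- ncol(z)
  cols <- rep(seq_len(p), each = n)
  with_seed(seed, {
    nulls <- vapply(seq_len(n_null), function(r) {
      # independent row permutation of every column in one order() call:
      # linear indices grouped by column, random order within column
      idx <- order(cols, stats::runif(n * p))
      eig_corr(matrix(z[idx], n, p))
    }, numeric(length(obs)))
    thr <- apply(nulls, 1L, stats::quantile, probs = quantile, names = FALSE)
    above <- obs > thr
    n_ret <- if (!above[1]) 1L else {
      run <- which(!above)
      if (length(run) == 0L) length(above) else run[1] - 1L
    }
    structure(max(1L, n_ret), observed = obs, null_quantile = thr)
  })
}

# Fiedler vector (eigenvector of the second-smallest eigenvalue of the
# symmetric normalized Laplacian), i.e. the second-largest eigenvector of the
# normalized affinity N = D^{-1/2} S D^{-1/2}. For large band sets this is
# computed by power iteration on N + I deflated by the known top eigenvector
# D^{1/2} 1.
fiedler_vector <- function(S, exact_limit = 600L) {
  p <- nrow(S)
  d <- rowSums(S)
  ds <- sqrt(d)
  N <- sweep(sweep(S, 1L, ds, "/"), 2L, ds, "/")
  if (p <= exact_limit) {
    es <- eigen(N, symmetric = TRUE)
    return(es$vectors[, 2L] / ds)
  }
  u1 <- ds / sqrt(sum(d))
  v <- seq_len(p) - (p + 1) / 2
  v <- v - u1 * sum(u1 * v)
  v <- v / sqrt(sum(v^2))
  for (it in seq_len(5000L)) {
    w <- as.numeric(N %*% v) + v          # shift +I keeps spectrum nonnegative
    w <- w - u1 * sum(u1 * w)
    w <- w / sqrt(sum(w^2))
    if (sum((w - v)^2) < 1e-20 || sum((w + v)^2) < 1e-20) {
      v <- w
      break
    }
    v <- w
  }
  v / ds
}

#' Bipartition a band set by normalized spectral clustering
#'
#' Similarity between bands is the squared Pearson correlation across
#' samples (so anti-correlated bands group together; absolute correlation is
#' available as an alternative). Bands are split by the sign of the Fiedler
#' vector of the symmetric normalized Laplacian; zero entries join the side
#' with fewer bands. The returned sides are ordered so the one containing the
#' smallest band id comes first.
#'
#' @param values Samples x bands matrix (or wide spectra tibble) restricted
#'   to the segment.
#' @param band_ids Band identifiers (nm); defaults to numeric column names.
#' @param similarity `"squared"` (default) or `"absolute"` correlation.
#' @return List with `left` and `right` band-id vectors (both non-empty).
#' @export
split_segment <- function(values, band_ids = NULL,
                          similarity = c("squared", "absolute")) {
  similarity <- match.arg(similarity)
  m <- as_band_matrix(values)
  if (is.null(band_ids)) band_ids <- as.numeric(colnames(m))
  p <- ncol(m)
  if (p < 2) abort("cannot split a segment with fewer than 2 bands")
  C <- suppressWarnings(cor(m))
  degenerate <- !all(is.finite(C)) ||
    all(abs(C[upper.tri(C)] - C[upper.tri(C)][1]) < 1e-12)
  if (degenerate) {
    warn("degenerate similarity; splitting segment at the band-index median")
    half <- ceiling(p / 2)
    return(list(left = band_ids[seq_len(half)], right = band_ids[-seq_len(half)]))
  }
  S <- if (similarity == "squared") C^2 else abs(C)
  diag(S) <- 1
  f <- fiedler_vector(S)
  pos <- f > 1e-12
  neg <- f < -1e-12
  zero <- !pos & !neg
  if (any(zero)) {
    if (sum(pos) <= sum(neg)) pos[zero] <- TRUE else neg[zero] <- TRUE
  }
  if (!any(pos) || !any(neg)) {
    warn("sign split degenerate; splitting segment at the band-index median")
    half <- ceiling(p / 2)
    return(list(left = band_ids[seq_len(half)], right = band_ids[-seq_len(half)]))
  }
  a <- band_ids[pos]
  b <- band_ids[neg]
  if (min(b) < min(a)) list(left = b, right = a) else list(left = a, right = b)
}

#' Run hierarchical spectral clustering with parallel analysis
#'
#' Starting from the full band set of the (centered) adjusted spectra, each
#' node is tested with [parallel_analysis()]; nodes retaining a single
#' principal component, or smaller than `min_bands`, or at `max_depth`,
#' become terminal segments, otherwise the band set is bipartitioned with
#' [split_segment()] and both children are processed. Node ids are assigned
#' in breadth-first order; the root has level 1.
#'
#' @param adjusted Wide spectra tibble of adjusted (environment-corrected)
#'   spectra.
#' @param n_null,quantile Parallel-analysis null parameters.
#' @param min_bands Minimum band count for further splitting (default 5).
#' @param max_depth Maximum tree depth (default 8).
#' @param seed Integer seed (per-node permutation seeds are derived from it).
#' @return An object of class `segment_tree`: list with `nodes` (tibble: id,
#'   parent, level, n_bands, n_retained, terminal, bands list-column) and
#'   `params`.
#' @export
run_hscpa <- function(adjusted, n_null = 100, quantile = 0.95, min_bands = 5,
                      max_depth = 8, seed = 1L) {
  m <- as_band_matrix(adjusted)
  m <- sweep(m, 2L, colMeans(m), "-")
  wl <- as.numeric(colnames(m))
  nodes <- list()
  queue <- list(list(id = 1L, parent = NA_integer_, level = 1L, bands = wl))
  next_id <- 2L
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    sub <- m[, match(node$bands, wl), drop = FALSE]
    n_ret <- if (length(node$bands) >= 2) {
      as.integer(parallel_analysis(sub, n_null = n_null, quantile = quantile,
                                   seed = derive_seed(seed, node$id)))
    } else 1L
    terminal <- n_ret == 1L || length(node$bands) < min_bands ||
      node$level >= max_depth
    children <- c(NA_integer_, NA_integer_)
    if (!terminal) {
      halves <- split_segment(sub, node$bands)
      children <- c(next_id, next_id + 1L)
      queue <- c(queue, list(
        list(id = next_id, parent = node$id, level = node$level + 1L,
             bands = halves$left),
        list(id = next_id + 1L, parent = node$id, level = node$level + 1L,
             bands = halves$right)
      ))
      next_id <- next_id + 2L
    }
    nodes[[node$id]] <- tibble(
      id = node$id, parent = node$parent, level = node$level,
      n_bands = length(node$bands), n_retained = n_ret, terminal = terminal,
      bands = list(node$bands)
    )
  }
  structure(
    list(nodes = dplyr::bind_rows(nodes),
         params = list(n_null = n_null, quantile = quantile,
                       min_bands = min_bands, max_depth = max_depth,
                       seed = seed),
         wavelengths = wl),
    class = "segment_tree"
  )
}

#' Terminal-segment PC1 phenotypes
#'
#' For each terminal segment of a fitted tree, computes first-principal-
#' component scores of the (centered) segment submatrix. The loading sign is
#' chosen so its sum is positive, and scores are standardized to mean 0 and
#' variance 1. Single-band terminals return the standardized band.
#'
#' @param tree A `segment_tree`.
#' @param adjusted Wide spectra tibble on the same band grid the tree was
#'   fitted on.
#' @return Tibble: `sample` plus one column per terminal segment (named
#'   `seg<id>`), with per-segment unit-norm loadings in the `loadings`
#'   attribute.
#' @export
segment_phenotypes <- function(tree, adjusted) {
  stopifnot(inherits(tree, "segment_tree"))
  m <- as_band_matrix(adjusted)
  wl <- as.numeric(colnames(m))
  if (!setequal(wl, tree$wavelengths)) {
    abort("adjusted spectra band grid does not match the fitted tree")
  }
  terms <- dplyr::filter(tree$nodes, .data$terminal)
  loadings <- list()
  scores <- purrr::map(seq_len(nrow(terms)), function(i) {
    bands <- terms$bands[[i]]
    sub <- m[, match(bands, wl), drop = FALSE]
    sub <- sweep(sub, 2L, colMeans(sub), "-")
    if (ncol(sub) == 1L) {
      v <- 1
    } else {
      sv <- svd(sub, nu = 0, nv = 1)
      v <- sv$v[, 1]
    }
    sgn <- sum(v)
    if (sgn == 0) sgn <- v[which(v != 0)[1]]
    if (sgn < 0) v <- -v
    loadings[[paste0("seg", terms$id[i])]] <<- setNames(v, bands)
    sc <- as.numeric(sub %*% v)
    s <- sd(sc)
    if (s == 0) sc else (sc - mean(sc)) / s
  })
  names(scores) <- paste0("seg", terms$id)
  out <- dplyr::bind_cols(tibble(sample = rownames(m)), as_tibble(scores))
  attr(out, "loadings") <- loadings
  out
}

#' @export
print.segment_tree <- function(x, ...) {
  g <- glance(x)
  cat("<segment_tree> ", g$n_nodes, " nodes, ", g$n_terminal,
      " terminal segments, levels 1-", g$max_level, "\n", sep = "")
  invisible(x)
}

#' Tidy a segment tree into one row per node
#'
#' @param x A `segment_tree`.
#' @param ... Unused.
#' @return Tibble: id, parent, level, n_bands, n_retained, terminal, and the
#'   band set as run-length `ranges` text.
#' @method tidy segment_tree
#' @export
tidy.segment_tree <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$nodes, -"bands"),
    ranges = vapply(x$nodes$bands, intervals_chr, character(1))
  )
}

#' One-row summary of a segment tree
#' @param x A `segment_tree`.
#' @param ... Unused.
#' @return Tibble: n_nodes, n_terminal, max_level, n_bands.
#' @method glance segment_tree
#' @export
glance.segment_tree <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_terminal = sum(x$nodes$terminal),
    max_level = max(x$nodes$level),
    n_bands = length(x$wavelengths)
  )
}

#' Serialize a segment tree as structured text
#' @param tree A `segment_tree`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segment_tree <- function(tree, path) {
  readr::write_tsv(tidy(tree), path, progress = FALSE)
  invisible(path)
}
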