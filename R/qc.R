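# Spectral quality control: local outlier factor (LOF) scores computed on a
# principal-component embedding of the spectra, plus deterministic flagging.

# Exact LOF on a points-in-rows matrix. Neighborhoods include all points at
# distance <= the k-th nearest-neighbour distance (ties included), per the
# original definition.
lof_from_points <- function(points, k) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  diag(d) <- Inf
  kdist <- numeric(n)
  nbhd <- vector("list", n)
  for (i in seq_len(n)) {
    ds <- sort(d[i, ])
    kdist[i] <- ds[k]
    nbhd[[i]] <- which(d[i, ] <= kdist[i] + 1e-12)
  }
  lrd <- vapply(seq_len(n), function(i) {
    nb <- nbhd[[i]]
    reach <- pmax(kdist[nb], d[i, nb])
    1 / mean(reach)
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    mean(lrd[nbhd[[i]]]) / lrd[i]
  }, numeric(1))
}

#' Local outlier factor scores for spectra
#'
#' Embeds the spectra in their top principal components and computes the
#' standard local outlier factor: the ratio of the average local reachability
#' density of a sample's k-nearest neighbourhood to its own. Scores near 1
#' indicate inliers; scores well above 1 indicate samples lying in sparser
#' regions than their neighbours.
#'
#' @param spectra Wide spectra tibble.
#' @param k Neighbourhood size (default 20); must be below the sample count.
#' @param n_pcs Number of principal components for the embedding (default 10).
#' @return Tibble: `sample`, `lof_score`.
#' @export
lof_scores <- function(spectra, k = 20, n_pcs = 10) {
  m <- spectra_to_matrix(spectra)
  n <- nrow(m)
  if (k >= n) abort("k must be smaller than the number of samples")
  n_pcs <- min(n_pcs, n - 1L, ncol(m))
  ctr <- sweep(m, 2L, colMeans(m), "-")
  sv <- svd(ctr, nu = n_pcs, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  tibble(sample = rownames(m), lof_score = lof_from_points(emb, k))
}

#' Flag outlying spectra by LOF score threshold
#'
#' Deterministic thresholding of LOF scores; the parameters used are retained
#' on the report for audit.
#'
#' @param scores Tibble from [lof_scores()] (columns `sample`, `lof_score`).
#' @param threshold Flag samples with `lof_score > threshold` (default 1.5).
#' @param k,n_pcs The parameters used to compute the scores, recorded in the
#'   report.
#' @return Tibble: `sample`, `lof_score`, `flagged`, `threshold`, `k`,
#'   `n_pcs`.
#' @export
flag_outliers <- function(scores, threshold = 1.5, k = 20, n_pcs = 10) {
  if (any(!is.finite(scores$lof_score))) abort("LOF scores must be finite")
  dplyr::mutate(scores,
                flagged = .data$lof_score > threshold,
                threshold = threshold, k = k, n_pcs = n_pcs)
}
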