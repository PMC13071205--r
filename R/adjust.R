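# Per-wavelength linear-model adjustment of spectra for known environmental
# effects, with sequential (Type I) variance partitioning in a declared term
# order: measurement technique -> spatial -> temporal -> maternal. Residuals
# are the downstream analysis phenotypes.

adjust_formula_terms <- function() {
  list(LN = "LN", REP = "REP", BA = "BA",
       `LN:REP` = c("LN", "REP"), `LN:BA` = c("LN", "BA"),
       DT = "DT", CT = "CT", `DT:CT` = c("DT", "CT"), MO = "MO")
}

# Indicator columns for one term: treatment-style dummies for a main effect
# (reference level dropped), full cell indicators for an interaction (the
# sequential rank filter trims them to the interaction df).
term_columns <- function(metadata, vars) {
  if (length(vars) == 1L) {
    f <- as.character(metadata[[vars]])
    lev <- sort(unique(f))
    lev <- lev[-1]
    if (length(lev) == 0L) return(NULL)
    cols <- vapply(lev, function(l) as.numeric(f == l), numeric(nrow(metadata)))
    colnames(cols) <- paste0(vars, lev)
  } else {
    key <- do.call(paste, c(lapply(vars, function(v) as.character(metadata[[v]])),
                            sep = ":"))
    lev <- sort(unique(key))
    cols <- vapply(lev, function(l) as.numeric(key == l), numeric(nrow(metadata)))
    colnames(cols) <- paste0(paste(vars, collapse = ":"), "_", lev)
  }
  cols
}

#' Build the environmental-adjustment design matrix
#'
#' Expands the adjustment model
#' `Y ~ LN + REP + BA + LN:REP + LN:BA + DT + CT + DT:CT + MO`
#' into treatment-contrast columns in that declared order, dropping aliased
#' columns sequentially (with a warning) so the retained design has full
#' column rank. The orthonormal basis built column-by-column is stored, which
#' makes the downstream Type-I sum-of-squares decomposition follow the
#' declared order exactly.
#'
#' @param metadata Data frame with columns `sample`, `LN`, `REP`, `BA`, `DT`,
#'   `CT`, `MO` (factors or characters, no missing values).
#' @return An object of class `design_matrix`: list with `X` (retained raw
#'   columns incl. intercept), `Q` (orthonormal basis in term order),
#'   `assign` (term index per column, 0 = intercept), `terms`, `samples`,
#'   `dropped` (aliased column names).
#' @export
build_design <- function(metadata) {
  need <- c("sample", "LN", "REP", "BA", "DT", "CT", "MO")
  if (!all(need %in% names(metadata))) {
    abort(paste("metadata must contain columns:", paste(need, collapse = ", ")))
  }
  if (anyNA(metadata[need])) abort("metadata contains missing values")
  n <- nrow(metadata)
  terms <- adjust_formula_terms()
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Q <- matrix(1 / sqrt(n), n, 1)
  assign <- 0L
  dropped <- character()
  tol <- 1e-8
  for (ti in seq_along(terms)) {
    cols <- term_columns(metadata, terms[[ti]])
    if (is.null(cols)) next
    for (j in seq_len(ncol(cols))) {
      c0 <- cols[, j]
      r <- c0 - Q %*% crossprod(Q, c0)
      r <- r - Q %*% crossprod(Q, r)  # reorthogonalize for stability
      nrm <- sqrt(sum(r^2))
      if (nrm > tol * sqrt(sum(c0^2))) {
        X <- cbind(X, c0)
        colnames(X)[ncol(X)] <- colnames(cols)[j]
        Q <- cbind(Q, r / nrm)
        assign <- c(assign, ti)
      } else {
        dropped <- c(dropped, colnames(cols)[j])
      }
    }
  }
  if (length(dropped) > 0) {
    warn(paste0("dropped ", length(dropped), " aliased design column(s): ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else ""))
  }
  structure(
    list(X = X, Q = Q, assign = assign, terms = names(terms),
         samples = as.character(metadata$sample), dropped = dropped),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", length(x$samples), " samples x ", ncol(x$X),
      " columns (", length(x$dropped), " aliased dropped)\n", sep = "")
  df <- table(factor(x$assign, levels = seq_along(x$terms), labels = x$terms))
  print(df)
  invisible(x)
}

# Align a samples-by-variables matrix to the design's sample order.
align_to_design <- function(m, design) {
  idx <- match(design$samples, rownames(m))
  if (anyNA(idx)) abort("samples in design not found in data")
  m[idx, , drop = FALSE]
}

#' Adjust spectra for environmental effects and partition variance
#'
#' Fits, per wavelength, the ordinary-least-squares environmental model from
#' [build_design()] and returns the residuals as adjusted spectral values,
#' together with the sequential (Type I) percent sum of squares of each term
#' in the declared order. Adjusted spectra have exactly zero sample mean at
#' every wavelength, and the per-wavelength percentages (terms + residual)
#' sum to 100.
#'
#' @param spectra Wide spectra tibble (samples must match the design).
#' @param design A `design_matrix` from [build_design()].
#' @return List with `adjusted` (wide residual spectra tibble, rows in design
#'   order) and `variance` (tibble: wavelength, term, percent).
#' @export
fit_adjust <- function(spectra, design) {
  stopifnot(inherits(design, "design_matrix"))
  y <- align_to_design(spectra_to_matrix(spectra), design)
  wl <- spectra_wavelengths(spectra)
  eff <- crossprod(design$Q, y)                    # K x p sequential effects
  resid <- y - design$Q %*% eff
  ss_tot <- colSums(sweep(y, 2L, colMeans(y), "-")^2)
  term_idx <- factor(design$assign, levels = seq_along(design$terms),
                     labels = design$terms)
  ss_term <- rowsum(eff[design$assign > 0L, , drop = FALSE]^2,
                    group = term_idx[design$assign > 0L])
  ss_resid <- colSums(resid^2)
  ss_tot[ss_tot == 0] <- NA_real_
  pct <- rbind(ss_term, residual = ss_resid) / rep(ss_tot, each = nrow(ss_term) + 1L) * 100
  variance <- tibble(
    wavelength = rep(wl, each = nrow(pct)),
    term = rep(rownames(pct), length(wl)),
    percent = as.numeric(pct)
  )
  list(adjusted = matrix_to_spectra(resid), variance = variance)
}

#' Adjust a scalar phenotype with the environmental model
#'
#' Same model as [fit_adjust()] applied to one or more per-sample scalar
#' phenotypes (e.g. spectral indices computed from raw spectra).
#'
#' @param values Data frame with a `sample` column and one or more numeric
#'   phenotype columns.
#' @param design A `design_matrix`.
#' @return Tibble of residuals, same columns, rows in design order.
#' @export
adjust_scalar <- function(values, design) {
  stopifnot(inherits(design, "design_matrix"), is.data.frame(values))
  num_cols <- setdiff(names(values), "sample")
  m <- as.matrix(values[num_cols])
  rownames(m) <- as.character(values$sample)
  m <- align_to_design(m, design)
  resid <- m - design$Q %*% crossprod(design$Q, m)
  dplyr::bind_cols(tibble(sample = design$samples),
                   as_tibble(resid, .name_repair = "minimal"))
}

#' Patch-level environmental effects from phytometer spectra
#'
#' Phytometers are replicated tester-genotype plants, one per 2x2 planting
#' patch; their spectral deviations estimate small-scale spatial effects.
#' Per patch and wavelength block, returns the mean phytometer deviation from
#' the grand phytometer mean, usable as a continuous spatial covariate
#' (alternative to patch-as-factor).
#'
#' @param phytometer_spectra Wide spectra tibble of phytometer samples.
#' @param metadata Metadata with `sample` and `BA` columns covering all
#'   patches of the experiment.
#' @param blocks Named list of wavelength blocks `c(lo, hi)`.
#' @return Tibble: `BA`, `block`, `effect` (patches without phytometers get 0
#'   with a warning).
#' @export
estimate_patch_effects <- function(phytometer_spectra, metadata,
                                   blocks = list(VIS = c(400, 700),
                                                 NIR = c(701, 1340),
                                                 SWIR = c(1341, 2500))) {
  m <- spectra_to_matrix(phytometer_spectra)
  wl <- spectra_wavelengths(phytometer_spectra)
  patch_of <- setNames(as.character(metadata$BA), as.character(metadata$sample))
  if (!all(rownames(m) %in% names(patch_of))) {
    abort("phytometer samples missing from metadata")
  }
  patches <- sort(unique(as.character(metadata$BA)))
  out <- purrr::map_dfr(names(blocks), function(bn) {
    sel <- wl >= blocks[[bn]][1] & wl <= blocks[[bn]][2]
    block_mean <- rowMeans(m[, sel, drop = FALSE])
    grand <- mean(block_mean)
    per_patch <- tapply(block_mean, patch_of[rownames(m)], mean)
    eff <- setNames(rep(0, length(patches)), patches)
    eff[names(per_patch)] <- per_patch - grand
    tibble(BA = patches, block = bn, effect = as.numeric(eff))
  })
  missing_patch <- setdiff(patches, unique(patch_of[rownames(m)]))
  if (length(missing_patch) > 0) {
    warn(paste0(length(missing_patch),
                " patch(es) without phytometers; effects imputed as 0"))
  }
  out
}
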