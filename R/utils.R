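# Internal helpers shared across modules. A "spectra table" is a wide tibble:
# first column `sample` (character, unique), remaining columns named by integer
# nanometre wavelength, strictly increasing.

# The canonical analysis grid: 400-2500 nm at 1 nm, 2101 bands.
grid_default <- function() 400:2500

spectra_wavelengths <- function(spectra) {
  wl <- suppressWarnings(as.numeric(names(spectra)[-1]))
  if (anyNA(wl)) {
    abort("spectra table columns after `sample` must be numeric wavelengths (nm)")
  }
  wl
}

validate_spectra_tbl <- function(spectra) {
  if (!is.data.frame(spectra) || ncol(spectra) < 2L) {
    abort("spectra must be a data frame: `sample` column plus wavelength columns")
  }
  if (names(spectra)[1] != "sample") {
    abort("first column of a spectra table must be `sample`")
  }
  if (anyDuplicated(spectra$sample)) {
    abort("duplicate sample ids in spectra table")
  }
  wl <- spectra_wavelengths(spectra)
  if (is.unsorted(wl, strictly = TRUE)) {
    abort("wavelength columns must be strictly increasing")
  }
  invisible(spectra)
}

# samples x wavelengths numeric matrix, dimnames (sample, nm)
spectra_to_matrix <- function(spectra) {
  validate_spectra_tbl(spectra)
  m <- as.matrix(spectra[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(spectra$sample)
  m
}

matrix_to_spectra <- function(m) {
  stopifnot(is.matrix(m))
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample = rownames(m) %||% as.character(seq_len(nrow(m)))), out)
}

# Column-standardize, dropping nothing; zero-variance columns become 0.
standardize_cols <- function(m) {
  mu <- colMeans(m)
  z <- sweep(m, 2L, mu, "-")
  s <- sqrt(colSums(z^2) / max(1L, nrow(m) - 1L))
  s[s == 0] <- Inf
  sweep(z, 2L, s, "/")
}

# Derive a reproducible child seed from a base seed and an index, kept within
# 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %% .Machine$integer.max)
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Run-length encode a sorted integer vector into "a-b" interval strings.
intervals_chr <- function(x) {
  x <- sort(unique(as.integer(x)))
  if (length(x) == 0L) return("")
  brk <- c(0L, which(diff(x) != 1L), length(x))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    a <- x[brk[i] + 1L]; b <- x[brk[i + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1)), collapse = ",")
}
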