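# Reflectance calibration from raw radiance scans, gridding to the canonical
# 1-nm analysis grid, and wide-CSV spectra input/output.

#' Compute calibrated relative reflectance from radiance scans
#'
#' Raw radiance scans are collected under four conditions: white and black
#' references, with and without leaf. Relative reflectance at each wavelength
#' is the background- and dark-current-corrected ratio
#' \deqn{R(\lambda) = panel(\lambda)\,\frac{S_{leaf}(\lambda) - S_{black}(\lambda)}
#'   {S_{white}(\lambda) - S_{black}(\lambda)}}
#' scaled by the known reflectance of the calibrated white reference panel.
#' With `dual_background = TRUE` and a `leaf_on_black` column present, the
#' same quantity is computed after subtracting the black-background leaf
#' signal from both numerator terms (algebraically equivalent; kept as an
#' explicit variant for instrument protocols that record it).
#'
#' @param scans Data frame with columns `wavelength`, `white`, `black`,
#'   `leaf_on_white` and optionally `leaf_on_black`, all on one grid.
#' @param panel_reflectance Reflectance of the white reference panel: a single
#'   number or one value per wavelength (default 1).
#' @param dual_background Use the leaf-on-black scan variant.
#' @param clamp_negative Clamp negative reflectance values to 0 (default
#'   FALSE: negatives are preserved for diagnostics).
#' @return Tibble with columns `wavelength`, `reflectance`.
#' @examples
#' scans <- tibble::tibble(wavelength = 400:410, white = 1, black = 0.2,
#'                         leaf_on_white = 0.6)
#' compute_reflectance(scans, panel_reflectance = 0.99)
#' @export
compute_reflectance <- function(scans, panel_reflectance = 1,
                                dual_background = FALSE,
                                clamp_negative = FALSE) {
  need <- c("wavelength", "white", "black", "leaf_on_white")
  if (!all(need %in% names(scans))) {
    abort(paste("scans must contain columns:", paste(need, collapse = ", ")))
  }
  wl <- scans$wavelength
  denom <- scans$white - scans$black
  if (any(denom <= 0)) {
    bad <- wl[which(denom <= 0)[1]]
    abort(paste0("white - black signal not strictly positive at ", bad, " nm"))
  }
  if (dual_background) {
    if (!"leaf_on_black" %in% names(scans)) {
      abort("dual_background = TRUE requires a leaf_on_black column")
    }
    num <- (scans$leaf_on_white - scans$leaf_on_black) -
      (scans$black - scans$leaf_on_black)
  } else {
    num <- scans$leaf_on_white - scans$black
  }
  r <- panel_reflectance * num / denom
  if (clamp_negative) r <- pmax(r, 0)
  tibble(wavelength = wl, reflectance = r)
}

#' Clip a spectrum to an analysis range and interpolate onto a regular grid
#'
#' Restricts a reflectance spectrum to `[lo, hi]` nm (dropping, by default,
#' the noisy 350-399 nm region below 400 nm) and linearly interpolates onto
#' an integer grid with the given step. Idempotent on already-gridded input.
#'
#' @param spectrum Data frame with columns `wavelength`, `reflectance`.
#' @param lo,hi Analysis range bounds in nm (defaults 400 and 2500).
#' @param step Output grid step in nm (default 1).
#' @return Tibble with `wavelength` (lo..hi by step) and `reflectance`.
#' @export
clip_and_grid <- function(spectrum, lo = 400, hi = 2500, step = 1) {
  wl <- spectrum$wavelength
  if (min(wl) > lo || max(wl) < hi) {
    abort(sprintf("input grid [%s, %s] does not cover [%s, %s] nm",
                  min(wl), max(wl), lo, hi))
  }
  grid <- seq(lo, hi, by = step)
  out <- approx(wl, spectrum$reflectance, xout = grid, ties = "ordered")$y
  tibble(wavelength = grid, reflectance = out)
}

#' Read a wide-format spectra table
#'
#' Expects a CSV whose first column is the sample id and whose remaining
#' headers are numeric wavelengths in nm, strictly increasing.
#'
#' @param path CSV file path.
#' @return Wide spectra tibble (first column `sample`).
#' @export
read_spectra <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "sample"
  x$sample <- as.character(x$sample)
  wl <- suppressWarnings(as.numeric(names(x)[-1]))
  if (anyNA(wl)) abort("non-numeric wavelength header in spectra file")
  if (is.unsorted(wl, strictly = TRUE)) {
    abort("wavelength headers must be strictly increasing")
  }
  if (anyDuplicated(x$sample)) abort("duplicate sample ids in spectra file")
  validate_spectra_tbl(x)
}

#' Write a wide-format spectra table
#' @param spectra Wide spectra tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  validate_spectra_tbl(spectra)
  readr::write_csv(spectra, path, progress = FALSE)
  invisible(path)
}

#' Pivot a wide spectra table to long form
#' @param spectra Wide spectra tibble.
#' @return Tibble with columns `sample`, `wavelength`, `value`.
#' @export
spectra_long <- function(spectra) {
  validate_spectra_tbl(spectra)
  tidyr::pivot_longer(spectra, -"sample", names_to = "wavelength",
                      values_to = "value",
                      names_transform = list(wavelength = as.numeric))
}
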