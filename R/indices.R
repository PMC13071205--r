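# Classical spectral indices: scalar band-ratio summaries of a reflectance
# spectrum serving as proxies for leaf water, chlorophyll and dry matter.

index_defs <- function() {
  list(
    # (Ra - Rb) / (Rc + Rd) four-band forms; NDWI/CCI are normalized
    # differences, CIre is a simple ratio minus one.
    NDWI      = function(R) (R(865) - R(1614)) / (R(865) + R(1614)),
    CIre      = function(R) R(783) / R(704) - 1,
    CCI       = function(R) (R(560) - R(664)) / (R(560) + R(664)),
    ARDSI_Cab = function(R) (R(750) - R(730)) / (R(770) + R(720)),
    ARDSI_Cw  = function(R) (R(1360) - R(1080)) / (R(1560) + R(1240)),
    ARDSI_Cm  = function(R) (R(2200) - R(1640)) / (R(2240) + R(1720))
  )
}

#' Names of the available spectral indices
#' @return Character vector: NDWI, CIre, CCI, ARDSI_Cab, ARDSI_Cw, ARDSI_Cm.
#' @export
index_names <- function() names(index_defs())

#' Compute one spectral index from a reflectance spectrum
#'
#' Exact integer-nanometre band lookup (no averaging window); the spectrum
#' must cover all bands the index uses. A zero denominator yields `NaN` with
#' a warning rather than an error, so undefined values can be flagged
#' downstream.
#'
#' @param spectrum Data frame with columns `wavelength`, `reflectance`.
#' @param name One of [index_names()].
#' @return A single numeric index value.
#' @examples
#' sp <- tibble::tibble(wavelength = 400:2500, reflectance = 0.3)
#' compute_index(sp, "NDWI")  # 0 for a flat spectrum
#' @export
compute_index <- function(spectrum, name = index_names()) {
  name <- match.arg(name)
  R <- function(w) {
    j <- match(w, spectrum$wavelength)
    if (is.na(j)) abort(paste0("spectrum does not cover required band ", w, " nm"))
    spectrum$reflectance[j]
  }
  val <- index_defs()[[name]](R)
  if (!is.finite(val)) {
    warn(paste0("zero denominator for index ", name))
    val <- NaN
  }
  val
}

#' Compute all six spectral indices for every sample in a spectra table
#'
#' @param spectra Wide spectra tibble on a grid covering all index bands.
#' @return Tibble: `sample` plus one column per index.
#' @export
spectral_indices <- function(spectra) {
  m <- spectra_to_matrix(spectra)
  wl <- spectra_wavelengths(spectra)
  out <- purrr::map_dfc(index_defs(), function(f) {
    R <- function(w) {
      j <- match(w, wl)
      if (is.na(j)) abort(paste0("spectra do not cover required band ", w, " nm"))
      m[, j]
    }
    unname(f(R))
  })
  dplyr::bind_cols(tibble(sample = rownames(m)), out)
}
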