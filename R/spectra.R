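#' Endmember reflectance curves
#'
#' Smooth reference spectra used by the scene simulator and, averaged over
#' regions of interest, by the spectral angle mapper. The rice canopy curve has
#' low visible reflectance with a green bump near 550 nm, a red-edge rise near
#' 700 nm and a high near-infrared plateau; the stem curve is brighter in the
#' visible and flatter in the NIR (exposed stems after lodging); soil is a
#' gentle monotone slope. The shapes reproduce the qualitative rice/soil
#' separation seen in canopy spectroscopy without claiming radiative-transfer
#' realism.
#'
#' @param wavelengths_nm numeric vector of band-center wavelengths (nm).
#' @return numeric vector of reflectances (unitless, nominal 0--1), one per
#'   wavelength.
#' @examples
#' wl <- default_wavelengths()
#' plot(wl, rice_canopy_spectrum(wl), type = "l", ylim = c(0, 0.6))
#' lines(wl, soil_spectrum(wl), lty = 2)
#' @export
rice_canopy_spectrum <- function(wavelengths_nm) {
  0.04 +
    0.05 * exp(-((wavelengths_nm - 550) / 35)^2) +
    0.45 * stats::plogis((wavelengths_nm - 718) / 11)
}

#' @rdname rice_canopy_spectrum
#' @export
rice_stem_spectrum <- function(wavelengths_nm) {
  0.10 + 0.00025 * (wavelengths_nm - 400) +
    0.15 * stats::plogis((wavelengths_nm - 730) / 25)
}

#' @rdname rice_canopy_spectrum
#' @export
soil_spectrum <- function(wavelengths_nm) {
  0.15 + 0.00042 * (wavelengths_nm - 400)
}

#' Default band-center wavelengths
#'
#' Evenly spaced band centers spanning the sensor's 400--1000 nm range.
#'
#' @param n_bands number of spectral bands (default 176).
#' @param range_nm two-element numeric, first and last band center.
#' @return strictly increasing numeric vector of length `n_bands`.
#' @export
default_wavelengths <- function(n_bands = 176, range_nm = c(400, 1000)) {
  stopifnot_scalar_number(n_bands, "n_bands", lower = 2)
  if (length(range_nm) != 2L || range_nm[2] <= range_nm[1]) {
    stop("`range_nm` must be an increasing pair", call. = FALSE)
  }
  seq(range_nm[1], range_nm[2], length.out = n_bands)
}

#' Mix canopy and stem spectra to emulate lodging
#'
#' When a plot lodges, the sensor records radiation from both the leaf canopy
#' and the exposed stems. This is modelled as a per-band convex combination
#' `(1 - alpha) * canopy + alpha * stem`.
#'
#' @param canopy,stem numeric reflectance vectors of equal length.
#' @param alpha mixing weight in \[0, 1\]; 0 returns the canopy unchanged,
#'   1 returns the stem spectrum.
#' @return numeric vector, the mixed spectrum.
#' @examples
#' apply_lodging_effect(c(0.2, 0.6), c(0.4, 0.2), 0.5) # c(0.3, 0.4)
#' @export
apply_lodging_effect <- function(canopy, stem, alpha) {
  if (length(canopy) != length(stem)) {
    stop("`canopy` and `stem` must have the same number of bands", call. = FALSE)
  }
  stopifnot_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  (1 - alpha) * canopy + alpha * stem
}
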