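#' Bundled hemoglobin extinction spectra
#'
#' Molar (decadic) extinction coefficients of deoxy- (HbR) and
#' oxy-hemoglobin (HbO2) in 1/(cm.M) at near-infrared wavelengths, from a
#' standard compiled tabulation (values rounded at the source's precision).
#' The absorption coefficient of whole blood follows as
#' `mua = log(10) * (eps_hbr * cHbR + eps_hbo2 * cHbO2)` with concentrations
#' in mol/L. Oxygen-saturation estimates are invariant to the decadic/natural
#' log convention because it rescales both chromophore columns equally.
#'
#' @return data frame with `wavelength` (nm), `eps_hbr`, `eps_hbo2`
#'   (1/(cm.M)).
#' @export
hb_spectra <- function() {
  utils::read.table(system.file("extdata", "hb_extinction.tsv",
                                package = "paflux"),
                    header = TRUE, sep = "\t")
}

#' Extinction matrix for linear unmixing
#'
#' Builds the 2 x 2 chromophore matrix `A` with rows indexed by wavelength
#' and columns by chromophore `(HbR, HbO2)`, interpolated linearly from a
#' spectra table. For the default wavelengths (750, 850 nm), which straddle
#' the ~800 nm isosbestic point, the matrix satisfies
#' `A["750","HbR"] > A["750","HbO2"]` and `A["850","HbO2"] > A["850","HbR"]`.
#'
#' @param wavelengths numeric vector of wavelengths, nm (default c(750, 850)).
#' @param spectra spectra table as returned by [hb_spectra()]; users may
#'   supply their own table with the same columns.
#' @return numeric matrix with `length(wavelengths)` rows and columns
#'   `c("HbR", "HbO2")`.
#' @export
extinction_matrix <- function(wavelengths = c(750, 850), spectra = hb_spectra()) {
  stopifnot(length(wavelengths) >= 2)
  rng <- range(spectra$wavelength)
  if (any(wavelengths < rng[1] | wavelengths > rng[2])) {
    stop("requested wavelength outside the spectra table (",
         rng[1], "-", rng[2], " nm)")
  }
  A <- cbind(
    HbR = stats::approx(spectra$wavelength, spectra$eps_hbr, xout = wavelengths)$y,
    HbO2 = stats::approx(spectra$wavelength, spectra$eps_hbo2, xout = wavelengths)$y
  )
  rownames(A) <- as.character(wavelengths)
  if (any(A <= 0)) stop("extinction coefficients must be positive")
  A
}

#' Blood absorption coefficient from saturation and total hemoglobin
#'
#' @param so2 oxygen saturation, percent in `[0, 100]`.
#' @param thb total hemoglobin, g/L (converted with 64,500 g/mol).
#' @param wavelength nm.
#' @param spectra spectra table, see [hb_spectra()].
#' @return absorption coefficient, 1/cm.
#' @export
blood_mua <- function(so2, thb = 150, wavelength = 750, spectra = hb_spectra()) {
  stopifnot(so2 >= 0, so2 <= 100, thb > 0)
  rng <- range(spectra$wavelength)
  if (wavelength < rng[1] || wavelength > rng[2]) {
    stop("wavelength outside the spectra table")
  }
  c_tot <- thb / 64500                      # mol/L
  e_hbr <- stats::approx(spectra$wavelength, spectra$eps_hbr, xout = wavelength)$y
  e_hbo2 <- stats::approx(spectra$wavelength, spectra$eps_hbo2, xout = wavelength)$y
  log(10) * (e_hbr * c_tot * (1 - so2 / 100) + e_hbo2 * c_tot * so2 / 100)
}
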