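## Photolysis rate coefficients: j = integral over wavelength of
## sigma(lambda) * phi(lambda) * F(lambda), in s^-1. Union-grid trapezoid
## with linear interpolation; contributions outside any table's support are
## zero (no extrapolation).

#' Convert a spectrum to the wavelength axis
#'
#' @param spectrum a [Spectrum-class].
#' @return data.frame(wavelength_nm, sigma_cm2), increasing in wavelength.
#' @export
spectrumOnWavelength <- function(spectrum) {
  e <- energyGrid(spectrum)
  lam <- .const$hc_evnm / e
  o <- order(lam)
  data.frame(wavelength_nm = lam[o], sigma_cm2 = crossSection(spectrum)[o])
}

#' Photolysis rate coefficient
#'
#' \deqn{j = \int \sigma(\lambda)\,\phi(\lambda)\,F(\lambda)\,d\lambda}
#' by trapezoidal quadrature on the union of all input grids (restricted to
#' \code{lambdaRange} and the overlap of the three supports), with linear
#' interpolation of each factor. sigma is converted from the photon-energy
#' axis first.
#'
#' @param spectrum a [Spectrum-class] (cross-section, cm^2).
#' @param phi quantum-yield table: data.frame(wavelength_nm, value), e.g.
#'   from [readWavelengthTable()], or a single number for a constant yield.
#' @param flux actinic-flux table: data.frame(wavelength_nm, value) in
#'   photons cm^-2 s^-1 nm^-1.
#' @param lambdaRange optional c(min, max) wavelength window, nm.
#' @return j in s^-1.
#' @examples
#' sp <- Spectrum(seq(3.0, 4.5, 0.01), rep(1e-19, 151))
#' flux <- data.frame(wavelength_nm = c(300, 310), value = c(1e14, 1e14))
#' photolysisRate(sp, 1, flux, c(300, 310))  # 1e-4
#' @export
photolysisRate <- function(spectrum, phi, flux, lambdaRange = NULL) {
  sig <- spectrumOnWavelength(spectrum)
  if (is.numeric(phi) && length(phi) == 1)
    phi <- data.frame(wavelength_nm = range(sig$wavelength_nm),
                      value = c(phi, phi))
  lo <- max(min(sig$wavelength_nm), min(phi$wavelength_nm),
            min(flux$wavelength_nm))
  hi <- min(max(sig$wavelength_nm), max(phi$wavelength_nm),
            max(flux$wavelength_nm))
  if (!is.null(lambdaRange)) {
    lo <- max(lo, lambdaRange[1])
    hi <- min(hi, lambdaRange[2])
  }
  if (lo >= hi)
    stop("no wavelength overlap between cross-section, yield and flux")
  grid <- sort(unique(c(
    lo, hi,
    sig$wavelength_nm[sig$wavelength_nm >= lo & sig$wavelength_nm <= hi],
    phi$wavelength_nm[phi$wavelength_nm >= lo & phi$wavelength_nm <= hi],
    flux$wavelength_nm[flux$wavelength_nm >= lo & flux$wavelength_nm <= hi])))
  interp <- function(df, col) {
    stats::approx(df$wavelength_nm, df[[col]], xout = grid, rule = 1)$y
  }
  y <- interp(sig, "sigma_cm2") * interp(phi, "value") *
    interp(flux, "value")
  if (any(y < 0, na.rm = TRUE)) {
    warning("negative interpolated integrand values clipped at 0")
    y <- pmax(y, 0)
  }
  y[is.na(y)] <- 0
  sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
}
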