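## Physical constants (CODATA 2018) and the package's internal unit system.
##
## Internal units everywhere: length in Angstrom, mass in amu, energy in eV,
## time in fs, vibrational wavenumbers in cm^-1, cross-sections in cm^2.
## All conversions between these and SI go through this one table.

.si <- list(
  e      = 1.602176634e-19,    # elementary charge, C (exact)
  m_e    = 9.1093837015e-31,   # electron mass, kg
  eps0   = 8.8541878128e-12,   # vacuum permittivity, F/m
  c      = 2.99792458e8,       # speed of light, m/s (exact)
  h      = 6.62607015e-34,     # Planck constant, J s (exact)
  hbar   = 6.62607015e-34 / (2 * pi),
  k_B    = 1.380649e-23,       # Boltzmann constant, J/K (exact)
  amu    = 1.66053906660e-27,  # unified atomic mass unit, kg
  a0     = 5.29177210903e-11   # Bohr radius, m
)

## Derived constants in internal units.
.const <- local({
  hbar_evfs <- .si$hbar / .si$e * 1e15            # eV fs
  kb_ev     <- .si$k_B / .si$e                    # eV / K
  c_cmfs    <- .si$c * 1e2 * 1e-15                # cm / fs
  hc_evnm   <- .si$h * .si$c / .si$e * 1e9        # eV nm
  amu_evfs  <- .si$amu / .si$e * 1e10             # 1 amu in eV fs^2 / A^2
  bohr_A    <- .si$a0 * 1e10                      # Angstrom
  ## NEA cross-section prefactor K = pi e^2 hbar / (2 m_e c eps0), eV cm^2
  k_nea <- pi * .si$e^2 * .si$hbar /
    (2 * .si$m_e * .si$c * .si$eps0) / .si$e * 1e4
  list(hbar_evfs = hbar_evfs, kb_ev = kb_ev, c_cmfs = c_cmfs,
       hc_evnm = hc_evnm, amu_evfs = amu_evfs, bohr_A = bohr_A,
       k_nea = k_nea)
})

#' Physical constants used by the package
#'
#' Returns the CODATA 2018 constants and the derived quantities the package
#' uses internally, including the absolute cross-section prefactor
#' \eqn{K = \pi e^2 \hbar / (2 m_e c \epsilon_0)} in eV cm\eqn{^2}.
#'
#' @return A named list with two components: \code{si}, the SI-valued CODATA
#'   constants, and \code{internal}, the derived constants in the package unit
#'   system (Angstrom, amu, eV, fs, cm\eqn{^{-1}}): \code{hbar_evfs} (eV fs),
#'   \code{kb_ev} (eV/K), \code{c_cmfs} (cm/fs), \code{hc_evnm} (eV nm),
#'   \code{amu_evfs} (1 amu expressed in eV fs\eqn{^2}/Angstrom\eqn{^2}),
#'   \code{bohr_A} (Angstrom) and \code{k_nea} (eV cm\eqn{^2}).
#'
#' @examples
#' physicalConstants()$internal$k_nea   # ~1.0975e-16 eV cm^2
#' @export
physicalConstants <- function() {
  list(si = .si, internal = .const)
}

#' Convert between vibrational wavenumber and angular frequency
#'
#' \code{omegaFromWavenumber} maps a wavenumber in cm\eqn{^{-1}} to an angular
#' frequency \eqn{\omega = 2\pi c \tilde\nu} in fs\eqn{^{-1}};
#' \code{wavenumberFromOmega} is its inverse.
#'
#' @param nu_cm wavenumber(s), cm^-1.
#' @param omega angular frequency(ies), fs^-1.
#' @return Numeric vector in the target unit.
#' @export
omegaFromWavenumber <- function(nu_cm) 2 * pi * .const$c_cmfs * nu_cm

#' @rdname omegaFromWavenumber
#' @export
wavenumberFromOmega <- function(omega) omega / (2 * pi * .const$c_cmfs)

## Standard atomic weights (amu), common elements; CIAAW 2021 abridged values.
.atomic_masses <- c(
  H = 1.008, D = 2.014, He = 4.002602,
  Li = 6.94, Be = 9.0121831, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403163, Ne = 20.1797, Na = 22.98976928, Mg = 24.305,
  Al = 26.9815384, Si = 28.085, P = 30.973761998, S = 32.06, Cl = 35.45,
  Ar = 39.95, K = 39.0983, Ca = 40.078, Ti = 47.867, Cr = 51.9961,
  Mn = 54.938043, Fe = 55.845, Ni = 58.6934, Cu = 63.546, Zn = 65.38,
  Br = 79.904, Kr = 83.798, I = 126.90447, Xe = 131.293,
  ## model-system pseudo-atoms: X is a generic heavy site
  X = 16.0
)

#' Standard atomic mass lookup
#'
#' @param symbols character vector of element symbols (plus the pseudo-atom
#'   \code{"X"} used by the bundled model systems).
#' @return Numeric vector of masses in amu.
#' @export
atomicMass <- function(symbols) {
  m <- .atomic_masses[symbols]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
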