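## Harmonic Wigner sampling of the vibrational ground state. For each mode i
## with angular frequency omega_i the ground-state (or thermal) Wigner
## distribution is a Gaussian in the mass-weighted normal coordinate Q_i and
## conjugate momentum P_i:
##   Var(Q_i) = (hbar / 2 omega_i) coth(hbar omega_i / 2 kT)
##   Var(P_i) = (hbar omega_i / 2)  coth(hbar omega_i / 2 kT)
## with the coth factor equal to 1 at T = 0. Cartesian members are built by
## the rectilinear back-transform x = x_ref + M^(-1/2) L Q. The rectilinear
## limitation is retained deliberately (no curvilinear correction): it is
## the mechanism behind the torsion-sampling artifact that mode exclusion
## mitigates.

#' Settings for Wigner sampling
#'
#' @param nSamples number of geometries to draw (default 500).
#' @param temperature sampling temperature in K (default 0 = ground-state
#'   Wigner distribution).
#' @param excludedModes integer indices (into the NormalModeSet, ascending
#'   frequency order) of modes to freeze: their Q and P are exactly 0.
#' @param seed RNG seed (mandatory: stochastic steps never self-seed).
#' @param sampleMomenta also draw momenta (default TRUE).
#' @return A validated list of settings.
#' @export
WignerSettings <- function(nSamples = 500, temperature = 0,
                           excludedModes = integer(), seed,
                           sampleMomenta = TRUE) {
  if (missing(seed)) stop("a seed is required for Wigner sampling")
  stopifnot(nSamples >= 1, temperature >= 0)
  list(nSamples = as.integer(nSamples), temperature = temperature,
       excludedModes = as.integer(excludedModes), seed = as.integer(seed),
       sampleMomenta = isTRUE(sampleMomenta))
}

## coth with a large-argument guard
.coth <- function(x) ifelse(x > 350, 1, 1 / tanh(x))

## Wigner standard deviations per mode: Q in amu^0.5 A, P in amu^0.5 A/fs.
.wigner_sd <- function(nu_cm, temperature) {
  omega <- omegaFromWavenumber(nu_cm)                 # fs^-1
  hbar_int <- .const$hbar_evfs / .const$amu_evfs     # amu A^2 / fs
  cothf <- if (temperature > 0) {
    .coth(.const$hbar_evfs * omega / (2 * .const$kb_ev * temperature))
  } else rep(1, length(omega))
  list(sdQ = sqrt(hbar_int / (2 * omega) * cothf),
       sdP = sqrt(hbar_int * omega / 2 * cothf))
}

#' Sample a geometry ensemble from the harmonic Wigner distribution
#'
#' Draws \code{nSamples} nuclear configurations (and momenta) from the
#' harmonic Wigner distribution of the vibrational ground state at the
#' requested temperature. Excluded modes are frozen exactly (zero
#' displacement and momentum); imaginary (negative) frequencies among the
#' non-excluded modes abort the sampling, since the Wigner distribution is
#' undefined for them.
#'
#' @param modes a [NormalModeSet-class].
#' @param settings a [WignerSettings()] list.
#' @param conformerLabel label recorded on the ensemble for downstream
#'   Boltzmann weighting.
#' @return A [GeometryEnsemble-class]; \code{normalCoordinates()} holds the
#'   sampled Q matrix (n_samples x n_modes, amu^0.5 A).
#' @examples
#' g <- Geometry(c("H", "Cl"), rbind(c(0, 0, 0), c(1.27, 0, 0)))
#' k <- 30
#' H <- matrix(0, 6, 6); H[1, 1] <- H[4, 4] <- k; H[1, 4] <- H[4, 1] <- -k
#' nm <- normalModeAnalysis(HessianMatrix(H, g))
#' ens <- sampleWigner(nm, WignerSettings(nSamples = 100, seed = 1))
#' nMembers(ens)
#' @export
sampleWigner <- function(modes, settings, conformerLabel = "") {
  stopifnot(is(modes, "NormalModeSet"))
  nu <- frequencies(modes)
  nm <- length(nu)
  excl <- settings$excludedModes
  if (length(excl) && (any(excl < 1) || any(excl > nm)))
    stop("excluded mode indices out of range 1..", nm)
  active <- setdiff(seq_len(nm), excl)
  if (any(nu[active] < 0))
    stop("imaginary frequencies among non-excluded modes: ",
         paste(which(nu < 0 & seq_len(nm) %in% active), collapse = ", "),
         "; sampling refused")
  ns <- settings$nSamples
  sd <- .wigner_sd(nu[active], settings$temperature)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(settings$seed)

  Q <- matrix(0, ns, nm)
  P <- matrix(0, ns, nm)
  if (length(active)) {
    Q[, active] <- sweep(matrix(stats::rnorm(ns * length(active)), ns),
                         2, sd$sdQ, `*`)
    if (settings$sampleMomenta)
      P[, active] <- sweep(matrix(stats::rnorm(ns * length(active)), ns),
                           2, sd$sdP, `*`)
  }
  ref <- modes@geometry
  n <- nAtoms(ref)
  invsqrt_m3 <- 1 / sqrt(rep(atomicMasses(ref), each = 3))
  L <- modeVectors(modes)
  ## Cartesian displacements: columns are members
  disp <- (L %*% t(Q)) * invsqrt_m3            # 3n x ns
  x0 <- as.vector(t(coordinates(ref)))         # x1 y1 z1 x2 ...
  coords <- array(0, dim = c(n, 3, ns))
  for (k in seq_len(ns))
    coords[, , k] <- matrix(x0 + disp[, k], ncol = 3, byrow = TRUE)
  new("GeometryEnsemble", reference = ref, coords = coords,
      normalCoords = Q,
      momenta = if (settings$sampleMomenta) P else NULL,
      provenance = list(sampler = "wigner", settings = settings),
      conformerLabel = conformerLabel)
}

#' Quantum vs classical width ratio per mode
#'
#' Diagnostic for the failure of thermal (Boltzmann) sampling to recover
#' zero-point width: returns the ratio of the quantum to the classical
#' harmonic position variance per mode,
#' \eqn{(\hbar\omega / 2 k_B T)\,\coth(\hbar\omega / 2 k_B T)},
#' which is >= 1 always and tends to 1 in the classical limit
#' \eqn{\hbar\omega \ll k_B T}.
#'
#' @param modes a [NormalModeSet-class] (or numeric wavenumbers, cm^-1).
#' @param temperature temperature in K, > 0.
#' @return Numeric vector of variance ratios, one per mode.
#' @export
classicalLimitCheck <- function(modes, temperature) {
  if (temperature <= 0)
    stop("classical variance undefined at T = 0; temperature must be > 0")
  nu <- if (is(modes, "NormalModeSet")) frequencies(modes)
        else as.numeric(modes)
  x <- .const$hbar_evfs * omegaFromWavenumber(nu) /
    (2 * .const$kb_ev * temperature)
  x * .coth(x)
}
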