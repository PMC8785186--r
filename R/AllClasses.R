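## S4 classes for the central data objects. Validity methods enforce the
## structural invariants; users construct objects through the exported
## constructors, which normalize inputs and fill defaults.

#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Geometry: one molecular configuration
#'
#' Holds a single nuclear configuration: element symbols, Cartesian
#' coordinates in Angstrom, atomic masses in amu and a free-text label used
#' for provenance (conformer id, trajectory frame index, ...).
#'
#' @slot symbols character vector of element symbols.
#' @slot coords numeric matrix, n_atoms x 3, Angstrom.
#' @slot masses numeric vector, amu, strictly positive.
#' @slot label character scalar.
#' @aliases Geometry
#' @exportClass Geometry
setClass("Geometry",
  representation(symbols = "character", coords = "matrix",
                 masses = "numeric", label = "character"),
  prototype(label = ""))

setValidity("Geometry", function(object) {
  msg <- character()
  n <- length(object@symbols)
  if (!is.numeric(object@coords) || !identical(dim(object@coords), c(n, 3L)))
    msg <- c(msg, "coords must be a numeric n_atoms x 3 matrix")
  if (length(object@masses) != n)
    msg <- c(msg, "one mass per atom required")
  if (any(!is.finite(object@masses)) || any(object@masses <= 0))
    msg <- c(msg, "masses must be finite and strictly positive")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(object@label) != 1)
    msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a Geometry
#'
#' @param symbols element symbols (see [atomicMass()] for the known set).
#' @param coords n x 3 numeric matrix of Cartesian coordinates, Angstrom.
#' @param masses atomic masses in amu; defaults to standard atomic weights.
#' @param label provenance tag.
#' @return A [Geometry-class] object.
#' @examples
#' g <- Geometry(c("O", "H"), rbind(c(0, 0, 0), c(0.96, 0, 0)))
#' nAtoms(g)
#' @export
Geometry <- function(symbols, coords, masses = atomicMass(symbols),
                     label = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  new("Geometry", symbols = as.character(symbols), coords = coords,
      masses = as.numeric(masses), label = as.character(label))
}

#' Cartesian Hessian of the potential energy
#'
#' Second derivatives of the energy with respect to Cartesian coordinates,
#' eV / Angstrom^2 (mass-free). Symmetrized on construction; a flag records
#' whether the translation/rotation subspace has been projected out.
#'
#' @slot values 3n x 3n numeric matrix, eV/A^2 (or eV/(A^2 amu) once
#'   mass-weighted).
#' @slot geometry the [Geometry-class] the Hessian was evaluated at.
#' @slot massWeighted logical, TRUE after mass weighting.
#' @slot projected logical, TRUE after Eckart projection.
#' @exportClass HessianMatrix
setClass("HessianMatrix",
  representation(values = "matrix", geometry = "Geometry",
                 massWeighted = "logical", projected = "logical"),
  prototype(massWeighted = FALSE, projected = FALSE))

setValidity("HessianMatrix", function(object) {
  n3 <- 3L * nAtoms(object@geometry)
  if (!identical(dim(object@values), c(n3, n3)))
    return("Hessian dimension must be 3 n_atoms, matching the geometry")
  asym <- max(abs(object@values - t(object@values)))
  scale <- max(abs(object@values), 1e-300)
  if (asym > 1e-6 * scale)
    return("Hessian must be symmetric")
  TRUE
})

#' Construct a HessianMatrix
#'
#' The input matrix is symmetrized as (H + t(H))/2; an asymmetry larger than
#' 1e-8 (relative) is rejected.
#'
#' @param values 3n x 3n matrix of second derivatives, eV/A^2.
#' @param geometry the [Geometry-class] at which they were evaluated.
#' @param massWeighted,projected bookkeeping flags, normally left FALSE.
#' @return A [HessianMatrix-class].
#' @export
HessianMatrix <- function(values, geometry, massWeighted = FALSE,
                          projected = FALSE) {
  values <- as.matrix(values)
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8 * max(abs(values), 1e-300))
    stop("Hessian asymmetry ", format(asym), " exceeds tolerance")
  new("HessianMatrix", values = (values + t(values)) / 2, geometry = geometry,
      massWeighted = massWeighted, projected = projected)
}

#' Harmonic normal modes of the ground-state surface
#'
#' Frequencies (wavenumbers, cm^-1; imaginary encoded as negative) and
#' orthonormal mass-weighted displacement vectors, sorted by increasing
#' frequency. This is the harmonic model behind Wigner sampling.
#'
#' @slot frequencies numeric, cm^-1, ascending; negative = imaginary.
#' @slot modes 3n x n_modes matrix; columns are orthonormal mass-weighted
#'   displacement vectors.
#' @slot geometry reference [Geometry-class].
#' @slot reducedMasses numeric, amu (reporting only); inverse-participation
#'   convention \eqn{\mu_i = (\sum_j L_{ij}^2 / m_j)^{-1}} over the
#'   mass-weighted components, which reduces to the atomic mass for a
#'   homonuclear diatomic stretch.
#' @exportClass NormalModeSet
setClass("NormalModeSet",
  representation(frequencies = "numeric", modes = "matrix",
                 geometry = "Geometry", reducedMasses = "numeric"))

setValidity("NormalModeSet", function(object) {
  msg <- character()
  nm <- length(object@frequencies)
  n3 <- 3L * nAtoms(object@geometry)
  if (!identical(dim(object@modes), c(n3, nm)))
    msg <- c(msg, "modes must be 3n x n_modes")
  if (is.unsorted(object@frequencies))
    msg <- c(msg, "frequencies must be sorted ascending")
  if (nm > 0) {
    gram <- crossprod(object@modes)
    if (max(abs(gram - diag(nm))) > 1e-8)
      msg <- c(msg, "mode vectors must be orthonormal to 1e-8")
  }
  if (length(object@reducedMasses) != nm)
    msg <- c(msg, "one reduced mass per mode required")
  if (length(msg)) msg else TRUE
})

#' Ensemble of sampled nuclear configurations
#'
#' Stores sampled geometries compactly as an n_atoms x 3 x n_samples array of
#' coordinates sharing the reference geometry's atoms and masses, together
#' with the per-member normal-coordinate displacements (mass-weighted,
#' amu^(1/2) Angstrom), optional momenta, sampler provenance and a conformer
#' label used for Boltzmann weighting downstream.
#'
#' @slot reference the reference [Geometry-class] (defines atoms and masses).
#' @slot coords array n_atoms x 3 x n_samples, Angstrom.
#' @slot normalCoords n_samples x n_modes matrix of mode displacements
#'   (amu^0.5 A), or NULL when not applicable.
#' @slot momenta n_samples x n_modes matrix of mode momenta
#'   (amu^0.5 A / fs), or NULL.
#' @slot provenance list: sampler name, settings, seed.
#' @slot conformerLabel character scalar.
#' @exportClass GeometryEnsemble
setClass("GeometryEnsemble",
  representation(reference = "Geometry", coords = "array",
                 normalCoords = "matrixOrNULL", momenta = "matrixOrNULL",
                 provenance = "list", conformerLabel = "character"),
  prototype(normalCoords = NULL, momenta = NULL, provenance = list(),
            conformerLabel = ""))

setValidity("GeometryEnsemble", function(object) {
  msg <- character()
  d <- dim(object@coords)
  n <- nAtoms(object@reference)
  if (length(d) != 3 || d[1] != n || d[2] != 3)
    msg <- c(msg, "coords must be an n_atoms x 3 x n_samples array")
  if (!is.null(object@normalCoords) && nrow(object@normalCoords) != d[3])
    msg <- c(msg, "normalCoords must have one row per member")
  if (!is.null(object@momenta) && nrow(object@momenta) != d[3])
    msg <- c(msg, "momenta must have one row per member")
  if (length(msg)) msg else TRUE
})

#' Table of vertical electronic transitions
#'
#' One row per (geometry, state): vertical excitation energy Delta E_0J in eV
#' and dimensionless oscillator strength f_0J, for each sampled nuclear
#' configuration.
#'
#' @slot records data.frame with columns \code{geometry_id} (character),
#'   \code{state} (integer >= 1), \code{delta_E_eV} (> 0),
#'   \code{osc_strength} (>= 0).
#' @exportClass TransitionTable
setClass("TransitionTable", representation(records = "data.frame"))

setValidity("TransitionTable", function(object) {
  df <- object@records
  need <- c("geometry_id", "state", "delta_E_eV", "osc_strength")
  if (!all(need %in% names(df)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  bad <- which(!is.finite(df$delta_E_eV) | df$delta_E_eV <= 0 |
               !is.finite(df$osc_strength) | df$osc_strength < 0 |
               df$state < 1)
  if (length(bad))
    return(paste("invalid transition rows (need delta_E_eV > 0,",
                 "osc_strength >= 0, state >= 1):",
                 paste(utils::head(bad, 10), collapse = ", ")))
  if (anyDuplicated(df[c("geometry_id", "state")]))
    return("duplicated (geometry_id, state) pairs")
  TRUE
})

#' Construct a TransitionTable
#'
#' @param geometry_id character ids referencing ensemble members.
#' @param state integer state index J >= 1.
#' @param delta_E_eV vertical excitation energies, eV (> 0).
#' @param osc_strength oscillator strengths (>= 0).
#' @return A [TransitionTable-class].
#' @export
TransitionTable <- function(geometry_id, state, delta_E_eV, osc_strength) {
  new("TransitionTable", records = data.frame(
    geometry_id = as.character(geometry_id),
    state = as.integer(state),
    delta_E_eV = as.numeric(delta_E_eV),
    osc_strength = as.numeric(osc_strength),
    stringsAsFactors = FALSE))
}

#' Lineshape used to broaden vertical transitions
#'
#' Unit-normalized lineshape on the energy axis; \code{delta} is the full
#' width at half maximum in eV.
#'
#' @slot kind "lorentzian" or "gaussian".
#' @slot delta FWHM, eV, > 0.
#' @exportClass LineShapeSpec
setClass("LineShapeSpec",
  representation(kind = "character", delta = "numeric"),
  prototype(kind = "lorentzian", delta = 0.05))

setValidity("LineShapeSpec", function(object) {
  if (!object@kind %in% c("lorentzian", "gaussian"))
    return("kind must be 'lorentzian' or 'gaussian'")
  if (length(object@delta) != 1 || !is.finite(object@delta) ||
      object@delta <= 0)
    return("delta (FWHM, eV) must be a single positive number")
  TRUE
})

#' @param kind "lorentzian" (default) or "gaussian".
#' @param delta FWHM in eV (default 0.05).
#' @rdname LineShapeSpec-class
#' @export
LineShapeSpec <- function(kind = "lorentzian", delta = 0.05) {
  new("LineShapeSpec", kind = kind, delta = delta)
}

#' Absolute photoabsorption cross-section on an energy grid
#'
#' @slot energy photon energies, eV, strictly increasing.
#' @slot sigma cross-section, cm^2 molecule^-1, >= 0.
#' @slot metadata list (N_p, states, lineshape, conformer weights, ...).
#' @exportClass Spectrum
setClass("Spectrum",
  representation(energy = "numeric", sigma = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@energy) != length(object@sigma))
    msg <- c(msg, "energy and sigma must have equal length")
  if (length(object@energy) == 0)
    msg <- c(msg, "spectrum must not be empty")
  if (length(object@energy) > 1 && any(diff(object@energy) <= 0))
    msg <- c(msg, "energy grid must be strictly increasing")
  if (any(object@sigma < 0))
    msg <- c(msg, "sigma must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param energy strictly increasing photon-energy grid, eV.
#' @param sigma cross-section values, cm^2 molecule^-1.
#' @param metadata optional provenance list.
#' @return A [Spectrum-class].
#' @export
Spectrum <- function(energy, sigma, metadata = list()) {
  new("Spectrum", energy = as.numeric(energy), sigma = as.numeric(sigma),
      metadata = metadata)
}

#' Generalized Langevin thermostat parameters
#'
#' Drift matrix A ((Ns+1) x (Ns+1), fs^-1) and stationary covariance C
#' ((Ns+1) x (Ns+1), eV) in the GLE4MD convention: the first row/column
#' couples to the (mass-scaled) physical momentum, the remaining Ns to
#' auxiliary momenta.
#'
#' @slot A drift matrix, fs^-1.
#' @slot C stationary covariance, eV; symmetric positive definite.
#' @slot ns number of auxiliary momenta (= dim - 1).
#' @slot temperature target temperature, K.
#' @slot classicalC TRUE when C was defaulted to kT * I (classical
#'   canonical sampling).
#' @exportClass GLEParameters
setClass("GLEParameters",
  representation(A = "matrix", C = "matrix", ns = "integer",
                 temperature = "numeric", classicalC = "logical"),
  prototype(classicalC = FALSE))

setValidity("GLEParameters", function(object) {
  msg <- character()
  d <- dim(object@A)
  if (d[1] != d[2]) msg <- c(msg, "A must be square")
  if (!identical(dim(object@C), d))
    msg <- c(msg, "C must have the same dimension as A")
  if (object@ns != d[1] - 1L)
    msg <- c(msg, "ns must equal dim(A) - 1")
  if (max(abs(object@C - t(object@C))) > 1e-10 * max(abs(object@C), 1e-300))
    msg <- c(msg, "C must be symmetric")
  else if (min(eigen((object@C + t(object@C)) / 2,
                     symmetric = TRUE, only.values = TRUE)$values) <= 0)
    msg <- c(msg, "C must be positive definite")
  if (object@temperature <= 0)
    msg <- c(msg, "temperature must be positive")
  if (length(msg)) msg else TRUE
})

#' Analytic potential-energy surface contract
#'
#' Wraps an energy function (eV) and its gradient (eV/Angstrom per Cartesian
#' component), both taking an n x 3 coordinate matrix. Stands in for an
#' external electronic-structure engine.
#'
#' @slot energy function(coords) -> eV.
#' @slot gradient function(coords) -> n x 3 matrix, eV/A.
#' @slot descriptor list: kind and parameters.
#' @slot reference equilibrium [Geometry-class] (atom layout).
#' @exportClass PotentialSurface
setClass("PotentialSurface",
  representation(energy = "function", gradient = "function",
                 descriptor = "list", reference = "Geometry"))

#' Quantum-thermostat MD trajectory
#'
#' @slot frames array n_atoms x 3 x n_frames of stored snapshots, Angstrom.
#' @slot velocities array n_atoms x 3 x n_frames, Angstrom/fs.
#' @slot kineticTemperature per-step kinetic temperature, K (length n_steps).
#' @slot potentialEnergy per-step potential energy, eV (length n_steps).
#' @slot frameSteps integer step index of each stored frame.
#' @slot settings list of run settings (dt, stride, seed, ...).
#' @slot reference starting [Geometry-class].
#' @exportClass Trajectory
setClass("Trajectory",
  representation(frames = "array", velocities = "array",
                 kineticTemperature = "numeric", potentialEnergy = "numeric",
                 frameSteps = "integer", settings = "list",
                 reference = "Geometry"))

#' Boltzmann weights of conformers
#'
#' @slot labels conformer labels.
#' @slot energies relative energies, eV (zero at the minimum).
#' @slot temperature K.
#' @slot weights normalized Boltzmann factors, sum to 1.
#' @exportClass ConformerWeights
setClass("ConformerWeights",
  representation(labels = "character", energies = "numeric",
                 temperature = "numeric", weights = "numeric"))

setValidity("ConformerWeights", function(object) {
  msg <- character()
  k <- length(object@labels)
  if (length(object@energies) != k || length(object@weights) != k)
    msg <- c(msg, "labels, energies and weights must have equal length")
  if (abs(sum(object@weights) - 1) > 1e-10)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})
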