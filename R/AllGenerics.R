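## Generics and accessors. Slot access from user code should go through
## these, never through @.

#' Number of atoms
#' @param x a Geometry, HessianMatrix, GeometryEnsemble or Trajectory.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn nAtoms atoms of a single geometry.
setMethod("nAtoms", "Geometry", function(x) length(x@symbols))

#' @describeIn nAtoms atoms of the geometry the Hessian belongs to.
setMethod("nAtoms", "HessianMatrix", function(x) nAtoms(x@geometry))

#' @describeIn nAtoms atoms of the ensemble's reference geometry.
setMethod("nAtoms", "GeometryEnsemble", function(x) nAtoms(x@reference))

#' @describeIn nAtoms atoms of the trajectory's reference geometry.
setMethod("nAtoms", "Trajectory", function(x) nAtoms(x@reference))

#' Cartesian coordinates
#' @param x a Geometry.
#' @return n x 3 numeric matrix, Angstrom.
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' @describeIn coordinates coordinates of a geometry.
setMethod("coordinates", "Geometry", function(x) x@coords)

#' Element symbols
#' @param x a Geometry or GeometryEnsemble.
#' @return character vector.
#' @export
setGeneric("elementSymbols", function(x) standardGeneric("elementSymbols"))

#' @describeIn elementSymbols symbols of a geometry.
setMethod("elementSymbols", "Geometry", function(x) x@symbols)

#' @describeIn elementSymbols symbols of the ensemble reference.
setMethod("elementSymbols", "GeometryEnsemble",
          function(x) x@reference@symbols)

#' Atomic masses (amu)
#' @param x a Geometry or GeometryEnsemble.
#' @return numeric vector, amu.
#' @export
setGeneric("atomicMasses", function(x) standardGeneric("atomicMasses"))

#' @describeIn atomicMasses masses of a geometry.
setMethod("atomicMasses", "Geometry", function(x) x@masses)

#' @describeIn atomicMasses masses of the ensemble reference.
setMethod("atomicMasses", "GeometryEnsemble", function(x) x@reference@masses)

#' Provenance label
#' @param x a Geometry or GeometryEnsemble.
#' @return character scalar.
#' @export
setGeneric("geometryLabel", function(x) standardGeneric("geometryLabel"))

#' @describeIn geometryLabel label of a geometry.
setMethod("geometryLabel", "Geometry", function(x) x@label)

#' @describeIn geometryLabel conformer label of an ensemble.
setMethod("geometryLabel", "GeometryEnsemble", function(x) x@conformerLabel)

#' Vibrational frequencies (cm^-1)
#' @param x a NormalModeSet.
#' @return numeric vector of wavenumbers, ascending; negative = imaginary.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @describeIn frequencies frequencies of a normal-mode set.
setMethod("frequencies", "NormalModeSet", function(x) x@frequencies)

#' Mass-weighted normal-mode vectors
#' @param x a NormalModeSet.
#' @return 3n x n_modes matrix with orthonormal columns.
#' @export
setGeneric("modeVectors", function(x) standardGeneric("modeVectors"))

#' @describeIn modeVectors vectors of a normal-mode set.
setMethod("modeVectors", "NormalModeSet", function(x) x@modes)

#' Number of members / samples
#' @param x a GeometryEnsemble or Trajectory.
#' @return integer count.
#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))

#' @describeIn nMembers sampled configurations in an ensemble.
setMethod("nMembers", "GeometryEnsemble", function(x) dim(x@coords)[3])

#' @describeIn nMembers stored frames in a trajectory.
setMethod("nMembers", "Trajectory", function(x) dim(x@frames)[3])

#' Extract ensemble members as Geometry objects
#'
#' @param x a GeometryEnsemble.
#' @param i member indices (default: all).
#' @return A list of [Geometry-class] objects labelled
#'   "<conformerLabel>:<index>".
#' @export
setGeneric("members", function(x, i = NULL) standardGeneric("members"))

#' @describeIn members materialize members of an ensemble.
setMethod("members", "GeometryEnsemble", function(x, i = NULL) {
  if (is.null(i)) i <- seq_len(nMembers(x))
  ref <- x@reference
  lab <- if (nzchar(x@conformerLabel)) paste0(x@conformerLabel, ":") else ""
  lapply(i, function(k) {
    Geometry(ref@symbols, x@coords[, , k, drop = TRUE], ref@masses,
             label = paste0(lab, k))
  })
})

#' Coordinate array of an ensemble
#' @param x a GeometryEnsemble or Trajectory.
#' @return n_atoms x 3 x n array, Angstrom.
#' @export
setGeneric("coordinateArray", function(x) standardGeneric("coordinateArray"))

#' @describeIn coordinateArray coordinates of all ensemble members.
setMethod("coordinateArray", "GeometryEnsemble", function(x) x@coords)

#' @describeIn coordinateArray coordinates of all stored frames.
setMethod("coordinateArray", "Trajectory", function(x) x@frames)

#' Normal-coordinate displacements of an ensemble
#' @param x a GeometryEnsemble.
#' @return n_samples x n_modes matrix (amu^0.5 Angstrom) or NULL.
#' @export
setGeneric("normalCoordinates",
           function(x) standardGeneric("normalCoordinates"))

#' @describeIn normalCoordinates displacements of an ensemble.
setMethod("normalCoordinates", "GeometryEnsemble", function(x) x@normalCoords)

#' Transition records as a data frame
#' @param x a TransitionTable.
#' @return data.frame(geometry_id, state, delta_E_eV, osc_strength).
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @describeIn records rows of a transition table.
setMethod("records", "TransitionTable", function(x) x@records)

#' Energy grid of a spectrum (eV)
#' @param x a Spectrum.
#' @return numeric vector.
#' @export
setGeneric("energyGrid", function(x) standardGeneric("energyGrid"))

#' @describeIn energyGrid grid of a spectrum.
setMethod("energyGrid", "Spectrum", function(x) x@energy)

#' Cross-section values (cm^2 molecule^-1)
#' @param x a Spectrum.
#' @return numeric vector.
#' @export
setGeneric("crossSection", function(x) standardGeneric("crossSection"))

#' @describeIn crossSection sigma of a spectrum.
setMethod("crossSection", "Spectrum", function(x) x@sigma)

#' Metadata list
#' @param x a Spectrum or GeometryEnsemble.
#' @return list.
#' @export
setGeneric("metadata", function(x) standardGeneric("metadata"))

#' @describeIn metadata metadata of a spectrum.
setMethod("metadata", "Spectrum", function(x) x@metadata)

#' @describeIn metadata provenance of an ensemble.
setMethod("metadata", "GeometryEnsemble", function(x) x@provenance)

#' Drift / covariance matrices of GLE parameters
#' @param x a GLEParameters object.
#' @return matrix (fs^-1 for the drift, eV for the covariance).
#' @export
setGeneric("driftMatrix", function(x) standardGeneric("driftMatrix"))

#' @describeIn driftMatrix drift matrix A.
setMethod("driftMatrix", "GLEParameters", function(x) x@A)

#' @rdname driftMatrix
#' @export
setGeneric("covarianceMatrix", function(x) standardGeneric("covarianceMatrix"))

#' @describeIn driftMatrix stationary covariance C.
setMethod("covarianceMatrix", "GLEParameters", function(x) x@C)

#' Kinetic-temperature series of a trajectory (K)
#' @param x a Trajectory.
#' @return numeric vector, one value per MD step.
#' @export
setGeneric("kineticTemperature",
           function(x) standardGeneric("kineticTemperature"))

#' @describeIn kineticTemperature series of a trajectory.
setMethod("kineticTemperature", "Trajectory",
          function(x) x@kineticTemperature)

#' Potential-energy series of a trajectory (eV)
#' @param x a Trajectory.
#' @return numeric vector, one value per MD step.
#' @export
setGeneric("potentialEnergySeries",
           function(x) standardGeneric("potentialEnergySeries"))

#' @describeIn potentialEnergySeries series of a trajectory.
setMethod("potentialEnergySeries", "Trajectory",
          function(x) x@potentialEnergy)

#' Conformer weights accessor
#' @param x a ConformerWeights object.
#' @return named numeric vector of normalized weights.
#' @export
setGeneric("normalizedWeights", function(x) standardGeneric("normalizedWeights"))

#' @describeIn normalizedWeights normalized Boltzmann weights.
setMethod("normalizedWeights", "ConformerWeights",
          function(x) stats::setNames(x@weights, x@labels))

## ---- show methods -------------------------------------------------------

setMethod("show", "Geometry", function(object) {
  cat("Geometry:", nAtoms(object), "atoms",
      if (nzchar(object@label)) paste0("[", object@label, "]") else "", "\n")
  cat("  elements:", paste(object@symbols, collapse = " "), "\n")
})

setMethod("show", "NormalModeSet", function(object) {
  f <- object@frequencies
  cat("NormalModeSet:", length(f), "modes,",
      nAtoms(object@geometry), "atoms\n")
  if (length(f)) {
    cat("  wavenumbers (cm^-1):",
        paste(sprintf("%.1f", f), collapse = ", "), "\n")
    if (any(f < 0)) cat("  NOTE: imaginary frequencies present (negative)\n")
  }
})

setMethod("show", "GeometryEnsemble", function(object) {
  cat("GeometryEnsemble:", nMembers(object), "members x",
      nAtoms(object), "atoms",
      if (nzchar(object@conformerLabel))
        paste0("[conformer ", object@conformerLabel, "]") else "", "\n")
  if (!is.null(object@provenance$sampler))
    cat("  sampler:", object@provenance$sampler, "\n")
})

setMethod("show", "TransitionTable", function(object) {
  df <- object@records
  cat("TransitionTable:", nrow(df), "records,",
      length(unique(df$geometry_id)), "geometries,",
      length(unique(df$state)), "state(s)\n")
})

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum:", length(object@energy), "points,",
      sprintf("%.3f..%.3f eV,", min(object@energy), max(object@energy)),
      sprintf("max sigma %.3e cm^2\n", max(object@sigma)))
})

setMethod("show", "GLEParameters", function(object) {
  cat("GLEParameters: Ns =", object@ns, ", target T =",
      object@temperature, "K",
      if (object@classicalC) "(classical C = kT I)" else "(colored noise)",
      "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@kineticTemperature), "steps,",
      nMembers(object), "stored frames,",
      sprintf("mean kinetic T %.1f K\n", mean(object@kineticTemperature)))
})

setMethod("show", "ConformerWeights", function(object) {
  cat("ConformerWeights at", object@temperature, "K:\n")
  print(round(stats::setNames(object@weights, object@labels), 4))
})

setMethod("show", "PotentialSurface", function(object) {
  cat("PotentialSurface:", object@descriptor$kind %||% "custom", "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
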