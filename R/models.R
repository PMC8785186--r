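## Analytic model systems standing in for a quantum-chemistry engine:
## potential surfaces with exact gradients, a torsion-stretch toy that
## reproduces the rectilinear-Wigner torsion artifact, a soft-intermolecular
## toy for microsolvation-like broadening, toy chromophores mapping geometry
## to vertical transitions, and finite-difference Hessians.

#' Construct a PotentialSurface
#'
#' @param energy function(coords_matrix) -> energy in eV.
#' @param gradient function(coords_matrix) -> n x 3 gradient, eV/A.
#' @param descriptor list with at least \code{kind}.
#' @param reference equilibrium [Geometry-class].
#' @return A [PotentialSurface-class].
#' @export
PotentialSurface <- function(energy, gradient, descriptor, reference) {
  new("PotentialSurface", energy = energy, gradient = gradient,
      descriptor = descriptor, reference = reference)
}

#' Potential energy / gradient evaluation
#' @param surface a [PotentialSurface-class].
#' @param geometry a [Geometry-class] or n x 3 coordinate matrix.
#' @return energy in eV / gradient matrix in eV/A.
#' @export
potentialEnergy <- function(surface, geometry) {
  x <- if (is(geometry, "Geometry")) coordinates(geometry) else geometry
  surface@energy(x)
}

#' @rdname potentialEnergy
#' @export
potentialGradient <- function(surface, geometry) {
  x <- if (is(geometry, "Geometry")) coordinates(geometry) else geometry
  surface@gradient(x)
}

#' Gradient consistency check
#'
#' Compares the analytic gradient against central finite differences of the
#' energy along random displacements. Part of the PotentialSurface contract:
#' every bundled potential passes this at 1e-5 relative.
#'
#' @param surface a [PotentialSurface-class].
#' @param geometry evaluation point (defaults to a perturbed reference).
#' @param nDirections number of random directions.
#' @param step finite-difference step, Angstrom.
#' @param seed RNG seed for the directions.
#' @return Maximum relative deviation over the tested directions.
#' @export
checkGradient <- function(surface, geometry = NULL, nDirections = 6,
                          step = 1e-5, seed = 42) {
  ref <- surface@reference
  set.seed(seed)
  ## default evaluation point: random (non-stationary) displacement
  x <- if (is.null(geometry)) {
    coordinates(ref) + 0.04 * matrix(stats::rnorm(3 * nAtoms(ref)),
                                     nAtoms(ref), 3)
  } else if (is(geometry, "Geometry")) coordinates(geometry) else geometry
  g <- surface@gradient(x)
  worst <- 0
  for (i in seq_len(nDirections)) {
    d <- matrix(stats::rnorm(length(x)), nrow(x))
    d <- d / sqrt(sum(d^2))
    num <- (surface@energy(x + step * d) -
            surface@energy(x - step * d)) / (2 * step)
    ana <- sum(g * d)
    scale <- max(abs(num), abs(ana), 1e-8)
    worst <- max(worst, abs(num - ana) / scale)
  }
  worst
}

#' Local geometry optimization
#'
#' BFGS minimization of a PotentialSurface starting from a given geometry;
#' used to verify that the embedded atom layouts of the model systems
#' reproduce their minimum-energy geometry.
#'
#' @param surface a [PotentialSurface-class].
#' @param start starting [Geometry-class] (default: the reference).
#' @param tol gradient tolerance, eV/A.
#' @return The optimized [Geometry-class].
#' @export
optimizeGeometry <- function(surface, start = NULL, tol = 1e-8) {
  g0 <- if (is.null(start)) surface@reference else start
  x0 <- as.vector(coordinates(g0))
  n <- nAtoms(g0)
  fn <- function(v) surface@energy(matrix(v, n, 3))
  gr <- function(v) as.vector(surface@gradient(matrix(v, n, 3)))
  opt <- stats::optim(x0, fn, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  Geometry(elementSymbols(g0), matrix(opt$par, n, 3), atomicMasses(g0),
           label = "optimized")
}

#' Finite-difference Cartesian Hessian
#'
#' Central differences of the analytic gradient, symmetrized.
#'
#' @param surface a [PotentialSurface-class].
#' @param geometry evaluation point, normally a minimum (default: the
#'   surface's reference geometry).
#' @param step displacement step, Angstrom (default 1e-3).
#' @return A [HessianMatrix-class], eV/A^2.
#' @export
finiteDifferenceHessian <- function(surface, geometry = NULL, step = 1e-3) {
  g0 <- if (is.null(geometry)) surface@reference else geometry
  x0 <- coordinates(g0)
  n3 <- 3L * nrow(x0)
  H <- matrix(0, n3, n3)
  for (j in seq_len(n3)) {
    xp <- x0; xp[j] <- xp[j] + step
    xm <- x0; xm[j] <- xm[j] - step
    gp <- as.vector(surface@gradient(xp))
    gm <- as.vector(surface@gradient(xm))
    if (any(!is.finite(gp)) || any(!is.finite(gm)))
      stop("non-finite gradient during finite differencing")
    H[, j] <- (gp - gm) / (2 * step)
  }
  ## note: columns are d(grad)/dx_j with coords flattened column-major
  ## (x all atoms, then y, then z); reorder to atom-major (x1 y1 z1 x2 ...)
  perm <- as.vector(t(matrix(seq_len(n3), nrow(x0), 3)))
  H <- H[perm, perm]
  HessianMatrix((H + t(H)) / 2, g0)
}

## ---- simple potentials --------------------------------------------------

#' n-dimensional harmonic potential
#'
#' Independent harmonic restraints on every Cartesian coordinate:
#' V = 1/2 sum_i k_i (x_i - x0_i)^2. With a single atom and isotropic k this
#' is the canonical validation oscillator for the thermostat module.
#'
#' @param geometry equilibrium [Geometry-class].
#' @param k force constants, eV/A^2; scalar or one per Cartesian DOF.
#' @return A [PotentialSurface-class].
#' @export
makeHarmonicND <- function(geometry, k) {
  x0 <- coordinates(geometry)
  kk <- matrix(k, nrow(x0), 3)
  PotentialSurface(
    energy = function(x) 0.5 * sum(kk * (x - x0)^2),
    gradient = function(x) kk * (x - x0),
    descriptor = list(kind = "harmonic_nd", k = k),
    reference = geometry)
}

#' Morse bond potential between two atoms
#'
#' V = D (1 - exp(-a (r - r0)))^2 for the distance between atoms 1 and 2;
#' curvature at the minimum is 2 D a^2.
#'
#' @param geometry two-atom equilibrium [Geometry-class].
#' @param D dissociation energy, eV.
#' @param a width parameter, 1/A.
#' @param r0 equilibrium distance, A.
#' @return A [PotentialSurface-class].
#' @export
makeMorseBond <- function(geometry, D, a, r0) {
  stopifnot(nAtoms(geometry) == 2)
  PotentialSurface(
    energy = function(x) {
      r <- sqrt(sum((x[2, ] - x[1, ])^2))
      D * (1 - exp(-a * (r - r0)))^2
    },
    gradient = function(x) {
      d <- x[2, ] - x[1, ]
      r <- sqrt(sum(d^2))
      ex <- exp(-a * (r - r0))
      dVdr <- 2 * D * a * ex * (1 - ex)
      u <- d / r
      rbind(-dVdr * u, dVdr * u)
    },
    descriptor = list(kind = "morse_bond", D = D, a = a, r0 = r0),
    reference = geometry)
}

## ---- torsion-stretch toy ------------------------------------------------

#' Torsion-stretch toy: the rectilinear-Wigner torsion artifact
#'
#' Three sites: an anchored heavy atom A, a heavy atom B bonded to A along
#' z, and a light H at distance r from B in the xy-plane, with azimuth theta
#' about the anchor axis. The potential is
#' \deqn{V = \tfrac12 k_r (r - r_0)^2 + \tfrac12 k_\theta \theta^2}
#' plus stiff positional/bond restraints holding the anchors. A stiff
#' stretch combined with a soft torsion of a light atom is exactly the
#' regime in which rectilinear normal modes displace the H along a straight
#' line instead of an arc, stretching the B-H bond with no energy penalty.
#'
#' Also returned is an exact curvilinear sampler that draws (r, theta) from
#' the factorized quantum harmonic ground state (thermal coth factors at
#' finite temperature) with reduced mass \eqn{\mu = m_H m_B / (m_H + m_B)}
#' and moment of inertia \eqn{\mu r_0^2}, then embeds to Cartesian along the
#' arc. Comparing std(r) between the rectilinear-Wigner ensemble and this
#' reference isolates the artifact.
#'
#' @param kR stretch force constant, eV/A^2; default chosen so the stretch
#'   wavenumber is \code{nuStretch}.
#' @param kTheta torsion force constant, eV/rad^2; default chosen so the
#'   torsion wavenumber is \code{nuTorsion}.
#' @param r0 equilibrium B-H distance, A (default 0.96, O-H-like).
#' @param nuStretch,nuTorsion target wavenumbers in cm^-1 (defaults 3600 and
#'   200) used when \code{kR} / \code{kTheta} are not given.
#' @param massAnchor anchor masses, amu (default 16, O-like).
#' @param kAnchor positional/bond restraint stiffness for the anchors,
#'   eV/A^2.
#' @return A list: \code{potential} ([PotentialSurface-class]),
#'   \code{exactSampler} = function(nSamples, temperature = 0, seed), and
#'   \code{params} (all numeric parameters, including the realized kR and
#'   kTheta).
#' @export
makeTorsionStretch <- function(kR = NULL, kTheta = NULL, r0 = 0.96,
                               nuStretch = 3600, nuTorsion = 200,
                               massAnchor = 16, kAnchor = 60) {
  mH <- atomicMass("H")
  mu <- mH * massAnchor / (mH + massAnchor)
  if (is.null(kR))
    kR <- mu * .const$amu_evfs * omegaFromWavenumber(nuStretch)^2
  if (is.null(kTheta))
    kTheta <- mu * r0^2 * .const$amu_evfs * omegaFromWavenumber(nuTorsion)^2
  if (kR <= 0 || kTheta <= 0) stop("stiffnesses must be positive")
  if (kR * r0^2 < 10 * kTheta)
    warning("torsion not much softer than the stretch; the demonstration ",
            "regime needs k_r r0^2 >> k_theta")
  dAB <- 1.3
  ref <- Geometry(c("X", "X", "H"),
                  rbind(c(0, 0, -dAB), c(0, 0, 0), c(r0, 0, 0)),
                  masses = c(massAnchor, massAnchor, mH),
                  label = "torsion-stretch-min")
  a0 <- c(0, 0, -dAB)
  energy <- function(x) {
    dBH <- x[3, ] - x[2, ]
    r <- sqrt(sum(dBH^2))
    theta <- atan2(dBH[2], dBH[1])
    rAB <- sqrt(sum((x[2, ] - x[1, ])^2))
    0.5 * kR * (r - r0)^2 + 0.5 * kTheta * theta^2 +
      0.5 * kAnchor * (rAB - dAB)^2 + 0.5 * kAnchor * sum((x[1, ] - a0)^2)
  }
  gradient <- function(x) {
    g <- matrix(0, 3, 3)
    dBH <- x[3, ] - x[2, ]
    r <- sqrt(sum(dBH^2))
    u <- dBH / r
    gr <- kR * (r - r0) * u
    g[3, ] <- g[3, ] + gr
    g[2, ] <- g[2, ] - gr
    rho2 <- dBH[1]^2 + dBH[2]^2
    theta <- atan2(dBH[2], dBH[1])
    gt <- kTheta * theta * c(-dBH[2], dBH[1], 0) / rho2
    g[3, ] <- g[3, ] + gt
    g[2, ] <- g[2, ] - gt
    dABv <- x[2, ] - x[1, ]
    rAB <- sqrt(sum(dABv^2))
    gb <- kAnchor * (rAB - dAB) * dABv / rAB
    g[2, ] <- g[2, ] + gb
    g[1, ] <- g[1, ] - gb
    g[1, ] <- g[1, ] + kAnchor * (x[1, ] - a0)
    g
  }
  pot <- PotentialSurface(energy, gradient,
    descriptor = list(kind = "torsion_stretch", kR = kR, kTheta = kTheta,
                      r0 = r0, kAnchor = kAnchor, dAB = dAB),
    reference = ref)

  omega_r <- sqrt(kR / (mu * .const$amu_evfs))
  omega_t <- sqrt(kTheta / (mu * r0^2 * .const$amu_evfs))
  exactSampler <- function(nSamples, temperature = 0, seed) {
    if (missing(seed)) stop("a seed is required")
    hbar_int <- .const$hbar_evfs / .const$amu_evfs
    cothf <- function(om) {
      if (temperature > 0)
        .coth(.const$hbar_evfs * om / (2 * .const$kb_ev * temperature))
      else 1
    }
    sd_r <- sqrt(hbar_int / (2 * mu * omega_r) * cothf(omega_r))
    sd_t <- sqrt(hbar_int / (2 * mu * r0^2 * omega_t) * cothf(omega_t))
    set.seed(seed)
    r <- stats::rnorm(nSamples, r0, sd_r)
    th <- stats::rnorm(nSamples, 0, sd_t)
    coords <- array(0, dim = c(3, 3, nSamples))
    for (k in seq_len(nSamples)) {
      coords[1, , k] <- a0
      coords[3, , k] <- c(r[k] * cos(th[k]), r[k] * sin(th[k]), 0)
    }
    new("GeometryEnsemble", reference = ref, coords = coords,
        normalCoords = cbind(r = r - r0, theta = th),
        provenance = list(sampler = "exact-curvilinear",
                          settings = list(nSamples = nSamples,
                                          temperature = temperature,
                                          seed = seed)),
        conformerLabel = "")
  }
  list(potential = pot, exactSampler = exactSampler,
       params = list(kR = kR, kTheta = kTheta, r0 = r0, mu = mu,
                     nuStretch = wavenumberFromOmega(omega_r),
                     nuTorsion = wavenumberFromOmega(omega_t),
                     massAnchor = massAnchor, kAnchor = kAnchor))
}

## ---- soft intermolecular toy --------------------------------------------

#' Soft-intermolecular toy: microsolvation-like broadening
#'
#' Two sites on the x-axis: a chromophore site (mass 12) and a solvent-like
#' site (mass 18) at intermolecular distance d0. The soft intermolecular
#' coordinate q = x2 - x1 - d0 lives in a quartic-plus-harmonic well and
#' modulates the equilibrium of the stiff chromophore coordinate through a
#' bilinear coupling:
#' \deqn{V = \tfrac12 k_{intra} (x_1 - g q)^2 + \tfrac12 k_{soft} q^2
#'       + c_4 q^4 + \tfrac12 k_\perp \sum (y_i^2 + z_i^2)}
#' Quantum-thermostat dynamics at finite temperature samples the true
#' anharmonic, thermally excited soft-mode distribution; ground-state
#' harmonic Wigner sampling sees only the curvature at the minimum. The
#' soft-coordinate distribution is therefore broader under QT.
#'
#' @param kIntra chromophore stiffness, eV/A^2 (default ~1700 cm^-1).
#' @param kSoft soft-mode stiffness, eV/A^2 (default ~150 cm^-1 at reduced
#'   mass 7.2 amu).
#' @param d0 equilibrium intermolecular distance, A (default 2.8).
#' @param c4 quartic coefficient, eV/A^4 (default 1.4).
#' @param coupling bilinear coupling g (dimensionless, default 0.1).
#' @param kPerp transverse restraint, eV/A^2 (default 2).
#' @return A list: \code{potential}, \code{params}.
#' @export
makeSoftIntermolecular <- function(kIntra = 127, kSoft = 0.6, d0 = 2.8,
                                   c4 = 1.4, coupling = 0.1, kPerp = 2) {
  if (kSoft >= kIntra)
    stop("need k_soft << k_intra for the demonstration regime")
  ref <- Geometry(c("C", "X"), rbind(c(0, 0, 0), c(d0, 0, 0)),
                  masses = c(12.011, 18.0), label = "soft-intermolecular-min")
  energy <- function(x) {
    q <- (x[2, 1] - x[1, 1]) - d0
    0.5 * kIntra * (x[1, 1] - coupling * q)^2 +
      0.5 * kSoft * q^2 + c4 * q^4 +
      0.5 * kPerp * sum(x[, 2]^2 + x[, 3]^2)
  }
  gradient <- function(x) {
    q <- (x[2, 1] - x[1, 1]) - d0
    u <- x[1, 1] - coupling * q
    dVdq <- kSoft * q + 4 * c4 * q^3
    g <- matrix(0, 2, 3)
    g[1, 1] <- kIntra * u * (1 + coupling) - dVdq
    g[2, 1] <- -kIntra * u * coupling + dVdq
    g[, 2] <- kPerp * x[, 2]
    g[, 3] <- kPerp * x[, 3]
    g
  }
  pot <- PotentialSurface(energy, gradient,
    descriptor = list(kind = "soft_intermolecular", kIntra = kIntra,
                      kSoft = kSoft, d0 = d0, c4 = c4,
                      coupling = coupling, kPerp = kPerp),
    reference = ref)
  ## verify the minimum is stable for this coupling
  Hnum <- finiteDifferenceHessian(pot)
  ev <- eigen(Hnum@values, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("coupling destabilizes the minimum (negative curvature)")
  list(potential = pot,
       params = list(kIntra = kIntra, kSoft = kSoft, d0 = d0, c4 = c4,
                     coupling = coupling, kPerp = kPerp))
}

## ---- toy chromophores ---------------------------------------------------

#' Analytic toy chromophore: geometry-dependent vertical transitions
#'
#' Maps an internal coordinate q(R) to vertical excitation energies and
#' oscillator strengths for one or more states. Gap forms: \code{"linear"},
#' \eqn{\Delta E = E_0 + \kappa (q - q_0)}, or \code{"exponential"},
#' \eqn{\Delta E = E_0 \exp(-\alpha (q - q_0))} — the latter mimics a
#' dissociative n-sigma* state whose energy collapses as a bond elongates.
#' Strength form: \eqn{f = f_0 + s (q - q_0)}, constant for \eqn{s = 0}.
#'
#' @param coordFun function(coords_matrix) -> scalar internal coordinate q.
#' @param states list of per-state specs; each a list with \code{kind}
#'   ("linear"/"exponential"/"constant"), \code{E0} (eV), \code{q0},
#'   \code{kappa} (eV per coordinate unit, linear) or \code{alpha}
#'   (1/coordinate unit, exponential), \code{f0} (>= 0), optional
#'   \code{fslope} (default 0).
#' @return An object of class \code{ToyChromophore} (a structured list).
#' @export
ToyChromophore <- function(coordFun, states) {
  stopifnot(is.function(coordFun), is.list(states), length(states) >= 1)
  states <- lapply(states, function(s) {
    s$kind <- match.arg(s$kind, c("linear", "exponential", "constant"))
    s$fslope <- s$fslope %||% 0
    s$q0 <- s$q0 %||% 0
    if (is.null(s$E0) || s$E0 <= 0) stop("each state needs E0 > 0")
    if (is.null(s$f0) || s$f0 < 0) stop("each state needs f0 >= 0")
    s
  })
  structure(list(coordFun = coordFun, states = states),
            class = "ToyChromophore")
}

#' Evaluate a toy chromophore over an ensemble
#'
#' One [TransitionTable-class] row per member per state; geometry ids are
#' "<label>:<index>" matching [members()].
#'
#' @param chromophore a [ToyChromophore()].
#' @param ensemble a [GeometryEnsemble-class].
#' @return A [TransitionTable-class].
#' @export
evaluateChromophore <- function(chromophore, ensemble) {
  stopifnot(inherits(chromophore, "ToyChromophore"),
            is(ensemble, "GeometryEnsemble"))
  ns <- nMembers(ensemble)
  q <- vapply(seq_len(ns), function(k) {
    chromophore$coordFun(coordinateArray(ensemble)[, , k, drop = TRUE])
  }, numeric(1))
  lab <- geometryLabel(ensemble)
  ids <- paste0(if (nzchar(lab)) paste0(lab, ":") else "", seq_len(ns))
  out <- do.call(rbind, lapply(seq_along(chromophore$states), function(j) {
    s <- chromophore$states[[j]]
    dq <- q - s$q0
    dE <- switch(s$kind,
      linear = s$E0 + s$kappa * dq,
      exponential = s$E0 * exp(-s$alpha * dq),
      constant = rep(s$E0, length(dq)))
    f <- s$f0 + s$fslope * dq
    if (any(dE <= 0))
      stop("gap map produced non-positive excitation energies for ",
           "member(s) ", paste(utils::head(which(dE <= 0), 10),
                               collapse = ", "),
           " in state ", j)
    if (any(f < 0))
      stop("strength map produced negative oscillator strengths in state ",
           j)
    data.frame(geometry_id = ids, state = j, delta_E_eV = dE,
               osc_strength = f, stringsAsFactors = FALSE)
  }))
  TransitionTable(out$geometry_id, out$state, out$delta_E_eV,
                  out$osc_strength)
}

#' Internal-coordinate helper: distance between two atoms
#'
#' Convenience coordinate function factory for [ToyChromophore()].
#'
#' @param i,j atom indices.
#' @return function(coords) -> distance in Angstrom.
#' @export
distanceCoordinate <- function(i, j) {
  function(x) sqrt(sum((x[j, ] - x[i, ])^2))
}
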