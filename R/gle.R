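## Generalized-Langevin quantum thermostat (QT).
##
## The thermostat couples each (mass-scaled) Cartesian momentum p = sqrt(m) v
## to Ns auxiliary momenta s through a linear SDE
##     d(p, s) = -A (p, s) dt + B dW,     B B^T = A C + C^T A^T,
## where A (fs^-1) is the drift matrix and C (eV) the stationary covariance
## of (p, s) for a free particle. With C = kT I this is a classical
## canonical thermostat; colored-noise (A, C) pairs fitted against the
## quantum harmonic oscillator hold each vibrational frequency at its own
## effective temperature, so that classical dynamics reproduces quantum
## position/momentum variances — exactly so for uncoupled harmonic modes.
##
## Mass scaling means one (A, C) pair serves every atom (GLE4MD convention).

#' Build the discrete GLE half-step propagator
#'
#' For time step dt, the exact propagator of the linear thermostat SDE over
#' dt/2 is \eqn{T = \exp(-A\,dt/2)} with additive Gaussian noise of
#' covariance \eqn{C - T C T^T}; S is its symmetric matrix square root.
#' Both are computed once and reused every step.
#'
#' @param gle a [GLEParameters-class].
#' @param dt MD time step, fs.
#' @return list(Thalf, Shalf) with Shalf %*% t(Shalf) = C - T C T'.
#' @export
buildPropagator <- function(gle, dt) {
  stopifnot(is(gle, "GLEParameters"), dt > 0)
  A <- driftMatrix(gle)
  C <- covarianceMatrix(gle)
  Thalf <- if (all(A == 0)) diag(nrow(A)) else pracma::expm(-A * dt / 2)
  M <- C - Thalf %*% C %*% t(Thalf)
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  tol <- 1e-10 * max(abs(ee$values), .Machine$double.eps)
  if (min(ee$values) < -tol)
    stop("C - T C T' is not positive semidefinite: unstable (A, C) pair")
  Shalf <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
  list(Thalf = Thalf, Shalf = Shalf)
}

## Stationary covariance of (q, p, s) for a harmonic oscillator of angular
## frequency omega under the GLE: solves the continuous Lyapunov equation
## M Sigma + Sigma M' = D. Returns c(varQ, varP) in mass-scaled units
## (q in sqrt(amu-internal) A ~ eV fs^2, p in eV).
.gle_harmonic_variance <- function(A, C, omega) {
  d <- nrow(A)
  M <- matrix(0, d + 1, d + 1)
  M[1, 2] <- -1
  M[2, 1] <- omega^2
  M[2:(d + 1), 2:(d + 1)] <- A
  D <- matrix(0, d + 1, d + 1)
  D[2:(d + 1), 2:(d + 1)] <- A %*% C + C %*% t(A)
  big <- diag(d + 1) %x% M + M %x% diag(d + 1)
  sig <- solve(big, as.vector(D))
  Sigma <- matrix(sig, d + 1, d + 1)
  c(varQ = Sigma[1, 1], varP = Sigma[2, 2])
}

#' Predicted stationary variances of a GLE-thermostatted oscillator
#'
#' Analytic (Lyapunov-equation) prediction of the stationary position and
#' momentum variance of a 1D harmonic oscillator coupled to the thermostat,
#' per vibrational wavenumber — the design tool behind the bundled QT
#' matrices and the oracle the MD integrator is tested against.
#'
#' @param gle a [GLEParameters-class].
#' @param nu_cm vibrational wavenumbers, cm^-1.
#' @param mass oscillator mass, amu (default 1; position variance scales as
#'   1/mass).
#' @return data.frame with columns \code{nu_cm}, \code{varX_A2} (position
#'   variance, A^2), \code{varP_eV} (mass-scaled momentum variance =
#'   effective kinetic temperature in energy units, eV), and the quantum
#'   targets \code{targetX_A2}, \code{targetP_eV} =
#'   \eqn{(\hbar\omega/2)\coth(\hbar\omega/2k_BT)} mapped to the same units.
#' @export
gleStationaryVariance <- function(gle, nu_cm, mass = 1) {
  A <- driftMatrix(gle)
  C <- covarianceMatrix(gle)
  m_int <- mass * .const$amu_evfs
  out <- t(vapply(nu_cm, function(nu) {
    omega <- omegaFromWavenumber(nu)
    v <- .gle_harmonic_variance(A, C, omega)
    tgt <- 0.5 * .const$hbar_evfs * omega *
      .coth(.const$hbar_evfs * omega /
              (2 * .const$kb_ev * gle@temperature))
    c(varX = v[["varQ"]] / m_int,
      varP = v[["varP"]],
      targetX = tgt / (m_int * omega^2),
      targetP = tgt)
  }, numeric(4)))
  data.frame(nu_cm = nu_cm, varX_A2 = out[, "varX"],
             varP_eV = out[, "varP"], targetX_A2 = out[, "targetX"],
             targetP_eV = out[, "targetP"])
}

#' Fit quantum-thermostat GLE matrices
#'
#' Fits an (A, C) pair with \code{ns} auxiliary momenta such that the
#' stationary position and momentum variances of GLE-thermostatted harmonic
#' oscillators match the quantum expressions
#' \eqn{(\hbar\omega/2)\coth(\hbar\omega/2k_BT)} over a range of
#' wavenumbers.
#'
#' The fit runs in two stages. First the drift matrix A (a direct coupling
#' plus ns/2 damped-oscillatory memory channels) is optimized with the
#' noise covariance D = B B' treated as an unconstrained linear
#' least-squares variable — the stationary variances are linear in D
#' through the Lyapunov equation. Then, with A fixed, D is refit through
#' its Cholesky-type factor, which keeps it positive semidefinite by
#' construction, and the stationary covariance C is recovered from
#' A C + C A' = D (guaranteeing a usable thermostat: both C and the
#' fluctuation-dissipation noise are PSD). This is the tool that produced
#' the QT matrix fixture bundled under \code{inst/extdata/gle/}.
#'
#' @param temperature target temperature, K.
#' @param ns number of auxiliary momenta (even, default 6).
#' @param nuRange wavenumber range to fit over, cm^-1 (default 100-4000).
#' @param nNu number of (log-spaced) fitting wavenumbers.
#' @param maxit stage-1 (Nelder-Mead) iteration budget per restart.
#' @param seed RNG seed for the optimizer restarts.
#' @return A [GLEParameters-class], with fit diagnostics in
#'   \code{attr(, "fit")}.
#' @export
fitQTParameters <- function(temperature = 296, ns = 6,
                            nuRange = c(100, 4000), nNu = 24,
                            maxit = 4000, seed = 7) {
  stopifnot(ns >= 2, ns %% 2 == 0)
  nb <- ns / 2
  d <- ns + 1L
  kT <- .const$kb_ev * temperature
  nus <- exp(seq(log(nuRange[1]), log(nuRange[2]), length.out = nNu))
  omegas <- omegaFromWavenumber(nus)
  targets <- vapply(omegas, function(om) {
    0.5 * .const$hbar_evfs * om * .coth(.const$hbar_evfs * om / (2 * kT))
  }, numeric(1))
  rhs <- rep(targets, each = 2)

  ## symmetric basis for the noise covariance D
  ij <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  nD <- nrow(ij)
  sym_basis <- lapply(seq_len(nD), function(k) {
    E <- matrix(0, d, d)
    E[ij[k, 1], ij[k, 2]] <- E[ij[k, 2], ij[k, 1]] <- 1
    E
  })

  build_A <- function(par) {
    A <- matrix(0, d, d)
    A[1, 1] <- exp(par[1])
    gam <- exp(par[2:(1 + nb)])
    del <- exp(par[(2 + nb):(1 + 2 * nb)])
    cps <- par[(2 + 2 * nb):(1 + 3 * nb)]
    csp <- par[(2 + 3 * nb):(1 + 4 * nb)]
    for (b in seq_len(nb)) {
      i <- 2 * b; j <- 2 * b + 1
      A[i, i] <- A[j, j] <- gam[b]
      A[i, j] <- del[b]; A[j, i] <- -del[b]
      A[1, i] <- cps[b]
      A[i, 1] <- csp[b]
    }
    A
  }

  ## 2 nNu x nD response matrix: (omega^2 varQ, varP) per basis element of
  ## the noise covariance, via the full (q, p, s) Lyapunov equation
  resp_matrix <- function(A) {
    rows <- matrix(0, 2 * length(omegas), nD)
    r <- 1L
    for (om in omegas) {
      M <- matrix(0, d + 1, d + 1)
      M[1, 2] <- -1; M[2, 1] <- om^2
      M[2:(d + 1), 2:(d + 1)] <- A
      big <- diag(d + 1) %x% M + M %x% diag(d + 1)
      iqq <- 1L                       # vec index of Sigma[1,1]
      ipp <- (d + 1) + 2L             # vec index of Sigma[2,2]
      sel <- solve(t(big), cbind(replace(numeric((d + 1)^2), iqq, 1),
                                 replace(numeric((d + 1)^2), ipp, 1)))
      for (k in seq_len(nD)) {
        Df <- matrix(0, d + 1, d + 1)
        Df[2:(d + 1), 2:(d + 1)] <- sym_basis[[k]]
        vD <- as.vector(Df)
        rows[r, k] <- om^2 * sum(sel[, 1] * vD)
        rows[r + 1L, k] <- sum(sel[, 2] * vD)
      }
      r <- r + 2L
    }
    rows
  }

  dcoef <- function(D) D[cbind(ij[, 1], ij[, 2])]

  lls_D <- function(A) {
    X <- tryCatch(resp_matrix(A) / rhs, error = function(e) NULL)
    if (is.null(X)) return(NULL)
    cc <- tryCatch(solve(crossprod(X) + 1e-8 * diag(nD),
                         colSums(X)),
                   error = function(e) NULL)
    if (is.null(cc)) return(NULL)
    list(cc = cc, X = X, resid = X %*% cc - 1)
  }

  stage1 <- function(par) {
    A <- build_A(par)
    ev <- eigen(A, only.values = TRUE)$values
    if (min(Re(ev)) < 1e-6) return(1e6 + abs(min(Re(ev))) * 1e6)
    f <- lls_D(A)
    if (is.null(f)) return(1e6)
    sum(f$resid^2)
  }

  set.seed(seed)
  best <- NULL
  for (try in 1:3) {
    par0 <- c(log(0.05 * try),
              log(exp(seq(log(0.005), log(0.5), length.out = nb)) * try),
              log(rep(0.2, nb) * try),
              stats::rnorm(nb, 0, 0.3),
              stats::rnorm(nb, 0, 0.3))
    opt <- stats::optim(par0, stage1, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    opt <- stats::optim(opt$par, stage1, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  A <- build_A(best$par)

  ## stage 2: PSD noise covariance via its triangular factor, A fixed
  f1 <- lls_D(A)
  X <- f1$X
  Dlls <- matrix(0, d, d)
  for (k in seq_len(nD)) Dlls <- Dlls + f1$cc[k] * sym_basis[[k]]
  ee <- eigen((Dlls + t(Dlls)) / 2, symmetric = TRUE)
  Dpsd <- ee$vectors %*% (pmax(ee$values, 1e-8 * max(abs(ee$values))) *
                            t(ee$vectors))
  G0 <- t(chol(Dpsd + 1e-10 * max(diag(Dpsd)) * diag(d)))
  low <- which(lower.tri(diag(d), diag = TRUE))
  stage2 <- function(g) {
    G <- matrix(0, d, d); G[low] <- g
    D <- tcrossprod(G)
    sum((X %*% dcoef(D) - 1)^2)
  }
  opt2 <- stats::optim(G0[low], stage2, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-14))

  ## stage 3: joint refinement of (A, G) on the direct Lyapunov objective
  nA <- length(best$par)
  stage3 <- function(par) {
    if (any(!is.finite(par)) || any(par[seq_len(nA)] > 50)) return(1e7)
    A3 <- build_A(par[seq_len(nA)])
    ev <- eigen(A3, only.values = TRUE)$values
    if (min(Re(ev)) < 1e-6) return(1e6 + abs(min(Re(ev))) * 1e6)
    G3 <- matrix(0, d, d); G3[low] <- par[-seq_len(nA)]
    D3 <- tcrossprod(G3)
    tot <- 0
    for (w in seq_along(omegas)) {
      om <- omegas[w]
      M <- matrix(0, d + 1, d + 1)
      M[1, 2] <- -1; M[2, 1] <- om^2
      M[2:(d + 1), 2:(d + 1)] <- A3
      Df <- matrix(0, d + 1, d + 1)
      Df[2:(d + 1), 2:(d + 1)] <- D3
      big <- diag(d + 1) %x% M + M %x% diag(d + 1)
      Sg <- tryCatch(solve(big, as.vector(Df)), error = function(e) NULL)
      if (is.null(Sg)) return(1e6)
      Sg <- matrix(Sg, d + 1, d + 1)
      tot <- tot + (om^2 * Sg[1, 1] / targets[w] - 1)^2 +
        (Sg[2, 2] / targets[w] - 1)^2
    }
    tot
  }
  p3 <- c(best$par, opt2$par)
  opt3 <- stats::optim(p3, stage3, method = "BFGS",
                       control = list(maxit = 400, reltol = 1e-12))
  opt3 <- stats::optim(opt3$par, stage3, method = "Nelder-Mead",
                       control = list(maxit = 2 * maxit))
  opt3 <- stats::optim(opt3$par, stage3, method = "BFGS",
                       control = list(maxit = 400, reltol = 1e-12))
  A <- build_A(opt3$par[seq_len(nA)])
  G <- matrix(0, d, d); G[low] <- opt3$par[-seq_len(nA)]
  D <- tcrossprod(G)

  ## recover the stationary covariance: A C + C A' = D
  C <- matrix(solve(diag(d) %x% A + A %x% diag(d), as.vector(D)), d, d)
  C <- (C + t(C)) / 2
  eC <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(eC) <= 0)
    C <- C + (abs(min(eC)) + 1e-12 * max(eC)) * diag(d)
  out <- GLEParameters(A, C, temperature)
  attr(out, "fit") <- list(stage1 = best$value, stage2 = opt2$value,
                           stage3 = opt3$value, nus = nus)
  out
}

#' Settings for quantum-thermostat MD
#'
#' @param dt time step, fs (default 0.5).
#' @param nSteps number of MD steps.
#' @param equilibrationWindow window length (steps) for the running kinetic-
#'   temperature mean used by [detectEquilibration()].
#' @param temperatureTolerance relative tolerance on the kinetic-temperature
#'   convergence, in (0, 1).
#' @param stride snapshot interval in steps (>= 1).
#' @param seed RNG seed (mandatory).
#' @return Validated settings list.
#' @export
QTSettings <- function(dt = 0.5, nSteps, equilibrationWindow = 2000,
                       temperatureTolerance = 0.05, stride = 10, seed) {
  if (missing(seed)) stop("a seed is required for QT dynamics")
  stopifnot(dt > 0, nSteps >= 1, stride >= 1,
            temperatureTolerance > 0, temperatureTolerance < 1)
  list(dt = dt, nSteps = as.integer(nSteps),
       equilibrationWindow = as.integer(equilibrationWindow),
       temperatureTolerance = temperatureTolerance,
       stride = as.integer(stride), seed = as.integer(seed))
}

#' Run quantum-thermostat molecular dynamics
#'
#' Symmetric-splitting integrator: GLE half-step on (p, s) per Cartesian
#' DOF, velocity half-kick, position drift, force refresh, velocity
#' half-kick, GLE half-step. Auxiliary momenta persist across steps; the
#' kinetic temperature (over all 3n DOFs) and potential energy are recorded
#' every step. With A = 0 the scheme reduces to velocity Verlet; with
#' classical C = kT I it is a canonical Langevin thermostat.
#'
#' Initial velocities and auxiliary momenta are drawn jointly from the
#' stationary covariance C.
#'
#' @param potential a [PotentialSurface-class].
#' @param start starting [Geometry-class].
#' @param gle a [GLEParameters-class].
#' @param settings a [QTSettings()] list.
#' @return A [Trajectory-class].
#' @export
runQT <- function(potential, start, gle, settings) {
  stopifnot(is(potential, "PotentialSurface"), is(start, "Geometry"),
            is(gle, "GLEParameters"))
  prop <- buildPropagator(gle, settings$dt)
  Thalf <- prop$Thalf; Shalf <- prop$Shalf
  n <- nAtoms(start)
  ndof <- 3L * n
  d <- gle@ns + 1L
  m3 <- rep(atomicMasses(start), each = 3)
  m_int <- m3 * .const$amu_evfs
  sqm <- sqrt(m_int)
  dt <- settings$dt

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(settings$seed)

  ## state: x (flattened atom-major), S (d x ndof) thermostat state
  x <- as.vector(t(coordinates(start)))
  eeC <- eigen(covarianceMatrix(gle), symmetric = TRUE)
  sqC <- eeC$vectors %*% (sqrt(pmax(eeC$values, 0)) * t(eeC$vectors))
  S <- sqC %*% matrix(stats::rnorm(d * ndof), d, ndof)
  v <- S[1, ] / sqm

  coords_mat <- function(xv) matrix(xv, n, 3, byrow = TRUE)
  grad_flat <- function(xv) as.vector(t(potential@gradient(coords_mat(xv))))

  nfr <- settings$nSteps %/% settings$stride
  frames <- array(NA_real_, dim = c(n, 3, nfr))
  vels <- array(NA_real_, dim = c(n, 3, nfr))
  frame_steps <- integer(nfr)
  tkin <- numeric(settings$nSteps)
  epot <- numeric(settings$nSteps)

  f <- -grad_flat(x)
  noisy <- any(driftMatrix(gle) != 0)
  ifr <- 0L
  for (step in seq_len(settings$nSteps)) {
    if (noisy) {
      S[1, ] <- v * sqm
      S <- Thalf %*% S + Shalf %*% matrix(stats::rnorm(d * ndof), d, ndof)
      v <- S[1, ] / sqm
    }
    v <- v + 0.5 * dt * f / m_int
    dx <- dt * v
    if (max(abs(dx)) > 0.5)
      stop("integration blow-up at step ", step,
           ": displacement ", format(max(abs(dx))), " A exceeds 0.5 A")
    x <- x + dx
    f <- -grad_flat(x)
    if (any(!is.finite(f)))
      stop("non-finite gradient at step ", step)
    v <- v + 0.5 * dt * f / m_int
    if (noisy) {
      S[1, ] <- v * sqm
      S <- Thalf %*% S + Shalf %*% matrix(stats::rnorm(d * ndof), d, ndof)
      v <- S[1, ] / sqm
    }
    tkin[step] <- sum(m_int * v^2) / (ndof * .const$kb_ev)
    epot[step] <- potential@energy(coords_mat(x))
    if (step %% settings$stride == 0L) {
      ifr <- ifr + 1L
      frames[, , ifr] <- coords_mat(x)
      vels[, , ifr] <- coords_mat(v)
      frame_steps[ifr] <- step
    }
  }
  new("Trajectory", frames = frames, velocities = vels,
      kineticTemperature = tkin, potentialEnergy = epot,
      frameSteps = frame_steps, settings = settings, reference = start)
}

#' Detect the equilibrated part of a trajectory
#'
#' Returns the smallest step index (1-based) at which the running mean of
#' the kinetic temperature over \code{equilibrationWindow} steps agrees, to
#' within \code{temperatureTolerance} (relative), with the mean over the
#' remainder of the trajectory after that window.
#'
#' @param trajectory a [Trajectory-class].
#' @param settings optional override of the trajectory's own settings.
#' @return Integer step index; snapshots before it should be discarded.
#' @export
detectEquilibration <- function(trajectory, settings = NULL) {
  s <- settings %||% trajectory@settings
  tser <- kineticTemperature(trajectory)
  nstep <- length(tser)
  if (!nstep) stop("empty temperature series")
  w <- min(s$equilibrationWindow, max(nstep %/% 2, 1L))
  cs <- cumsum(c(0, tser))
  idx <- seq_len(nstep - w)          # the post-window tail must be nonempty
  runmean <- (cs[idx + w] - cs[idx]) / w
  tailmean <- (cs[nstep + 1L] - cs[idx + w]) / (nstep - idx - w + 1L)
  ok <- abs(runmean - tailmean) <= s$temperatureTolerance * abs(tailmean)
  hit <- which(ok)
  if (!length(hit))
    stop("kinetic temperature never converged at tolerance ",
         s$temperatureTolerance, "; run a longer trajectory")
  hit[1]
}

#' Extract an ensemble of snapshots from an equilibrated trajectory
#'
#' Takes \code{nSamples} stored frames at uniform stride over the segment
#' after \code{equilibratedFrom} (a step index, e.g. from
#' [detectEquilibration()]).
#'
#' @param trajectory a [Trajectory-class].
#' @param nSamples number of snapshots.
#' @param equilibratedFrom first equilibrated step (default: detected).
#' @param conformerLabel label for downstream Boltzmann weighting.
#' @return A [GeometryEnsemble-class].
#' @export
extractSnapshots <- function(trajectory, nSamples, equilibratedFrom = NULL,
                             conformerLabel = "") {
  if (is.null(equilibratedFrom))
    equilibratedFrom <- detectEquilibration(trajectory)
  avail <- which(trajectory@frameSteps >= equilibratedFrom)
  if (nSamples > length(avail))
    stop("insufficient equilibrated frames: need ", nSamples, ", have ",
         length(avail), "; required trajectory length >= ",
         equilibratedFrom + nSamples * trajectory@settings$stride, " steps")
  stride <- length(avail) %/% nSamples
  pick <- avail[seq(length(avail) - stride * (nSamples - 1L),
                    length(avail), by = stride)]
  new("GeometryEnsemble", reference = trajectory@reference,
      coords = trajectory@frames[, , pick, drop = FALSE],
      normalCoords = NULL, momenta = NULL,
      provenance = list(sampler = "qt",
                        settings = trajectory@settings,
                        equilibratedFrom = equilibratedFrom,
                        frameSteps = trajectory@frameSteps[pick]),
      conformerLabel = conformerLabel)
}
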