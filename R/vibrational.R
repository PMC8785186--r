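## Harmonic vibrational analysis: mass weighting, Eckart projection of the
## rigid translation/rotation subspace, and the eigendecomposition that
## yields wavenumbers and mass-weighted rectilinear normal modes.

.mass_weight <- function(hessian) {
  if (hessian@massWeighted) return(hessian)
  m3 <- rep(atomicMasses(hessian@geometry), each = 3)
  if (any(m3 <= 0)) stop("degenerate atomic masses")
  w <- 1 / sqrt(m3)
  new("HessianMatrix",
      values = hessian@values * outer(w, w),
      geometry = hessian@geometry, massWeighted = TRUE,
      projected = hessian@projected)
}

## Orthonormal basis of the mass-weighted translation + infinitesimal
## rotation subspace (3 + 3, or 3 + 2 for linear molecules).
.tr_rot_basis <- function(geometry) {
  xyz <- coordinates(geometry)
  m <- atomicMasses(geometry)
  n <- nrow(xyz)
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  sm <- sqrt(m)
  vecs <- matrix(0, 3 * n, 6)
  for (a in 1:3) vecs[seq(a, 3 * n, by = 3), a] <- sm          # translations
  ax <- diag(3)
  for (a in 1:3) {                                             # rotations
    cr <- t(vapply(seq_len(n),
                   function(i) pracma::cross(ax[a, ], r[i, ]), numeric(3)))
    vecs[, 3 + a] <- as.vector(t(cr * sm))
  }
  q <- qr(vecs)
  ## rank < 6 for linear molecules: the rotation about the axis vanishes
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

#' Eckart projection of a Cartesian Hessian
#'
#' Mass-weights the Hessian and projects out the rigid-translation (3) and
#' infinitesimal-rotation (3, or 2 for linear molecules) subspace, so the
#' remaining eigenvalues are purely vibrational. Assumes the geometry is a
#' stationary point (the gradient is not checked here).
#'
#' @param hessian a [HessianMatrix-class] (Cartesian, eV/A^2).
#' @return A mass-weighted, projected [HessianMatrix-class]
#'   (eV / (A^2 amu)).
#' @export
eckartProject <- function(hessian) {
  stopifnot(is(hessian, "HessianMatrix"))
  hmw <- .mass_weight(hessian)
  B <- .tr_rot_basis(hessian@geometry)
  P <- diag(nrow(hmw@values)) - tcrossprod(B)
  H <- P %*% hmw@values %*% P
  new("HessianMatrix", values = (H + t(H)) / 2,
      geometry = hessian@geometry, massWeighted = TRUE, projected = TRUE)
}

#' Harmonic normal-mode analysis
#'
#' Diagonalizes the mass-weighted Hessian \eqn{M^{-1/2} H M^{-1/2}} and
#' converts eigenvalues to wavenumbers,
#' \eqn{\tilde\nu_i = \sqrt{\lambda_i} / (2\pi c)}; negative eigenvalues are
#' reported as negative (imaginary) wavenumbers. Modes with
#' \eqn{|\tilde\nu|} below \code{floorThreshold} are dropped as residual
#' translation/rotation (or genuinely free internal coordinates of model
#' potentials).
#'
#' @param hessian a [HessianMatrix-class]. If not yet mass-weighted it is
#'   processed first: with \code{project = TRUE} (default) through
#'   [eckartProject()], otherwise by mass weighting alone. Projection is the
#'   right choice for translation/rotation-invariant potentials; anchored
#'   model potentials whose external motions carry real restoring forces
#'   should use \code{project = FALSE}.
#' @param floorThreshold wavenumber floor in cm^-1 (default 10) below which
#'   modes are discarded.
#' @param project apply Eckart projection when preprocessing (default TRUE).
#' @return A [NormalModeSet-class] with frequencies sorted ascending.
#' @examples
#' ## diatomic: single mode at (1 / 2 pi c) sqrt(k / mu)
#' g <- Geometry(c("H", "Cl"), rbind(c(0, 0, 0), c(1.27, 0, 0)))
#' k <- 30  # eV / A^2
#' H <- matrix(0, 6, 6); H[1, 1] <- H[4, 4] <- k; H[1, 4] <- H[4, 1] <- -k
#' nm <- normalModeAnalysis(HessianMatrix(H, g))
#' frequencies(nm)
#' @export
normalModeAnalysis <- function(hessian, floorThreshold = 10,
                               project = TRUE) {
  stopifnot(is(hessian, "HessianMatrix"))
  if (!hessian@massWeighted) {
    hessian <- if (project) eckartProject(hessian) else .mass_weight(hessian)
  }
  ee <- eigen(hessian@values, symmetric = TRUE)
  lambda <- rev(ee$values)                  # ascending
  vecs <- ee$vectors[, rev(seq_along(lambda)), drop = FALSE]
  nu <- sign(lambda) * wavenumberFromOmega(sqrt(abs(lambda) / .const$amu_evfs))
  keep <- abs(nu) >= floorThreshold
  nu <- nu[keep]
  vecs <- vecs[, keep, drop = FALSE]
  if (sum(nu < 0) > 0) {
    warning(sum(nu < 0), " imaginary frequenc",
            if (sum(nu < 0) > 1) "ies" else "y",
            " above the floor threshold; Wigner sampling will refuse",
            " these modes")
  }
  m3 <- rep(atomicMasses(hessian@geometry), each = 3)
  red_mass <- 1 / colSums(vecs^2 / m3)
  new("NormalModeSet", frequencies = nu, modes = vecs,
      geometry = hessian@geometry, reducedMasses = red_mass)
}
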