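## NEA cross-section assembly. The absolute photoabsorption cross-section on
## a photon-energy grid E is
##
##   sigma(E) = K/E * sum_J (1/N_p) sum_n dE_0J(R_n) f_0J(R_n)
##                                   w_s[E - dE_0J(R_n), delta]
##
## with K = pi e^2 hbar / (2 m_e c eps0) (eV cm^2), J running over
## electronic states, n over the N_p sampled geometries, and w_s a
## unit-normalized lineshape of FWHM delta. No empirical shifts or scaling
## factors are ever applied. A switch drops the dE/E weighting (pure-f
## form) for cross-checks; both collapse to the same line-center intensity.

#' Evaluate a normalized lineshape
#'
#' @param shape a [LineShapeSpec()].
#' @param x energy offsets from the line center, eV.
#' @return Lineshape values, 1/eV; integrates to 1 over the real line.
#' @export
lineshapeValues <- function(shape, x) {
  stopifnot(is(shape, "LineShapeSpec"))
  if (shape@kind == "lorentzian") {
    hw <- shape@delta / 2
    (hw / pi) / (x^2 + hw^2)
  } else {
    s <- shape@delta / (2 * sqrt(2 * log(2)))
    stats::dnorm(x, sd = s)
  }
}

## analytic mass of a lineshape within [-W, W] around its center
.lineshape_mass <- function(shape, W) {
  if (shape@kind == "lorentzian") {
    (2 / pi) * atan(2 * W / shape@delta)
  } else {
    s <- shape@delta / (2 * sqrt(2 * log(2)))
    2 * stats::pnorm(W / s) - 1
  }
}

#' Default energy grid for a set of transitions
#'
#' Covers [min dE - 5 delta, max dE + 5 delta] at spacing delta/10.
#'
#' @param table a [TransitionTable-class].
#' @param shape a [LineShapeSpec()].
#' @param pad half-width padding in units of delta (default 5).
#' @return Numeric energy grid, eV.
#' @export
defaultEnergyGrid <- function(table, shape, pad = 5) {
  dE <- records(table)$delta_E_eV
  lo <- max(min(dE) - pad * shape@delta, shape@delta / 10)
  hi <- max(dE) + pad * shape@delta
  seq(lo, hi, by = shape@delta / 10)
}

#' Assemble an absolute NEA cross-section
#'
#' Averages broadened vertical transitions over the ensemble (uniform
#' weight 1/N_p per sampled geometry) and sums over electronic states.
#' N_p is taken as the number of distinct geometry ids in the table.
#'
#' @param table a [TransitionTable-class] for one ensemble.
#' @param lineshape a [LineShapeSpec()] (default Lorentzian, FWHM 0.05 eV).
#' @param grid energy grid, eV (default [defaultEnergyGrid()]).
#' @param energyWeighted keep the dE/E factor of the NEA expression
#'   (default TRUE); FALSE gives the pure-f cross-check form
#'   sigma = K/N_p sum f w.
#' @return A [Spectrum-class]; metadata records N_p, the states, the
#'   lineshape and the weighting convention.
#' @examples
#' tt <- TransitionTable("g1", 1, 4.0, 0.01)
#' sp <- assembleSigma(tt)
#' max(crossSection(sp))
#' @export
assembleSigma <- function(table, lineshape = LineShapeSpec(), grid = NULL,
                          energyWeighted = TRUE) {
  stopifnot(is(table, "TransitionTable"))
  df <- records(table)
  if (!nrow(df)) stop("empty transition table")
  if (is.null(grid)) grid <- defaultEnergyGrid(table, lineshape)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  np <- length(unique(df$geometry_id))
  clipped <- df$delta_E_eV < min(grid) | df$delta_E_eV > max(grid)
  if (any(clipped))
    warning(sum(clipped), " transition line(s) fall outside the grid: ",
            paste(utils::head(sprintf("%.3f eV", df$delta_E_eV[clipped]), 5),
                  collapse = ", "))
  K <- .const$k_nea
  sig <- numeric(length(grid))
  for (i in seq_len(nrow(df))) {
    w <- lineshapeValues(lineshape, grid - df$delta_E_eV[i])
    amp <- df$osc_strength[i] * (if (energyWeighted) df$delta_E_eV[i] else 1)
    sig <- sig + amp * w
  }
  sig <- K * sig / np
  if (energyWeighted) sig <- sig / grid
  Spectrum(grid, sig,
           metadata = list(n_p = np,
                           states = sort(unique(df$state)),
                           lineshape = list(kind = lineshape@kind,
                                            delta_eV = lineshape@delta),
                           energyWeighted = energyWeighted))
}

#' Integrate a spectrum over energy
#'
#' Trapezoidal integral of sigma(E) dE, optionally adding the analytic
#' lineshape tail mass outside the grid (needed for sum-rule checks with
#' Lorentzian lineshapes, whose tails decay slowly).
#'
#' @param spectrum a [Spectrum-class].
#' @param tailCorrection add the analytic out-of-grid tail mass, computed
#'   from the stored lineshape and the transitions' mean line position
#'   (default FALSE). Requires metadata written by [assembleSigma()] plus a
#'   \code{sumF} entry (K-weighted total line strength); used by the
#'   sum-rule tests.
#' @param lineCenter line-center energy used for the tail correction.
#' @param lineStrength total strength K * mean(sum_J dE f)/E-ish prefactor;
#'   when supplied with \code{lineCenter}, the missing tail mass
#'   lineStrength * (1 - mass_within_grid) is added.
#' @return Integral in eV cm^2.
#' @export
integrateSpectrum <- function(spectrum, tailCorrection = FALSE,
                              lineCenter = NULL, lineStrength = NULL) {
  e <- energyGrid(spectrum)
  s <- crossSection(spectrum)
  val <- sum(diff(e) * (s[-1] + s[-length(s)]) / 2)
  if (tailCorrection) {
    if (is.null(lineCenter) || is.null(lineStrength))
      stop("tail correction needs lineCenter and lineStrength")
    md <- metadata(spectrum)
    if (is.null(md$lineshape))
      stop("spectrum has no lineshape metadata")
    shape <- LineShapeSpec(md$lineshape$kind, md$lineshape$delta_eV)
    W <- min(lineCenter - min(e), max(e) - lineCenter)
    val <- val + lineStrength * (1 - .lineshape_mass(shape, W))
  }
  val
}

#' Boltzmann weights for conformers
#'
#' w_i proportional to exp(-dE_i / kT), normalized to 1; energies are
#' shifted so the minimum is zero before exponentiation.
#'
#' @param relativeEnergies conformer energies, eV (any common zero).
#' @param temperature K, > 0.
#' @param labels conformer labels (default c1, c2, ...).
#' @return A [ConformerWeights-class].
#' @examples
#' kT <- physicalConstants()$internal$kb_ev * 296
#' normalizedWeights(boltzmannWeights(c(0, kT * log(2)), 296))  # 2/3, 1/3
#' @export
boltzmannWeights <- function(relativeEnergies, temperature,
                             labels = paste0("c", seq_along(relativeEnergies))) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (any(!is.finite(relativeEnergies))) stop("energies must be finite")
  dE <- relativeEnergies - min(relativeEnergies)
  w <- exp(-dE / (.const$kb_ev * temperature))
  new("ConformerWeights", labels = as.character(labels),
      energies = dE, temperature = temperature, weights = w / sum(w))
}

.check_same_grid <- function(spectra) {
  g <- energyGrid(spectra[[1]])
  for (s in spectra[-1]) {
    if (length(energyGrid(s)) != length(g) ||
        max(abs(energyGrid(s) - g)) > 1e-12 * max(abs(g)))
      stop("spectra are on different energy grids; no silent regridding")
  }
  g
}

#' Combine conformer spectra with Boltzmann weights
#'
#' sigma_total = sum_i w_i sigma_i on a shared grid.
#'
#' @param spectra list of [Spectrum-class] on identical grids; names (or
#'   metadata conformer labels) must match the weights' labels.
#' @param weights a [ConformerWeights-class].
#' @return A [Spectrum-class].
#' @export
combineConformers <- function(spectra, weights) {
  stopifnot(is(weights, "ConformerWeights"), length(spectra) >= 1)
  g <- .check_same_grid(spectra)
  labs <- names(spectra)
  if (is.null(labs))
    labs <- vapply(spectra, function(s)
      metadata(s)$conformer %||% "", "")
  w <- normalizedWeights(weights)
  if (!setequal(labs, names(w)) || length(labs) != length(w))
    stop("conformer labels of spectra and weights do not match")
  sig <- Reduce(`+`, lapply(labs, function(l)
    w[[l]] * crossSection(spectra[[which(labs == l)]])))
  Spectrum(g, sig, metadata = list(conformers = labs,
                                   weights = unname(w[labs]),
                                   temperature_K = weights@temperature))
}

#' Composite spectrum of independent fragments
#'
#' Unweighted sum of fragment cross-sections on a shared grid — the
#' structure-activity (SAR-style) composite that approximates a
#' multichromophoric molecule by its monofunctional fragments.
#'
#' @param spectra list of [Spectrum-class] on identical grids.
#' @return A [Spectrum-class] with metadata$composite = TRUE.
#' @export
compositeSpectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  g <- .check_same_grid(spectra)
  sig <- Reduce(`+`, lapply(spectra, crossSection))
  Spectrum(g, sig, metadata = list(composite = TRUE,
                                   n_fragments = length(spectra)))
}

#' Reflection-principle reference band
#'
#' Closed-form NEA limit for a linear gap map dE = E0 + kappa (q - q0) over
#' a Gaussian coordinate density N(q0, sigma_x^2) with constant oscillator
#' strength f: the line-position density is Gaussian with mean E0 and std
#' |kappa| sigma_x, and the cross-section is its convolution with the
#' lineshape,
#' \deqn{\sigma_{ref}(E) = (K f / E) \int u\, N(u; E_0, \kappa^2\sigma_x^2)
#'        \, w_s(E - u)\, du,}
#' evaluated by quadrature on a fine grid. Used as a validation oracle for
#' [assembleSigma()]; set \code{convolve = FALSE} for the bare Gaussian
#' band.
#'
#' @param E0 vertical excitation energy at the coordinate mean, eV.
#' @param kappa gap-map slope, eV per coordinate unit (non-zero).
#' @param sigma_x coordinate std (> 0).
#' @param f oscillator strength.
#' @param lineshape a [LineShapeSpec()].
#' @param grid output energy grid, eV.
#' @param convolve convolve with the lineshape (default TRUE).
#' @param energyWeighted match [assembleSigma()]'s dE/E weighting
#'   (default TRUE).
#' @return A [Spectrum-class].
#' @export
reflectionReference <- function(E0, kappa, sigma_x, f = 0.01,
                                lineshape = LineShapeSpec(delta = 0.01),
                                grid, convolve = TRUE,
                                energyWeighted = TRUE) {
  if (kappa == 0) stop("kappa must be non-zero")
  if (sigma_x <= 0) stop("sigma_x must be positive")
  K <- .const$k_nea
  s_band <- abs(kappa) * sigma_x
  if (!convolve) {
    dens <- stats::dnorm(grid, E0, s_band)
    amp <- if (energyWeighted) grid * dens else dens  # u N(u) at u = E
    sig <- K * f * amp / (if (energyWeighted) grid else 1)
    return(Spectrum(grid, pmax(sig, 0),
                    metadata = list(reference = "reflection")))
  }
  if (s_band < lineshape@delta / 50) {
    ## band much narrower than the lineshape: the convolution collapses
    ## onto the lineshape at E0
    w <- lineshapeValues(lineshape, grid - E0)
    sig <- K * f * (if (energyWeighted) E0 * w / grid else w)
    return(Spectrum(grid, pmax(sig, 0),
                    metadata = list(reference = "reflection")))
  }
  ## fine quadrature grid over the line-position density: resolve both the
  ## Gaussian band and the lineshape core
  hw <- 8 * s_band + 6 * lineshape@delta
  np <- max(4001, ceiling(2 * hw / (min(s_band, lineshape@delta) / 8)))
  u <- seq(E0 - hw, E0 + hw, length.out = min(np, 200001))
  du <- u[2] - u[1]
  dens <- stats::dnorm(u, E0, s_band)
  wgt <- if (energyWeighted) u * dens else dens
  sig <- vapply(grid, function(E)
    sum(wgt * lineshapeValues(lineshape, E - u)) * du, numeric(1))
  sig <- K * f * sig / (if (energyWeighted) grid else rep(1, length(grid)))
  Spectrum(grid, pmax(sig, 0), metadata = list(reference = "reflection"))
}
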