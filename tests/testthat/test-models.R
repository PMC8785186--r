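test_that("all bundled potentials pass the gradient-consistency contract", {
  toy <- makeTorsionStretch()
  soft <- makeSoftIntermolecular()
  morse <- makeMorseBond(Geometry(c("O", "H"),
                                  rbind(c(0, 0, 0), c(0.96, 0, 0))),
                         D = 4.6, a = 2.2, r0 = 0.96)
  harm <- makeHarmonicND(Geometry("C", matrix(0, 1, 3)), 10)
  for (pot in list(toy$potential, soft$potential, morse, harm)) {
    expect_lt(checkGradient(pot), 1e-5)
  }
})

test_that("finite-difference Hessians match closed forms", {
  ## 1D harmonic: curvature k
  k <- 17.3
  harm <- makeHarmonicND(Geometry("C", matrix(0, 1, 3)), k)
  H <- finiteDifferenceHessian(harm)@values
  expect_equal(diag(H), rep(k, 3), tolerance = 1e-8)
  expect_lt(max(abs(H - diag(diag(H)))), 1e-8)
  ## Morse at r0: curvature 2 D a^2 along the bond
  D <- 4.6; a <- 2.2
  morse <- makeMorseBond(Geometry(c("O", "H"),
                                  rbind(c(0, 0, 0), c(0.96, 0, 0))),
                         D = D, a = a, r0 = 0.96)
  Hm <- finiteDifferenceHessian(morse)@values
  ## reduced curvature along x of the relative coordinate
  expect_equal(Hm[4, 4], 2 * D * a^2, tolerance = 1e-4)
  expect_equal(Hm[1, 4], -2 * D * a^2, tolerance = 1e-4)
})

test_that("model minima are recovered by local optimization", {
  toy <- makeTorsionStretch()
  soft <- makeSoftIntermolecular()
  perturb <- function(pot) {
    Geometry(elementSymbols(pot@reference),
             coordinates(pot@reference) +
               matrix(c(0.05, -0.03, 0.02), nAtoms(pot@reference), 3,
                      byrow = TRUE),
             atomicMasses(pot@reference))
  }
  ## soft toy: every coordinate is restrained, the minimum is unique
  opt <- optimizeGeometry(soft$potential, perturb(soft$potential))
  expect_lt(max(abs(coordinates(opt) -
                      coordinates(soft$potential@reference))), 1e-6)
  ## torsion toy: the free H polar coordinate leaves a valley of minima;
  ## the optimizer must reach the bottom (energy and gradient vanish)
  opt2 <- optimizeGeometry(toy$potential, perturb(toy$potential))
  expect_lt(potentialEnergy(toy$potential, opt2), 1e-10)
  expect_lt(max(abs(potentialGradient(toy$potential, opt2))), 1e-5)
})

test_that("exact curvilinear sampler has the designed bond-length width", {
  toy <- makeTorsionStretch()
  n <- 20000
  ens <- toy$exactSampler(n, temperature = 0, seed = 31)
  r <- coordinateSeries(ens, InternalCoordinateSpec("distance", c(2, 3)))
  sd_ref <- sqrt(wigner_var_q(toy$params$nuStretch) / toy$params$mu)
  expect_equal(sd(r), sd_ref, tolerance = 3 * sqrt(2 / n))
})

test_that("rectilinear Wigner inflates the stretch; exclusion cures it", {
  toy <- makeTorsionStretch()
  nm <- normalModeAnalysis(finiteDifferenceHessian(toy$potential),
                           project = FALSE)
  spec <- InternalCoordinateSpec("distance", c(2, 3))
  n <- 1500
  exact <- toy$exactSampler(n, temperature = 296, seed = 1)
  wig <- sampleWigner(nm, WignerSettings(nSamples = n, temperature = 296,
                                         seed = 2))
  ratio <- sd(coordinateSeries(wig, spec)) /
    sd(coordinateSeries(exact, spec))
  expect_gt(ratio, 1.5)
  wig2 <- sampleWigner(nm, WignerSettings(nSamples = n, temperature = 296,
                                          excludedModes = 1, seed = 2))
  ratio2 <- sd(coordinateSeries(wig2, spec)) /
    sd(coordinateSeries(exact, spec))
  expect_lt(ratio2, 1.1)
})

test_that("soft-intermolecular toy: uncoupled limit matches Wigner widths", {
  soft <- makeSoftIntermolecular(coupling = 0)
  nm <- normalModeAnalysis(finiteDifferenceHessian(soft$potential),
                           project = FALSE)
  ## softest mode at the designed curvature; Wigner variance of the
  ## intermolecular distance equals the harmonic prediction
  spec <- InternalCoordinateSpec("distance", c(1, 2))
  n <- 8000
  ens <- sampleWigner(nm, WignerSettings(nSamples = n, seed = 8))
  r <- coordinateSeries(ens, spec)
  ## analytic: project displacement onto the relative-x coordinate
  L <- modeVectors(nm)
  m3 <- rep(atomicMasses(nm@geometry), each = 3)
  u <- c(-1, 0, 0, 1, 0, 0) / sqrt(m3)      # d(x2 - x1)
  var_ana <- sum((colSums(L * u))^2 *
                 vapply(frequencies(nm), wigner_var_q, numeric(1)))
  expect_equal(var(r) / var_ana, 1, tolerance = 0.06)
})

test_that("toy chromophores map ensembles to transition tables", {
  toy <- makeTorsionStretch()
  nm <- normalModeAnalysis(finiteDifferenceHessian(toy$potential),
                           project = FALSE)
  ens <- sampleWigner(nm, WignerSettings(nSamples = 2000, seed = 12))
  r0 <- toy$params$r0
  ## constant maps: all records identical
  cst_chrom <- ToyChromophore(distanceCoordinate(2, 3),
    states = list(list(kind = "constant", E0 = 4, q0 = r0, f0 = 0.01)))
  tt <- evaluateChromophore(cst_chrom, ens)
  expect_equal(nrow(records(tt)), 2000)
  expect_true(all(records(tt)$delta_E_eV == 4))
  expect_true(all(records(tt)$osc_strength == 0.01))
  ## linear gap on a harmonic ensemble: Normal(E0, kappa sigma_q)
  kap <- -1.5
  lin <- ToyChromophore(distanceCoordinate(2, 3),
    states = list(list(kind = "linear", E0 = 4, kappa = kap, q0 = r0,
                       f0 = 0.01)))
  dE <- records(evaluateChromophore(lin, ens))$delta_E_eV
  r <- coordinateSeries(ens, InternalCoordinateSpec("distance", c(2, 3)))
  expect_equal(mean(dE), 4 + kap * (mean(r) - r0), tolerance = 1e-10)
  expect_equal(sd(dE), abs(kap) * sd(r), tolerance = 1e-10)
  ks <- ks.test(dE, "pnorm", mean(dE), sd(dE))
  expect_gt(ks$p.value, 1e-4)
  ## exponential map: perfect negative rank correlation with q
  ex <- ToyChromophore(distanceCoordinate(2, 3),
    states = list(list(kind = "exponential", E0 = 4, alpha = 2, q0 = r0,
                       f0 = 0.01)))
  dEe <- records(evaluateChromophore(ex, ens))$delta_E_eV
  expect_equal(cor(r, dEe, method = "spearman"), -1)
  ## non-positive gaps are refused
  bad <- ToyChromophore(distanceCoordinate(2, 3),
    states = list(list(kind = "linear", E0 = 0.001, kappa = -5, q0 = r0,
                       f0 = 0.01)))
  expect_error(evaluateChromophore(bad, ens), "non-positive")
})

test_that("torsion artifact grows monotonically as the torsion softens", {
  spec <- InternalCoordinateSpec("distance", c(2, 3))
  ratios <- vapply(c(400, 280, 200), function(nu_t) {
    toy <- makeTorsionStretch(nuTorsion = nu_t)
    nm <- normalModeAnalysis(finiteDifferenceHessian(toy$potential),
                             project = FALSE)
    wig <- sampleWigner(nm, WignerSettings(nSamples = 1200,
                                           temperature = 296, seed = 5))
    ex <- toy$exactSampler(1200, temperature = 296, seed = 6)
    sd(coordinateSeries(wig, spec)) / sd(coordinateSeries(ex, spec))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
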