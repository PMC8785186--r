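K <- physicalConstants()$internal$k_nea

test_that("single-line sum rule: integral sigma dE = K f", {
  f <- 0.01; dE <- 4
  tt <- TransitionTable("g1", 1, dE, f)
  shape <- LineShapeSpec("lorentzian", 0.05)
  grid <- seq(dE - 1.2, dE + 1.2, by = 0.005)
  ## pure-f weighting: exact up to quadrature + analytic tails
  sp0 <- assembleSigma(tt, shape, grid, energyWeighted = FALSE)
  I0 <- integrateSpectrum(sp0, tailCorrection = TRUE, lineCenter = dE,
                          lineStrength = K * f)
  expect_equal(I0, K * f, tolerance = 1e-4)
  ## full NEA weighting: dE/E factor ~ 1 near the line center
  sp <- assembleSigma(tt, shape, grid)
  I1 <- integrateSpectrum(sp, tailCorrection = TRUE, lineCenter = dE,
                          lineStrength = K * f)
  expect_equal(I1, K * f, tolerance = 0.02)
  ## prefactor magnitude check against CODATA constituents
  expect_equal(K, 1.0975e-16, tolerance = 2e-4)
})

test_that("zero strengths give an identically zero spectrum", {
  tt <- TransitionTable(c("a", "b"), c(1, 1), c(4, 4.2), c(0, 0))
  sp <- assembleSigma(tt)
  expect_true(all(crossSection(sp) == 0))
})

test_that("duplicating every geometry leaves the spectrum unchanged", {
  set.seed(2)
  dE <- runif(50, 3.8, 4.4)
  f <- runif(50, 0, 0.05)
  tt1 <- TransitionTable(sprintf("g%d", 1:50), 1, dE, f)
  tt2 <- TransitionTable(sprintf("g%d", 1:100), 1, rep(dE, 2), rep(f, 2))
  grid <- seq(3.3, 4.9, by = 0.005)
  s1 <- assembleSigma(tt1, grid = grid)
  s2 <- assembleSigma(tt2, grid = grid)
  expect_equal(crossSection(s1), crossSection(s2), tolerance = 1e-12)
})

test_that("sigma is linear in the oscillator strengths", {
  tt <- TransitionTable(c("a", "b"), c(1, 1), c(4, 4.3), c(0.01, 0.02))
  tt3 <- TransitionTable(c("a", "b"), c(1, 1), c(4, 4.3), 3 * c(0.01, 0.02))
  grid <- seq(3.5, 4.8, by = 0.01)
  expect_equal(3 * crossSection(assembleSigma(tt, grid = grid)),
               crossSection(assembleSigma(tt3, grid = grid)),
               tolerance = 1e-12)
})

test_that("grid refinement changes the integral by < 0.1%", {
  tt <- TransitionTable(sprintf("g%d", 1:20), 1, seq(3.9, 4.1, length.out = 20),
                        rep(0.01, 20))
  g1 <- seq(3.4, 4.6, by = 0.005)
  g2 <- seq(3.4, 4.6, by = 0.0025)
  I1 <- integrateSpectrum(assembleSigma(tt, grid = g1))
  I2 <- integrateSpectrum(assembleSigma(tt, grid = g2))
  expect_lt(abs(I2 - I1) / I1, 1e-3)
})

test_that("Boltzmann weights follow the closed forms", {
  w0 <- normalizedWeights(boltzmannWeights(c(0.3, 0.3), 296))
  expect_equal(unname(w0), c(0.5, 0.5))
  kT <- physicalConstants()$internal$kb_ev * 296
  w1 <- normalizedWeights(boltzmannWeights(c(0, kT * log(2)), 296))
  expect_equal(unname(w1), c(2 / 3, 1 / 3), tolerance = 1e-12)
  ## eight conformers: normalized and anti-monotone in energy
  set.seed(9)
  e8 <- runif(8, 0, 0.2)
  w8 <- normalizedWeights(boltzmannWeights(e8, 296,
                                           labels = paste0("c", 1:8)))
  expect_equal(sum(w8), 1, tolerance = 1e-12)
  expect_true(all(diff(w8[order(e8)]) <= 0))   # higher energy, lower weight
  expect_error(boltzmannWeights(c(0, 0.1), -5), "temperature")
})

test_that("conformer combination is the weighted sum", {
  grid <- seq(3.5, 4.5, 0.01)
  s1 <- Spectrum(grid, dnorm(grid, 4.0, 0.1) * 1e-17)
  s2 <- Spectrum(grid, dnorm(grid, 4.2, 0.15) * 1e-17)
  w <- boltzmannWeights(c(0, 0.02), 296, labels = c("a", "b"))
  tot <- combineConformers(list(a = s1, b = s2), w)
  wv <- normalizedWeights(w)
  expect_equal(crossSection(tot),
               wv[["a"]] * crossSection(s1) + wv[["b"]] * crossSection(s2),
               tolerance = 1e-12)
  ## weight (1, 0) returns the first spectrum exactly
  wd <- boltzmannWeights(c(0, 10), 296, labels = c("a", "b"))
  expect_equal(crossSection(combineConformers(list(a = s1, b = s2), wd)),
               crossSection(s1), tolerance = 1e-10)
  ## integral linearity
  Itot <- integrateSpectrum(tot)
  expect_equal(Itot, wv[["a"]] * integrateSpectrum(s1) +
                 wv[["b"]] * integrateSpectrum(s2), tolerance = 1e-10)
  ## grid mismatch is an error, not a silent regrid
  s3 <- Spectrum(grid + 0.001, crossSection(s2))
  expect_error(combineConformers(list(a = s1, b = s3), w), "grids")
})

test_that("composite spectra add fragments without weights", {
  grid <- seq(3, 5, 0.01)
  sA <- Spectrum(grid, dnorm(grid, 3.8, 0.2) * 1e-17)
  zero <- Spectrum(grid, numeric(length(grid)))
  expect_equal(crossSection(compositeSpectrum(list(sA, zero))),
               crossSection(sA))
  sB <- Spectrum(grid, dnorm(grid, 4.4, 0.1) * 2e-17)
  comp <- compositeSpectrum(list(sA, sB))
  expect_equal(integrateSpectrum(comp),
               integrateSpectrum(sA) + integrateSpectrum(sB),
               tolerance = 1e-12)
  expect_true(metadata(comp)$composite)
})

test_that("a coupled two-chromophore parent absorbs at least its composite", {
  ## fragments: two constant-strength linear-gap chromophores on the same
  ## harmonic coordinate; parent adds an interaction that increases f
  ## where the fragments' bands overlap
  n <- 3000
  q <- stratified_normal(n, 0, 0.05, seed = 77)
  ids <- sprintf("g%d", seq_len(n))
  grid <- seq(3.0, 5.2, by = 0.005)
  fragment <- function(E0, kap, f0) {
    assembleSigma(TransitionTable(ids, 1, E0 + kap * q, rep(f0, n)),
                  grid = grid)
  }
  sA <- fragment(3.9, 1.2, 0.010)
  sB <- fragment(4.3, 1.2, 0.015)
  comp <- compositeSpectrum(list(sA, sB))
  ## parent: same two states plus a positive interaction term in f
  parent <- assembleSigma(TransitionTable(
    c(ids, ids), rep(1:2, each = n),
    c(3.9 + 1.2 * q, 4.3 + 1.2 * q),
    c(rep(0.012, n), rep(0.017, n))), grid = grid)
  expect_true(all(crossSection(parent) - crossSection(comp) > -1e-25))
  expect_gt(integrateSpectrum(parent), integrateSpectrum(comp))
})

test_that("NEA spectrum converges to the reflection-principle band", {
  E0 <- 4; kappa <- 0.5; sx <- 0.03; f <- 0.01; n <- 5000
  q <- stratified_normal(n, 0, sx, seed = 13)
  tt <- TransitionTable(sprintf("g%d", 1:n), 1, E0 + kappa * q, rep(f, n))
  shape <- LineShapeSpec("lorentzian", 0.01)
  grid <- seq(E0 - 0.12, E0 + 0.12, by = 0.001)
  nea <- assembleSigma(tt, shape, grid)
  ref <- reflectionReference(E0, kappa, sx, f, shape, grid)
  dev <- max(abs(crossSection(nea) - crossSection(ref))) /
    max(crossSection(ref))
  expect_lt(dev, 0.03)
})

test_that("reflection reference limits: lineshape collapse and width scaling", {
  shape <- LineShapeSpec("lorentzian", 0.01)
  grid <- seq(3.8, 4.2, by = 5e-4)
  ## kappa sigma_x -> 0: band tends to the lineshape at E0
  tiny <- reflectionReference(4, 1e-4, 1e-3, 0.01, shape, grid,
                              energyWeighted = FALSE)
  pure <- 0.01 * K * lineshapeValues(shape, grid - 4)
  expect_lt(max(abs(crossSection(tiny) - pure)) / max(pure), 1e-3)
  ## doubling kappa doubles the fitted band std
  fit_sd <- function(kap) {
    sp <- reflectionReference(4, kap, 0.02, 0.01,
                              LineShapeSpec("gaussian", 0.002), grid)
    s <- crossSection(sp)
    sqrt(sum(s * (grid - sum(s * grid) / sum(s))^2) / sum(s))
  }
  expect_equal(fit_sd(2) / fit_sd(1), 2, tolerance = 0.01)
})
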