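test_that("ground-state Wigner variances match hbar/2omega at n = 20000", {
  nus <- c(200, 1000, 3600)
  nm <- synthetic_modes(nus)
  n <- 20000
  ens <- sampleWigner(nm, WignerSettings(nSamples = n, seed = 101))
  Q <- normalCoordinates(ens)
  for (i in seq_along(nus)) {
    tgt <- wigner_var_q(nus[i])
    se <- tgt * sqrt(2 / n)
    expect_lt(abs(var(Q[, i]) - tgt), 3 * se)
  }
})

test_that("finite-temperature variance carries the coth factor", {
  ## wavenumber chosen so hbar omega / 2 kT = 1 at 296 K
  nu1 <- 2 * cst$kb_ev * 296 / cst$hbar_evfs / (2 * pi * cst$c_cmfs)
  nm <- synthetic_modes(nu1)
  n <- 20000
  ens <- sampleWigner(nm, WignerSettings(nSamples = n, temperature = 296,
                                         seed = 5))
  ratio <- var(normalCoordinates(ens)[, 1]) / wigner_var_q(nu1, 0)
  expect_lt(abs(ratio - 1 / tanh(1)), 3 * (1 / tanh(1)) * sqrt(2 / n))
})

test_that("excluded modes are frozen exactly", {
  nm <- synthetic_modes(c(200, 1000, 3600))
  ens <- sampleWigner(nm, WignerSettings(nSamples = 200,
                                         excludedModes = 1, seed = 3))
  Q <- normalCoordinates(ens)
  expect_identical(max(abs(Q[, 1])), 0)
  ## project members back onto the excluded mode vector: zero displacement
  L <- modeVectors(nm)
  x0 <- as.vector(t(coordinates(nm@geometry)))
  m3 <- rep(atomicMasses(nm@geometry), each = 3)
  for (k in c(1, 100, 200)) {
    dx <- as.vector(t(coordinateArray(ens)[, , k])) - x0
    expect_lt(abs(sum(L[, 1] * sqrt(m3) * dx)), 1e-12)
    expect_gt(abs(sum(L[, 2] * sqrt(m3) * dx)), 0)
  }
})

test_that("sampling refuses imaginary non-excluded modes", {
  h <- diatomic_hessian(-10)
  nm <- suppressWarnings(normalModeAnalysis(h))
  expect_error(sampleWigner(nm, WignerSettings(nSamples = 10, seed = 1)),
               "imaginary")
  ## but excluding the offending mode is allowed
  ens <- sampleWigner(nm, WignerSettings(nSamples = 10, excludedModes = 1,
                                         seed = 1))
  expect_equal(nMembers(ens), 10)
})

test_that("sampled Cartesian covariance matches the analytic form", {
  nm <- synthetic_modes(c(500, 2000))
  n <- 20000
  ens <- sampleWigner(nm, WignerSettings(nSamples = n, seed = 7))
  flat <- t(apply(coordinateArray(ens), 3, function(x) as.vector(t(x))))
  emp <- cov(flat)
  L <- modeVectors(nm)
  sdq2 <- vapply(frequencies(nm), wigner_var_q, numeric(1), temperature = 0)
  m3 <- rep(atomicMasses(nm@geometry), each = 3)
  ana <- (L %*% (sdq2 * t(L))) * outer(1 / sqrt(m3), 1 / sqrt(m3))
  se <- sqrt((outer(diag(ana), diag(ana)) + ana^2) / n)
  expect_lt(max(abs(emp - ana) / pmax(se, 1e-12)), 6)
})

test_that("identical seed and settings give bit-identical ensembles", {
  nm <- synthetic_modes(c(200, 3600))
  s <- WignerSettings(nSamples = 50, temperature = 296, seed = 42)
  e1 <- sampleWigner(nm, s)
  e2 <- sampleWigner(nm, s)
  expect_identical(coordinateArray(e1), coordinateArray(e2))
  expect_identical(e1@momenta, e2@momenta)
  e3 <- sampleWigner(nm, WignerSettings(nSamples = 50, temperature = 296,
                                        seed = 43))
  expect_false(identical(coordinateArray(e1), coordinateArray(e3)))
})

test_that("quantum/classical width ratio has the right limits", {
  ## classical limit
  nuc <- 0.01 * 2 * cst$kb_ev * 296 / cst$hbar_evfs / (2 * pi * cst$c_cmfs)
  expect_equal(classicalLimitCheck(nuc, 296), 1, tolerance = 1e-4)
  ## high-frequency asymptote: ratio ~ hbar omega / 2 kT
  x <- cst$hbar_evfs * omegaFromWavenumber(30000) / (2 * cst$kb_ev * 296)
  expect_equal(classicalLimitCheck(30000, 296), x, tolerance = 1e-10)
  expect_true(all(classicalLimitCheck(c(10, 100, 1000, 5000), 296) >= 1))
  expect_error(classicalLimitCheck(3600, 0), "T = 0|> 0")
})

test_that("closed-form width ratio agrees with quadrature of the densities", {
  ## nu = 3600 cm^-1, T = 296 K: integrate the quantum-thermal and the
  ## classical harmonic position densities for their second moments
  nu <- 3600; temp <- 296; m <- 1
  om <- omegaFromWavenumber(nu)
  kT <- cst$kb_ev * temp
  varq <- cst$hbar_evfs / cst$amu_evfs / (2 * om) /
    tanh(cst$hbar_evfs * om / (2 * kT))
  varc <- kT / (m * cst$amu_evfs * om^2)
  m2 <- function(v) {
    integrate(function(x) x^2 * dnorm(x, 0, sqrt(v)), -Inf, Inf)$value
  }
  expect_equal(classicalLimitCheck(nu, temp), m2(varq) / m2(varc),
               tolerance = 1e-6)
})

test_that("center of mass is preserved for translation-free mode sets", {
  ## modes from a projected Hessian have no translational component
  h <- diatomic_hessian(30)
  nm <- normalModeAnalysis(h)
  ens <- sampleWigner(nm, WignerSettings(nSamples = 500, seed = 9))
  m <- atomicMasses(ens)
  com0 <- colSums(coordinates(h@geometry) * m) / sum(m)
  coms <- apply(coordinateArray(ens), 3, function(x)
    colSums(x * m) / sum(m))
  expect_lt(max(abs(coms - com0)), 1e-12)
})
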