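test_that("propagator limits: free dynamics and white-noise Langevin", {
  kT <- cst$kb_ev * 296
  ## A = 0: no thermostat
  g0 <- GLEParameters(matrix(0, 1, 1), matrix(kT, 1, 1), 296)
  p <- buildPropagator(g0, 0.5)
  expect_equal(p$Thalf, diag(1))
  expect_equal(p$Shalf, matrix(0, 1, 1))
  ## Ns = 0 scalar closed form
  gamma <- 0.37; dt <- 0.5
  g1 <- classical_gle(gamma)
  p1 <- buildPropagator(g1, dt)
  expect_equal(p1$Thalf[1, 1], exp(-gamma * dt / 2), tolerance = 1e-7)
  expect_equal(p1$Shalf[1, 1]^2, kT * (1 - exp(-gamma * dt)),
               tolerance = 1e-5)
})

test_that("bundled QT matrices give a consistent symmetric factorization", {
  gle <- qtFixtureParameters()
  p <- buildPropagator(gle, 0.5)
  M <- covarianceMatrix(gle) -
    p$Thalf %*% covarianceMatrix(gle) %*% t(p$Thalf)
  expect_lt(max(abs(p$Shalf %*% t(p$Shalf) - M)), 1e-10)
})

test_that("unstable (A, C) pairs are rejected", {
  ## C much larger along the auxiliary DOF than the drift can sustain
  A <- rbind(c(0.1, -2), c(2, 0.1))
  C <- diag(c(1, 1e-6))
  expect_error(buildPropagator(GLEParameters(A, C, 296), 0.5),
               "not positive semidefinite")
})

test_that("zero-noise integrator conserves energy (symplectic limit)", {
  m <- 12; nu <- 100
  k <- m * cst$amu_evfs * omegaFromWavenumber(nu)^2
  pot <- makeHarmonicND(Geometry("C", matrix(0, 1, 3), masses = m), k)
  start <- Geometry("C", matrix(c(0.1, 0, 0), 1, 3), masses = m)
  gle <- GLEParameters(matrix(0, 1, 1),
                       matrix(cst$kb_ev * 296, 1, 1), 296)
  traj <- runQT(pot, start, gle,
                QTSettings(dt = 0.5, nSteps = 10000, stride = 1, seed = 1))
  v <- traj@velocities; fr <- coordinateArray(traj)
  E <- vapply(seq_len(nMembers(traj)), function(i)
    0.5 * m * cst$amu_evfs * sum(v[, , i]^2) + 0.5 * k * sum(fr[, , i]^2),
    numeric(1))
  ## no secular drift; bounded Verlet oscillation
  drift <- abs(mean(E[9001:10000]) - mean(E[1:1000])) / E[1]
  expect_lt(drift, 1e-6)
  expect_lt((max(E) - min(E)) / E[1], 1e-4)
})

test_that("classical white-noise limit recovers equipartition", {
  m <- 12; nu <- 1000
  k <- m * cst$amu_evfs * omegaFromWavenumber(nu)^2
  g <- Geometry("C", matrix(0, 1, 3), masses = m)
  pot <- makeHarmonicND(g, k)
  traj <- runQT(pot, g, classical_gle(0.02),
                QTSettings(dt = 0.5, nSteps = 60000, stride = 5, seed = 3))
  eq <- detectEquilibration(traj)
  fr <- coordinateArray(traj)[, , traj@frameSteps >= eq]
  expect_equal(var(c(fr)), cst$kb_ev * 296 / k, tolerance = 0.05)
})

test_that("stationary momentum variance on a free particle equals C[1,1]", {
  gle <- qtFixtureParameters()
  m <- 12
  g <- Geometry("C", matrix(0, 1, 3), masses = m)
  free <- PotentialSurface(function(x) 0, function(x) matrix(0, 1, 3),
                           list(kind = "free"), g)
  traj <- runQT(free, g, gle,
                QTSettings(dt = 0.25, nSteps = 40000, stride = 2, seed = 11))
  v <- traj@velocities
  p2 <- m * cst$amu_evfs * mean(v^2)   # <p~^2> over dofs and frames
  expect_equal(p2, covarianceMatrix(gle)[1, 1], tolerance = 0.08)
})

test_that("identical seeds reproduce trajectories bit-for-bit", {
  m <- 12
  k <- m * cst$amu_evfs * omegaFromWavenumber(800)^2
  g <- Geometry("C", matrix(0, 1, 3), masses = m)
  pot <- makeHarmonicND(g, k)
  s <- QTSettings(dt = 0.5, nSteps = 500, stride = 5, seed = 21)
  t1 <- runQT(pot, g, classical_gle(0.05), s)
  t2 <- runQT(pot, g, classical_gle(0.05), s)
  expect_identical(coordinateArray(t1), coordinateArray(t2))
  expect_identical(kineticTemperature(t1), kineticTemperature(t2))
})

test_that("equilibration detection finds the settling point", {
  mk_traj <- function(tser) {
    new("Trajectory", frames = array(0, c(1, 3, 1)),
        velocities = array(0, c(1, 3, 1)),
        kineticTemperature = tser, potentialEnergy = numeric(length(tser)),
        frameSteps = 1L,
        settings = QTSettings(nSteps = length(tser),
                              equilibrationWindow = 200,
                              temperatureTolerance = 0.02, seed = 1),
        reference = Geometry("C", matrix(0, 1, 3)))
  }
  expect_equal(detectEquilibration(mk_traj(rep(300, 2000))), 1L)
  step <- c(rep(100, 1000), rep(300, 4000))
  idx <- detectEquilibration(mk_traj(step))
  ## settles within the window around the jump (tolerance admits a few
  ## pre-jump samples in the running mean)
  expect_gte(idx, 950)
  expect_lte(idx, 1200)
  expect_error(detectEquilibration(mk_traj(seq(100, 400, length.out = 500))),
               "never converged")
})

test_that("snapshot extraction strides uniformly and checks budgets", {
  nfr <- 1000
  frames <- array(seq_len(nfr * 3), c(1, 3, nfr))
  traj <- new("Trajectory", frames = frames,
              velocities = array(0, c(1, 3, nfr)),
              kineticTemperature = rep(300, nfr),
              potentialEnergy = numeric(nfr),
              frameSteps = seq_len(nfr),
              settings = QTSettings(nSteps = nfr, stride = 1, seed = 1),
              reference = Geometry("C", matrix(0, 1, 3)))
  ens <- extractSnapshots(traj, 500, equilibratedFrom = 1)
  expect_equal(nMembers(ens), 500)
  expect_equal(diff(metadata(ens)$frameSteps), rep(2L, 499))
  expect_error(extractSnapshots(traj, 1001, equilibratedFrom = 1),
               "insufficient")
  ## conformer labels propagate
  e2 <- extractSnapshots(traj, 10, equilibratedFrom = 1,
                         conformerLabel = "ttt")
  expect_equal(geometryLabel(e2), "ttt")
})

test_that("blow-up guard aborts with the offending step", {
  m <- 1
  g <- Geometry("H", matrix(0, 1, 3), masses = m)
  steep <- PotentialSurface(function(x) -1e3 * x[1, 1],
                            function(x) matrix(c(-1e3, 0, 0), 1, 3),
                            list(kind = "cliff"), g)
  expect_error(
    runQT(steep, g, classical_gle(0.01),
          QTSettings(dt = 0.5, nSteps = 1000, stride = 10, seed = 2)),
    "blow-up")
})
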