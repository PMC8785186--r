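## Shared builders for the test suite. Everything is generated in code.

cst <- physicalConstants()$internal

## diatomic along x with force constant k (eV/A^2)
diatomic_hessian <- function(k = 30, symbols = c("H", "Cl"), r = 1.27,
                             masses = atomicMass(symbols)) {
  g <- Geometry(symbols, rbind(c(0, 0, 0), c(r, 0, 0)), masses)
  H <- matrix(0, 6, 6)
  H[1, 1] <- H[4, 4] <- k
  H[1, 4] <- H[4, 1] <- -k
  HessianMatrix(H, g)
}

## synthetic mode set: n_modes uncoupled unit-mass oscillators embedded in
## a 3-atom geometry; mode i displaces the x coordinate of atom i
synthetic_modes <- function(nu_cm) {
  stopifnot(length(nu_cm) <= 3)
  g <- Geometry(rep("X", 3),
                rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                masses = rep(1, 3))
  H <- matrix(0, 9, 9)
  for (i in seq_along(nu_cm)) {
    lam <- cst$amu_evfs * omegaFromWavenumber(nu_cm[i])^2
    H[3 * (i - 1) + 1, 3 * (i - 1) + 1] <- lam
  }
  normalModeAnalysis(HessianMatrix(H, g), project = FALSE)
}

## quantum harmonic Var(Q) (amu A^2) for wavenumber nu at temperature T
wigner_var_q <- function(nu_cm, temperature = 0) {
  om <- omegaFromWavenumber(nu_cm)
  coth <- if (temperature > 0) {
    1 / tanh(cst$hbar_evfs * om / (2 * cst$kb_ev * temperature))
  } else 1
  cst$hbar_evfs / cst$amu_evfs / (2 * om) * coth
}

## classical white-noise Langevin parameters
classical_gle <- function(gamma = 0.02, temperature = 296) {
  GLEParameters(matrix(gamma, 1, 1),
                matrix(cst$kb_ev * temperature, 1, 1),
                temperature, classicalC = TRUE)
}

## stratified (variance-reduced) normal sample: marginally exact N(mu, sd)
stratified_normal <- function(n, mu, sd, seed) {
  set.seed(seed)
  u <- (seq_len(n) - stats::runif(n)) / n
  mu + sd * stats::qnorm(sample(u))
}
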