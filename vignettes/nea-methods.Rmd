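---
title: "Nuclear-ensemble photoabsorption cross-sections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear-ensemble photoabsorption cross-sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neaspec)
```

## The model

A photoabsorption cross-section $\sigma(E)$ is the fingerprint a molecule
presents to light, and — folded with an actinic flux $F(\lambda)$ and a
quantum yield $\phi(\lambda)$ — it determines the photolysis rate
coefficient of a volatile organic compound in the troposphere:

$$ j = \int \sigma(\lambda)\,\phi(\lambda)\,F(\lambda)\,\mathrm d\lambda. $$

The nuclear ensemble approach (NEA) approximates the band shape of
$\sigma(E)$ by sampling nuclear configurations $\mathbf R_n$ from the
ground-state nuclear density, evaluating a vertical excitation energy
$\Delta E_{0J}(\mathbf R_n)$ and oscillator strength
$f_{0J}(\mathbf R_n)$ for each geometry and electronic state $J$, and
averaging broadened sticks:

$$ \sigma(E) \;=\; \frac{\pi e^2 \hbar}{2 m_e c \varepsilon_0}\,
   \frac1E \sum_{J}^{N_s} \frac1{N_p} \sum_{n}^{N_p}
   \Delta E_{0J}(\mathbf R_n)\, f_{0J}(\mathbf R_n)\,
   w_s\!\left[E - \Delta E_{0J}(\mathbf R_n),\, \delta\right], $$

with $w_s$ a unit-normalized lineshape of phenomenological width
$\delta$. The prefactor $K = \pi e^2\hbar / (2 m_e c \varepsilon_0)$
evaluates to $1.0975\times10^{-16}$ eV cm$^2$ from CODATA 2018 constants
(`physicalConstants()`), so the assembled cross-section is absolute, in
cm$^2$ molecule$^{-1}$, with no empirical shift or scale anywhere in the
pipeline. The NEA captures band positions, widths and intensities —
including non-Condon geometry dependence of the transition strength — but
by construction contains no vibronic fine structure.

Because the sum collapses to $K\,\bar f$ when integrated over a narrow
band, the package pins its conventions with a sum rule (see the test
suite): $\int\sigma\,\mathrm dE = K f$ for a single line, with the
slowly-decaying Lorentzian tails corrected analytically.

### Two quantum samplers

Everything interesting happens in how the $\mathbf R_n$ are drawn.
Classical thermal sampling at room temperature misses zero-point motion
entirely and produces bands that are far too narrow, so both samplers aim
at the *quantum* ground-state density:

**Harmonic Wigner sampling** (`sampleWigner`). From a Hessian at the
minimum, `normalModeAnalysis` builds mass-weighted rectilinear normal
modes; each mode $i$ is an independent Gaussian in the normal coordinate
with
$$\mathrm{Var}(Q_i) = \frac{\hbar}{2\omega_i}
  \coth\!\frac{\hbar\omega_i}{2k_BT},$$
the $\coth$ factor being 1 at $T=0$ and reducing to the classical
$k_BT/\omega_i^2$ in the high-temperature limit (`classicalLimitCheck`
reports the quantum/classical variance ratio per mode). Momenta are
sampled with the conjugate variance for completeness, though the spectrum
pipeline uses only geometries.

**Quantum-thermostat (QT) sampling** (`runQT`). Classical molecular
dynamics driven by a colored-noise generalized Langevin thermostat: each
mass-scaled momentum couples to $N_s$ auxiliary momenta through a drift
matrix $A$ with stationary covariance $C$, fitted so that every
vibrational frequency is held at its own effective temperature. The
dynamics never invokes the harmonic approximation, so mode coupling and
anharmonicity of the real surface are sampled faithfully; on uncoupled
harmonic oscillators the method is exact, which is the module's central
test property.

### Why two samplers: the rectilinear torsion artifact

Rectilinear normal modes displace atoms along straight lines. For a soft
torsion of a light atom around a stiff bond this is a poor coordinate: the
atom is sheared off its arc, which *stretches* the adjacent bond with no
energy penalty. Spurious large bond elongations then pick up spurious
low-energy, high-strength transitions (dissociative $n\sigma^*$ states
whose gap collapses with bond elongation), polluting the cross-section.

The package reproduces this artifact on an analytic 3-site toy
(`makeTorsionStretch`: O–H-like 3600 cm$^{-1}$ stretch, few-hundred
cm$^{-1}$ torsion of a 1-amu site, anchors of 16 amu, $r_0 = 0.96$ Å,
296 K). The toy also returns an exact curvilinear sampler — the
factorized quantum ground state in $(r, \theta)$ with reduced mass
$\mu = m_H m_B/(m_H+m_B)$ and moment of inertia $\mu r_0^2$, embedded
along the arc — as the reference. At the default parameters the
rectilinear-Wigner ensemble inflates std$(r)$ by a factor of about 2
relative to the exact reference; excluding the torsional mode
(`WignerSettings(excludedModes = ...)`) restores the ratio to within a
few percent of 1. The artifact grows monotonically as the torsion
softens. Supported mitigations are exactly these two: filter the
problematic mode, or use QT sampling, which needs no harmonic
approximation in the first place.

The rectilinear back-transform is retained *deliberately* — no
curvilinear correction is applied — because reproducing the artifact and
its mitigation is part of the package's purpose.

### Microsolvation-like broadening

`makeSoftIntermolecular` embeds a stiff chromophore coordinate
(~1700 cm$^{-1}$, mass 12) bilinearly coupled to a soft intermolecular
coordinate (~90 cm$^{-1}$, mass 18, a quartic-plus-harmonic well at
$d_0 = 2.8$ Å) — a cartoon of a hydrogen-bonded water rattling against a
carbonyl chromophore. Ground-state (0 K) harmonic Wigner sampling sees
only the curvature at the minimum; QT dynamics at 296 K additionally
samples thermal excitation and anharmonicity of the soft well, so the
soft-coordinate distribution is substantially broader under QT (std ratio
about 1.5–1.8 at the defaults). This mirrors the choice made in
production use of these methods: Wigner ensembles are generated at 0 K
(the common practice, and this package's default), QT runs thermostat to
the target temperature.

## The bundled QT matrices

Thermostat matrices are inputs in the GLE4MD plain-text convention
(`readGLEParameters`; $A$ in fs$^{-1}$ or ps$^{-1}$, $C$ in eV or K,
first index = physical momentum). The package bundles one synthetic QT
set, `inst/extdata/gle/qt296_ns6_{A,C}_synthetic.dat` ($N_s = 6$, target
296 K), produced by `fitQTParameters`: the stationary position and
momentum variances of a GLE-thermostatted harmonic oscillator are
analytic through a Lyapunov equation (`gleStationaryVariance`), and the
fit minimizes their deviation from
$(\hbar\omega/2)\coth(\hbar\omega/2k_BT)$ over 24 log-spaced frequencies
in 100–4000 cm$^{-1}$. The drift matrix is parameterized as a direct
coupling plus three damped-oscillatory memory channels; the noise
covariance is optimized through its triangular factor so it stays
positive semidefinite by construction, and $C$ is recovered from
$AC + CA^{\mathsf T} = BB^{\mathsf T}$. The frozen set reproduces the
quantum position variance to within ~3% across 150–3600 cm$^{-1}$
(momentum within ~2%), and the discrete-time propagator
$C - TCT^{\mathsf T}$ is PSD at the default 0.5 fs step.

Two practical notes. First, the fitted coupling is weak at very low
frequencies, so soft modes decorrelate slowly (tens of ps); sampling
soft-mode distributions needs correspondingly long trajectories (the
package's own checks use 100–300 ps) and `detectEquilibration` to discard
the transient. Second, a single $(A, C)$ pair serves every atom because
the thermostat acts on mass-scaled momenta.

## Numerical choices

* **Units.** Å, amu, eV, fs, cm$^{-1}$ internally; every conversion goes
  through one CODATA 2018 constants table. Molden `[FR-COORD]` is Bohr
  (Molden standard), XYZ is Å, $\lambda\,[\mathrm{nm}] = 1239.841984/E\,
  [\mathrm{eV}]$.
* **Lineshape.** $\delta$ is interpreted as the FWHM of the normalized
  lineshape (Lorentzian by default, $\delta = 0.05$ eV); broadening is
  performed on the energy axis and the wavelength column is derived
  afterwards. Default grid spacing $\delta/10$, default grid padding
  $5\delta$ beyond the extreme lines. Vacuum is assumed ($n = 1$).
* **Energy weighting.** The $\Delta E/E$ factor of the NEA expression is
  kept by default; `assembleSigma(..., energyWeighted = FALSE)` switches
  to pure-$f$ weighting for cross-checks. Both collapse to the same
  line-center intensity; the sum rule pins the behavior.
* **Vibrational analysis.** The Hessian is symmetrized on construction
  (asymmetry beyond $10^{-8}$ relative is an error). Eckart projection
  removes rigid translations and infinitesimal rotations for
  rotation-invariant potentials; anchored model potentials, whose
  external motions carry real restoring forces, skip projection. Modes
  below a 10 cm$^{-1}$ floor are discarded as residual external (or
  genuinely free) coordinates — the studied molecules have no physical
  modes that low, and the threshold is configurable. Imaginary
  frequencies are reported as negative wavenumbers; the Wigner sampler
  refuses them unless excluded.
* **Integrator.** Symmetric splitting (GLE half-step, velocity half-kick,
  drift, force, half-kick, GLE half-step), chosen for stationarity of the
  harmonic distribution; with $A = 0$ it reduces to velocity Verlet
  (energy drift $<10^{-6}$ relative over $10^4$ steps in the tests, with
  the usual bounded Verlet oscillation). Thermostat state is initialized
  from $C$; a step displacing any coordinate by more than 0.5 Å aborts as
  a blow-up. Equilibration is detected as the first step whose
  running-window kinetic-temperature mean matches the post-window mean
  within a relative tolerance (5% over 2000 steps by default).
* **Reduced masses** are reported with the inverse-participation
  convention $\mu_i = (\sum_j L_{ij}^2/m_j)^{-1}$; conventions differ
  between codes, so they are reporting-only and never enter the
  sampling.
* **Photolysis.** Union-grid trapezoid with linear interpolation (the
  atmospheric community's tables are piecewise linear); no extrapolation
  outside any table's support; negative interpolated values are clipped
  to zero with a warning.
* **Reflection oracle.** The closed-form reference band for a linear gap
  map over a Gaussian coordinate density is convolved with the lineshape
  by quadrature; when the band is much narrower than the lineshape the
  convolution collapses analytically onto the lineshape. Validation
  against this oracle uses stratified (variance-reduced, marginally
  exact) normal sampling so that the comparison probes the assembly
  code, not Monte-Carlo noise.
* **Determinism.** Every stochastic entry point requires a seed; no
  silent time-based seeding. Identical seeds give bit-identical
  ensembles, trajectories and output files. RNG state of the calling
  session is restored afterwards.

## What the synthetic systems do and do not show

The bundled potentials and toy chromophores are analytic stand-ins for an
electronic-structure engine; transitions enter through a CSV contract
(`geometry_id,state,delta_E_eV,osc_strength`), so a real engine can be
substituted file-for-file. The toys emulate the *mechanisms* — harmonic
zero-point width, torsional artifacts of rectilinear sampling, soft-mode
thermal/anharmonic broadening, conformer Boltzmann mixing, SAR-style
composite spectra — at desk scale, with parameters chosen to mimic the
physically relevant regimes (O–H-like stretches, few-hundred-cm$^{-1}$
torsions, weak intermolecular wells, 296 K). Passing tests therefore
demonstrate correctness of the sampling, assembly and integration
machinery, and qualitative reproduction of the sampling artifacts; they
do not validate any electronic-structure method, absolute band positions
of real molecules, or Å-scale histograms of real bond-length
distributions, all of which depend on the quantum-chemistry surfaces.

Problem sizes used by the checks (chosen to keep every statistical
tolerance comfortably resolved): Wigner variance checks at
$n = 20{,}000$; spectra at $N_p = 500$–5000; QT harmonic checks over
$2\times10^5$ steps of 0.5 fs with 12 replicas per oscillator; the
soft-mode comparison over $6\times10^5$ steps with 500 extracted
snapshots.

## Known limitations

* Exact (anharmonic) Wigner transforms, path-integral methods (PIMD,
  PI+GLE, PIGLET) and vibronically resolved (Franck–Condon type) spectra
  are out of scope.
* Conformer handling weights whole-conformer spectra by Boltzmann
  factors; trajectories keep their starting conformer label and are never
  re-assigned to basins (a basin-occupancy diagnostic would be the
  extension point).
* The bundled QT matrix set targets 296 K and 100–4000 cm$^{-1}$; other
  temperatures or unusually soft/stiff systems need their own fit
  (`fitQTParameters`) or externally supplied GLE4MD matrices.
* Classical thermal sampling is available only as a diagnostic limit
  (classical $C = k_BT\,I$), not as a production sampling mode.
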