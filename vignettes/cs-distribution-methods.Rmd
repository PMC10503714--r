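---
title: "Sedimentation coefficient distributions by direct boundary modelling: methods and numerical choices"
author: "svengine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sedimentation coefficient distributions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(svengine)
```

# The measurement and the model

In a sedimentation velocity experiment a solution column between the
meniscus radius $m$ and the cell bottom $b$ (cm from the center of rotation)
is spun at angular velocity $\omega$, and an optical system records signal
profiles $a(r, t)$ at a sequence of times. A single ideal species with
sedimentation coefficient $s$ and diffusion coefficient $D$ evolves
according to the Lamm equation in the sector-shaped cell,

$$\frac{\partial c}{\partial t} =
  \frac{1}{r}\frac{\partial}{\partial r}
  \left[ r D \frac{\partial c}{\partial r} - s\,\omega^2 r^2 c \right],$$

with zero-flux conditions at both ends of the column and, here, a uniform
unit initial loading. `svengine` fits the recorded boundaries directly as a
superposition of such single-species solutions,

$$a(r, t) \approx \int_{s_{\min}}^{s_{\max}} c(s)\, K(s; r, t)\, ds
  + \mathrm{TI}(r) + \mathrm{RI}(t) + b_0,$$

where $c(s)$ is the sedimentation coefficient distribution (signal density
per svedberg, $c \ge 0$), and the two systematic noise terms absorb the
radius-dependent (time-invariant, TI) and scan-dependent (radial-invariant,
RI) offsets that are characteristic of interference and, to a lesser
degree, absorbance optics.

Two kernels are implemented:

* **ls-g\*(s)** — the apparent distribution: non-diffusing step boundaries,
  $K = 0$ below the boundary position $m e^{s\omega^2 t}$ and the radial
  dilution plateau $e^{-2 s \omega^2 t}$ above it. When the boundary passes
  the bottom, the column is cleared and the kernel is zero (sedimented
  material is not represented).
* **c(s)** — the diffusion-deconvoluted distribution: full Lamm solutions in
  which $D(s)$ follows from a single frictional ratio $f/f_0$ shared by all
  species,
  $$D(s) = \frac{\sqrt{2}}{18\pi}\, kT\, s^{-1/2}
    \left(\eta \frac{f}{f_0}\right)^{-3/2}
    \left(\frac{1 - \bar v \rho}{\bar v}\right)^{1/2},$$
  with $s$ in seconds and all quantities in CGS units ($\eta$: solvent
  viscosity in poise, $\rho$: density in g/mL, $\bar v$: partial-specific
  volume in mL/g). This is the standard hydrodynamic scaling law of c(s)
  analysis; it is exact for a single compact species and a controlled
  approximation for mixtures, where $f/f_0$ acts as a weight-average shape
  parameter. The absolute temperature is taken from the scan-file headers
  (average over the loaded scans), since the solvent parameters of the
  request refer to the experimental temperature.

The assumptions are those of standard c(s) work: ideal, non-interacting
sedimentation (no concentration dependence of $s$ or $D$), constant rotor
speed (the generator and the $\omega^2 t$ bookkeeping assume instant
acceleration), constant temperature, and a common frictional ratio.

# The inversion

The integral is discretized on a grid of `Resolution` s-values between
`Smin` and `Smax`, arithmetic by default or geometric with
`UseLogSpaceSgrid` (geometric spacing matches the roughly constant relative
resolution of SV-AUC). Internally the unknowns are density values at the
nodes; kernel columns are scaled by the trapezoidal node weights so that
$\sum_i c_i w_i$ is the total fitted signal.

**Noise elimination.** For fixed $c$, the optimal TI/RI/baseline terms are
linear least squares; data and kernels are therefore projected onto the
orthogonal complement of the noise subspace (pivoted QR), the non-negative
problem is solved on the projected system, and the noise components are
recovered from the residual afterwards. TI + RI + baseline are mutually
collinear in their constant components; the reported decomposition follows
a fixed convention: the mean of RI is shifted into the baseline if fitted,
otherwise into TI, and when both TI and a baseline are fitted the TI mean
is shifted into the baseline. This affects only the decomposition, never
the fit.

**Non-negativity.** The core solver is a Lawson–Hanson active-set NNLS on
the normal equations, with KKT conditions verified at exit. It is written
in the package (and cross-checked in the tests against an exhaustive
feasible-subset oracle) because its termination and KKT contract are part
of the package's specification.

**Regularization.** Unregularized inversions of diffusion-broadened
boundaries produce spurious spikes. The regularization weight $\lambda$ is
chosen by the F-statistics criterion: with $SSR_0$ the unregularized
optimum and $\nu = N_\text{points} - (K + \mathrm{rank}\,N)$ the residual
degrees of freedom, the target is
$SSR(\lambda) \le SSR_0 \cdot F(p;\,\nu,\nu)$ at the request's
`RegularizationPvalue` $p \in [0.5, 1]$ (default 0.68, the one-sigma
convention). The symmetric-degrees-of-freedom variance-ratio convention is
a documented choice of this implementation. The largest admissible
$\lambda$ is found by bisection on $\log\lambda$ (bracket $10^{\pm 6}$ on a
normalized scale, terminating when the SSR is within 0.1% of the target;
if even the bracket ends fail, the corresponding end is returned with a
warning). Two penalty families are available:

* `Tikhonov` — squared second differences of $c$ (natural ends), favoring
  smooth distributions;
* `maxent` — $\sum_i c_i \ln(c_i/\bar c)$ with the uniform reference
  $\bar c$ = total signal / grid span, solved by iterated local
  quadratic reweighting around the current iterate (at most 80 sweeps,
  relative tolerance $10^{-3}$; non-convergence is a solver error).

`SuppressBaselineCorrelation` adds a strong prior (weight $10^3$, adjustable
via `options(svengine.baseline_prior_weight=)`) pinning the smallest grid
node toward zero, which removes the well-known degeneracy between baseline
offsets and near-zero s-values.

# Nonlinear regression

Meniscus, bottom and $f/f_0$ enter the kernels nonlinearly. When flagged
for fitting they are optimized within their request bounds, with the
projected linear fit as the inner objective. Two algorithms are provided:

* **Simplex** (Nelder–Mead) with the initial simplex built by a seeded
  random perturbation within 2% of each parameter's bound span. The seed is
  derived deterministically from the handshake string, so repeat runs of
  the same session are bit-identical — randomized restarts otherwise make
  fits irreproducible at the last digits.
* **Levenberg–Marquardt** with forward-difference Jacobians (relative step
  $10^{-4}$ of the bound span), multiplicative damping, and bound
  projection.

Convergence for both: relative SSR improvement below $10^{-6}$ over 5
iterations, capped at 200 iterations. During the optimization the objective
is the *unregularized* SSR; the final distribution is the regularized fit
at the best-fit parameters. This is a deliberate design choice: the
regularization criterion is itself defined relative to the unregularized
optimum, so applying it inside the objective would rescale both sides of
every comparison while tripling the cost. Bottom fitting defaults to off —
unless back-diffusion is visible in the fit range, the bottom position is
not determined by the data.

# Numerical solution of the Lamm equation

The solver uses Crank–Nicolson time stepping on a finite-element (hat
function) discretization over a log-spaced radial grid (180 nodes by
default), the standard well-conditioned scheme for this PDE. The weak form
gives tridiagonal mass and transport matrices (2-point Gauss per element,
exact for the cubic integrands); the time step is bounded so the boundary
moves at most one radial cell per step, and the factorized tridiagonal
system is marched in compiled code. Two properties follow by construction
and are asserted in the tests:

* discrete mass $\mathbf{1}^T B c$ is conserved exactly (the transport
  operator has vanishing column sums), and
* requested output times are met by linear interpolation between steps,
  consistent with the scheme's second-order accuracy.

Advection-dominated configurations (small $D$, coarse grid) destabilize a
pure Galerkin scheme. Elements whose cell Péclet number
$\mathrm{Pe} = v h / 2D$ exceeds 1 therefore receive the minimal artificial
diffusion $(vh/2)(1 - 1/\mathrm{Pe})$ (critical upwinding). Well-resolved
kernels — all c(s) kernels at typical grids — carry no numerical
broadening; the addition is $O(h)$ only across under-resolved fronts and
vanishes under refinement. The residual numerical smearing at the cell
bottom (the back-diffusion layer is of width $D / s\omega^2 b$, often below
the grid scale) lies outside any sensible fit range, which is why the
convergence tests compare solutions over the analysis range rather than
across the pile-up at the bottom. Kernels are cached on
(s, D, geometry, rotor speed, time grid), so repeated evaluations at the
same nonlinear parameters are free.

`NumberComputationThreads` is accepted and echoed for protocol
compatibility; this implementation's numerics are deterministic and
single-threaded, so results are trivially invariant to the setting.

# Protocol behavior

The session lifecycle is: parse the three command-line tokens; read and
validate the XML request; refuse to run if the completion flag file already
exists; create the output directory (its leaf must not pre-exist, its
parent must); load, spike-filter and range-restrict the scans; analyze;
write `screenshot.bmp`, `RInoise.dat`, `TInoise.dat`, `ScanRMSD.dat`,
`distribution.dat`, `dfr.dat`, a JSON session log and
`ResultParameters.xml`; write the `sdist` grid file next to the scan data;
and only then create the flag file containing the handshake string. Any
failure before that point leaves no flag file, which is what a supervising
program polls for.

Decisions taken where the protocol leaves room (each is a fixed, documented
convention of this implementation):

* Defaults for unset parameters: booleans default to FALSE except
  `FilterDataSpikes` (TRUE, threshold 0.4) and `TINoiseFitted` /
  `RINoiseFitted` (TRUE, the customary treatment of systematic noise);
  `Model` defaults to `cofs`, `RegularizationType` to `maxent` with
  p = 0.68, `FittingAlgorithm` to `Simplex`, `StartingFrictionalRatio` to
  1.2, threads to 2. Unset meniscus/bottom fitting limits default to the
  point values themselves (a degenerate bracket, i.e. the parameter is
  effectively fixed until limits are supplied).
* Mode `112` is interpreted as a validation profile that rejects
  `GridfromFile`, `UseLogSpaceSgrid` and `BottomFitted`; the protocol
  names the restricted mode but not the restricted set, so the profile is
  a choice of this engine.
* `ResultParameters.xml` reuses the `cGMPSedfitCall` root, for symmetry
  with the input.
* Unknown input elements are ignored with a warning (forward
  compatibility); parameter names are case-sensitive; `PassThrough` is
  preserved verbatim including nested markup.
* `screenshot.bmp` keeps its name for drop-in compatibility although its
  content is a rendered plot (data+fit overlay, residuals, distribution,
  optional residuals histogram, and a text block with the rmsd), not a
  window capture. A GUI-style session-restore file is *not* written; a
  clearly non-compatible `session_log.json` takes its place.
* The spike filter removes an interior point when it deviates from both
  neighbors in the same direction by more than the threshold, sweeping to a
  fixpoint (which makes the filter idempotent); points are removed, not
  interpolated.
* `CheckTimeStamps` only reports whether file modification times were
  readable; no scan-time correction is applied.
* The runs-test orders residuals scan-major, radius-ascending, excluding
  zeros. `HistogramH` is a documented stand-in (RMS deviation of the
  standardized residual histogram, Scott's-rule bins, from the standard
  normal density); it shares the qualitative meaning "0 = Gaussian-like"
  but is not claimed to match any other software numerically.

# The synthetic-data generator

`simulation_spec()` / `generate_dataset()` simulate complete experiments:
sums of single-species Lamm solutions scaled by loadings, plus a smooth
deterministic TI profile, per-scan Gaussian RI offsets, white Gaussian
noise, and isolated spikes (interior points, mutually non-adjacent,
amplitude 1.0–1.5 signal units so they are unambiguous at the default 0.4
threshold). All randomness derives from one seed; generation is
byte-reproducible. `nistmab_like_preset()` fixes the study conditions used
throughout the validation: four species at 4.2 / 6.5 / 9.5 / 16.8 S with a
common $f/f_0$ of 1.37 and loadings 0.0095 / 0.2920 / 0.1251 / 0.5177
signal units (the fractions of a partially degraded antibody preparation
with a trace fragment, monomer, dimer and broad aggregates), 50,000 rpm,
column 6.0–7.2 cm, 13 scans from 300 s to 6300 s, radial step 0.003 cm,
noise 0.005, TI amplitude 0.01, RI amplitude 0.005, and solvent parameters
of water at 20 °C with $\bar v$ = 0.73 mL/g.

What the generator deliberately does *not* emulate: optical artifacts
(fringe jumps, intensity nonlinearity), rotor stretch and acceleration
ramps, temperature drift beyond a small linear trend, concentration
dependence, and finite scan duration. Passing tests on this generator
therefore demonstrate the correctness of the inversion and protocol
machinery under the stated model, not robustness to every instrumental
imperfection of real data.

# Validation scale

The equivalence study (`cs_equivalence_study()`, also run by
`scripts/acceptance.R` and the test suite) analyzes the preset dataset at
grid resolution 60 (log-spaced, 1–30 S), 150 radial nodes, maximum-entropy
regularization at p = 0.68 with baseline suppression, and
Levenberg–Marquardt fitting of meniscus and frictional ratio — about 4,500
data points, chosen as a faithful small instance of routine c(s) practice.
The two analysis paths (one automated session vs. Run + refit from
perturbed starting values) agree to well under 0.01 S in peak position and
0.1 percentage points in peak population.

# Known limitations

* Only the two distribution models are implemented; co-solute dynamic
  density gradients, band/zone sedimentation, compressibility,
  size-and-shape (2-D) distributions and interacting-system models are out
  of scope.
* Floating species ($s < 0$, or non-positive buoyancy) are rejected.
* The frictional-ratio error surface is intrinsically flat when boundaries
  are broad; the optimizer then returns a bounded, converged value whose
  last digits are data-limited, which is why validation compares
  integrated peak quantities rather than raw $f/f_0$.
* Binary instrument formats and multi-channel composite files are not
  parsed; scans follow the documented ASCII dialect.
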