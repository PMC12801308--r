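---
title: "From trajectories to transition kinetics: the fespath methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From trajectories to transition kinetics: the fespath methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fespath)
```

`fespath` re-implements, at desk scale, the computational chain used to map
the conformational free-energy landscape of a flexible two-helix protein
domain: conformational clustering of trajectories, well-tempered
metadynamics (WT-MetaD) along two distance collective variables,
free-energy-surface (FES) reconstruction from the deposited hills, minimum
free-energy paths between basins, and Eyring–Polanyi transition kinetics.
This vignette is the package's own account of the models, their
assumptions, the tunable parameters, and the numerical choices made where
the design was genuinely open.

## 1. The synthetic world

Real production runs of this chain need microseconds of solvated all-atom
molecular dynamics.  The package instead ships two generators whose ground
truth is known exactly, so that every downstream stage can be validated
against analytic references rather than against another simulation.

### Model potentials

`make_gaussian_wells()` composes a CV-space free energy from Gaussian wells
plus an optional harmonic confinement,
$$F(s) = -\sum_i A_i e^{-\|s-c_i\|^2/(2w_i^2)} + \tfrac{k}{2}\|s-c_0\|^2 .$$
At construction the well centres are refined to true stationary points
(BFGS on the analytic gradient, accepted when $\|\nabla F\| < 10^{-6}$
kJ/mol/nm) and index-1 saddle points are located by a dense-grid search on
$\|\nabla F\|^2$ (400×400 nodes over the padded well bounding box,
non-strict local-minimum candidates so that symmetry ties are not lost,
Nelder–Mead refinement, Hessian classification, de-duplication).  The
canonical two-well fixture — wells of depth 18.7 kJ/mol and width 0.3 nm at
(0.6, 1.0) and (2.0, 1.0) nm with confinement k = 5 kJ/mol/nm² — has an
analytic barrier of 15.05 kJ/mol, the scale of the barriers separating
compact conformations in the system this package emulates.

### Langevin sampler

CV-space dynamics are overdamped (position-only) Langevin, integrated by
one-step Euler–Maruyama:
$$x \leftarrow x - \frac{\Delta t}{\zeta}\nabla(F + V_\mathrm{bias})
  + \sqrt{2 k_B T \Delta t/\zeta}\;\xi .$$
The artifact needs correct *stationary* statistics, not inertial dynamics,
and this scheme preserves the Boltzmann distribution up to
$O(\kappa\,\Delta t/\zeta)$: on a harmonic well the sampled variance is
inflated by $1/(1-\kappa\Delta t/2\zeta)$, which is 0.5–1% at the defaults
(friction ζ = 1.0 ps⁻¹, Δt = 2–5·10⁻⁴ ps, stiffness κ ≲ 200 kJ/mol/nm²).
The property suite checks equipartition to 5% and the full distribution by
a Kolmogorov–Smirnov distance < 0.02 on 10⁵ near-decorrelated samples.
Distances cannot be negative, so biased runs place a reflecting wall at
0 nm.  Units throughout: nm, ps, kJ/mol, K, with
$k_B = 0.0083144626$ kJ/(mol·K).

### Two-helix trajectories

`generate_helix_pair_trajectory()` builds backbone (N, Cα, C, O) frames for
residues 202–284: helix 1 spans 202–228, helix 2 239–281 (continued to
284), joined by a 10-residue loop.  Ideal α-helix parameters are used
(rise 0.15 nm/residue, 3.6 residues/turn, Cα radius 0.23 nm), which puts
the two CVs on a realistic nm scale.  The hinge is constructed so that the
*measured* interhelical angle — between the Cα(210)→Cα(221) and
Cα(249)→Cα(267) chords — equals the requested schedule value exactly before
noise; the 249→267 span is five full helical turns, so its chord lies
exactly along the helix-2 axis.  Thermal fluctuation is emulated by
isotropic Gaussian coordinate noise, default 0.03 nm, the order of backbone
RMSF in a folded protein at 300–310 K.

What this generator does *not* emulate: side chains, secondary-structure
breathing, anisotropic and correlated fluctuations, solvent, or any real
force field.  A green clustering test therefore establishes that the
descriptor → PCA → k-means → representative chain recovers planted, well
separated conformational regimes — not that it would resolve the subtler
ensembles of a real protein.

## 2. Descriptors and clustering

The per-frame descriptor is the vector of pairwise distances between
selected backbone atoms, which is rigid-motion invariant and so needs no
alignment convention ("positions" descriptors would).  Default selection:
Cα atoms, thinned to every other residue when more than 50 atoms would be
selected.  Mass-weighted centres (standard atomic masses inferred from the
atom name) define *d1*; *d2* is the Cα(218)–Cα(250) distance.  RMSD
profiles superpose backbone atoms by the Kabsch rotation (reflection
forbidden, det +1), unweighted — mass-weighting the RMSD is a convention
choice and the unweighted form is what the common trajectory tools default
to.

PCA is mean-centred and unscaled (`stats::prcomp`), keeping 2 components by
default: the downstream state assignment works in a 2D map.  k-means runs
Lloyd iterations from greedy spread-out (k-means++) seeds with 10 restarts
under one master seed; the best within-cluster sum of squares wins, making
the partition deterministic given the seed.  Cluster identity numbers are
arbitrary; reports order clusters by descending density.  Representatives
are the member frames nearest their centroid in component space, ties going
to the lowest frame index; the transition timeline orders representatives
by frame time.

## 3. Well-tempered metadynamics

Hills of height $W(k\tau) = W_0\,e^{-V(s,k\tau)/(k_B \Delta T)}$,
$\Delta T = (\gamma - 1)T$, are deposited every stride τ and immediately
contribute to the bias force.  Defaults are the production parameters of
the landscape this package emulates: σ = 0.2 nm per CV, W₀ = 1.2 kJ/mol,
τ = 1 ps, γ = 8, T = 310.15 K.  Bias forces are evaluated analytically
from the Gaussian sum with a 6σ cutoff per hill (no grid interpolation
during sampling); at desk scale (≲ a few thousand hills) a plain cutoff
test is as fast as a spatial index.  Heights are recorded *as deposited*
(post-scaling), the convention of standard hills files; consequently the
reconstruction applies the γ/(γ−1) correction.  Toy runs shorten total
time relative to production (nanoseconds rather than microseconds); the
convergence diagnostics below are the guard against over-reading them.

The hills stream is written in the standard dialect
(`#! FIELDS time d1 d2 sigma_d1 sigma_d2 height biasf`), at 17 significant
digits so the write→read round trip is bit-exact.

## 4. FES reconstruction, basins, marginals, convergence

`bias_sum_fes()` sums every hill onto a rectilinear grid (default 256
nodes per axis spanning the hills' bounding box padded by 3σ) and returns
$F = -\frac{\gamma}{\gamma-1}V$, min-shifted to zero.  The well-tempered
correction is on by default because hills store post-scaling heights; a
switch is provided because analysis packages differ in this convention and
desk-scale results cannot disambiguate which convention a given published
table used.

**Basins.** `find_minima()` reports strict grid minima (8-neighbourhood in
2D, 2-neighbourhood in 1D) filtered by *topographic prominence*: sweeping
nodes in ascending free energy with a union-find, a basin's prominence is
the level at which it first connects to a deeper basin, minus its minimum —
exactly the "depth relative to the lowest surrounding saddle" notion, and
robust to nested basins.  Labels A, B, C… follow ascending free energy, so
the global minimum is always A at 0.00 kJ/mol.  The default threshold is
1 kJ/mol.  One scale matters when choosing it: a *single* well-tempered
hill deposited in a rarely-visited region carves a dip of prominence
$W_0\,\gamma/(\gamma-1) \approx 1.4$ kJ/mol at the default parameters, so
desk-scale surfaces can show sub-thermal artifact basins above the 1 kJ/mol
default.  Where "exactly the planted basins" is the question being asked —
as in the package's acceptance checks and the pipeline defaults — the
threshold is set to the thermal energy $k_B T \approx 2.58$ kJ/mol at
310.15 K: a dip shallower than thermal energy is not a metastable state.

**Marginals.** The 1D profiles integrate the Boltzmann factor over the
discarded CV by trapezoidal quadrature in log-space (log-sum-exp, so large
barriers cannot underflow), then re-normalize min-to-zero.  For a separable
surface this recovers the kept component exactly up to the shift, which is
the oracle test.

**Convergence.** `block_convergence()` reconstructs the surface from
cumulative prefixes of the hills series and reports RMS differences between
successive estimates on a common grid; a converging run shows these
differences shrink.  The cumulative bias itself is pointwise non-decreasing
in time (heights are positive), which the property suite asserts.

## 5. Paths and kinetics

`neb_path()` relaxes a chain of images (default 32, linear initialization)
under the projected nudged-elastic-band force — the perpendicular component
of the surface gradient plus a tangential spring force (default
100 kJ/mol/nm²) — by plain gradient descent (step 10⁻⁴ nm per kJ/mol/nm,
tolerance 0.5 kJ/mol/nm on the maximum perpendicular force, cap 5000
iterations, no climbing image).  The surface is interpolated bilinearly and
differentiated by central differences at half the grid spacing.
Non-convergence returns the path with a flag and warning rather than an
error.  The transition state is the profile maximum refined by a parabola
through its three bracketing images (in arc length) and re-evaluated on the
surface: with 32 images the inter-image spacing exceeds a fine grid's cell
diagonal, and the refinement is what recovers saddle positions below the
image spacing (validated against analytically located saddles to within one
grid-cell diagonal, barriers to 5%).

`eyring_half_life()` is classical transition-state kinetics,
$k = \kappa (k_B T/h) e^{-\Delta F/RT}$, $t_{1/2} = \ln 2 / k$, with CODATA
constants and κ = 1.  The kinetics temperature is an explicit parameter
defaulting to 300 K: published half-life tables for this system are
consistent with the closed form at 300 K even though the sampling ran at
310.15 K, so the two temperatures are deliberately decoupled.  (One
published row, B→D, is inconsistent with the closed form that reproduces
every other row to better than 0.5% — most plausibly a typo in its printed
barrier — and is excluded from the package's reference checks.)
`transition_table()` relaxes one path per unordered basin pair, fills both
directional barriers (so that forward-minus-backward always equals the
endpoint free-energy difference on *its own* profiles), and flags rows with
$t_{1/2} < 1$ ps as transient: such states are not captured at an ordinary
2 ps trajectory-saving stride.

## 6. Pipeline

`run_pipeline()` chains generate → cluster → cvs → metad → fes → paths →
report from a single JSON-mapping configuration (unknown keys rejected, all
violations reported together, a fully-defaulted config runs end-to-end).
Stages communicate through files under the output directory, so any stage
can be re-run in isolation; identical configuration and seeds give
byte-identical artifacts.  The pipeline's WT-MetaD default (6·10⁵ steps of
5·10⁻⁴ ps, i.e. 300 hills) is chosen so the whole chain completes in a few
seconds while still filling both wells of the default fixture; the
acceptance-level barrier-recovery experiments use 2·10⁶ steps (1000 hills)
and three seeds.

## 7. Known limitations

* The Langevin world is 2-dimensional CV-space dynamics on a stated
  potential; nothing is learned about force fields, solvent, or the
  projection error of choosing CVs in the first place.
* Bias-sum FES values in regions the walker rarely visited are not
  converged estimates; basins and barriers should be read only within the
  sampled region (see the prominence-threshold discussion above).
* The NEB implementation targets smooth desk-scale surfaces: plain gradient
  descent with fixed step, no climbing image, bilinear interpolation.  On
  very rough surfaces the returned path is a local, not global, MFEP.
* Reference half-life checks validate the kinetics formula, not the MAX
  free-energy surface itself, which requires microsecond all-atom sampling
  outside this package's scope.
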