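---
title: "Models and methods behind retmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`retmech` analyses tensile tests of soft neural tissue (adult retina)
mounted across a two-scaffold stretcher with a glass-fiber force sensor.
This vignette documents the models the package implements, the parameters
that matter, the numerical choices, and the limits of what the synthetic
tests demonstrate.

## The experiment being modelled

A slab of retina (6 mm x 10 mm x 0.22 mm) is bonded, photoreceptor side
down, across two stiff nanostructured scaffolds (3 mm x 10 mm x 0.1 mm
each) that initially touch. A stepper motor pulls one scaffold away at a
constant displacement rate (0.1-2.0 um/s); the stationary scaffold hangs on
a pair of glass fibers that act as a linear spring, so the force follows
from Hooke's law once the fiber spring constant is calibrated. The
measured record is a force-distance (FD) curve: sensor force against motor
travel. "Distance" in this package is always motor travel, not the
sensor-corrected scaffold separation; the corrected gap is carried as an
auxiliary column for downstream use.

## Sensor calibration

Known masses m (150-2200 mg) are hung off the sensor and the fiber
extension x recorded. The package fits ordinary least squares of the
gravitational load F = m g (g = 9.81 m/s^2) against x with a *free
intercept*; the spring constant k is the slope and its standard error is
reported. The intercept absorbs any constant offset in the dot-tracking
reference and is deliberately *not* applied when converting extensions to
forces - it is a calibration diagnostic, not part of the sensor response.
The < 1.5% change in spring constant with a scaffold attached is treated as
negligible. The synthetic calibration generator draws extension noise as
i.i.d. Gaussians (default 2 um), which emulates camera-tracking jitter but
no drift.

## FD regime model and segmentation

Measured FD curves show five pieces: a nonlinear toe below 0.01 mm
(attributed to loose initial clamping and entropic network effects), a
linear elastic rise of slope `k1` (the *elastic constant*, a structural
stiffness in N/m, not a material modulus), a constant-force plateau
entered at the first yield force `F_y1`, a second steeper rise `k3`, and a
second plateau at `F_y2`.

The segmentation fits a continuous piecewise-linear function with four
breakpoints by least squares. In the hinge basis
(1, d, (d-b1)+, ..., (d-b4)+) the fit is linear for fixed breakpoints; the
breakpoints themselves are restricted to the sample grid and located by

1. a coarse grid search (about 25 candidate positions per breakpoint, plus
   the sample nearest the nominal 0.01 mm toe boundary),
2. cyclic coordinate descent from the five best coarse quadruples, each
   sweep rescanning one breakpoint over its whole admissible range at
   sample resolution,
3. exact QR re-scoring of the refined candidates.

The inner least-squares problem is evaluated in O(1) per candidate from
precomputed suffix sums of d, d^2, f and f d, which is what makes the
full-range sweeps affordable. A candidate quadruple is *admissible* if
every segment keeps at least 10 samples, the fitted `k1` is positive, and
each plateau slope is below 10% of the neighbouring rise. The tests verify
on short curves that this search attains exactly the same minimal SSE as
exhaustive enumeration of all admissible quadruples.

Reported parameters are deliberately not read off the global fit:

- `k1` and `k3` are re-estimated by plain OLS on the *interior* samples of
  their segments (a 2-sample buffer next to each breakpoint is dropped).
  On noise-free curves this recovers the generator slopes to machine
  precision even when a true corner falls between two samples. Samples
  below 0.01 mm never enter the `k1` fit.
- `F_y1` and `F_y2` are the maximum measured force within 5 samples of the
  corresponding breakpoint, matching the operational definition of a yield
  point as the local force maximum at the entry of a plateau; with noisy
  data this estimator carries a small positive bias (about 1.5 noise
  standard deviations, i.e. ~0.03 mN at the default noise), which is well
  inside the replicate spread of the experiment.

Curves that stop before the later regimes (deliberately interrupted
stretches) are fit with a reduced model - toe + rise + first plateau, or
toe + rise alone - and flagged `partial_fit` (plus `no_yield_detected` when
no plateau is present). A straight line through the origin is either
rejected or returned as such a flagged degenerate fit.

Pre-smoothing (moving average) is available but off by default: it must
not bias slopes on clean synthetic data, and the estimator is already
robust at the sensor noise scale.

## Synthetic data generator

The generator emulates the *statistical structure the analysis assumes*,
with the measured anchors at the two extreme rates: elastic constants 21.5
and 33.5 N/m and yield forces 1.5 and 2.2 mN at 2.0 and 0.1 um/s
respectively; toe end 0.01 mm; first plateau length 200 um; total travel
1 mm. Values never reported by the experiment take documented defaults,
flagged `invented_default` in the preset: `k3 = 2 k1`, `F_y2 = 2.5 F_y1`,
and linear interpolation in rate between the two anchors (e.g. the 0.5 um/s
preset). Rate dependence is therefore *phenomenological* - presets encode
it; nothing viscoelastic is simulated.

The toe is the unique cubic through the origin with zero initial slope
whose slope *and curvature* match the regime-1 line at the toe end (a C2
junction, so no spurious corner biases the `k1` fit); consequently the toe
ends at 2/3 of the linear extrapolation. Plateau-to-line transitions are
exact corners - the simplest shape consistent with the described regimes,
and deliberately a stress test for the segmentation, which must tolerate
corners anyway. Noise is additive zero-mean Gaussian on force only
(default 0.02 mN, the sensor noise scale); the displacement grid is
uniform and noise-free, as motor travel is essentially exact. Every
generator takes a mandatory seed and restores the caller's RNG state.

What passing tests on these data do *not* show: robustness to drift,
heteroscedastic noise, displacement jitter, rounded (non-corner) regime
transitions, or tissue-to-tissue geometry variation. They do show that the
estimators are unbiased and tight under the idealized noise model at the
measured parameter scales.

## Forward finite-element model

The stretcher is modelled as static small-strain isotropic linear
elasticity: two titanium scaffolds (E = 105 GPa, nu = 0.33 - standard
handbook values; any plausible choice is immaterial because the scaffolds
are ~1e8 times stiffer than the tissue) and the tissue slab bonded to
their top faces with E of order 1 kPa, nu = 0.49. Density is carried in
the configuration for fidelity but the solve is static with no gravity.
One scaffold is clamped in all directions; every node of the moving
scaffold is constrained to u_z = 0; a uniform traction in x with the
prescribed resultant (default 1.0 mN) acts on the moving scaffold's outer
sidewall. The readout u_x is the mean x-displacement of that sidewall
(the plate moves rigidly, so any consistent readout coincides).

Discretization: structured axis-aligned 8-node hexahedra with *selective
reduced integration* - the shear part with the full 2x2x2 Gauss rule, the
dilatational (lambda) part with the 1-point rule - which avoids the
volumetric locking that plain trilinear (or linear tetrahedral) elements
suffer at nu close to 0.5. Element sizes are geometrically graded (ratio
1.25) toward the scaffold-scaffold interface line and toward the tissue
bottom, where the deformation localizes. The solver assembles one sparse
symmetric stiffness per material block (`K = K_scaffold + E K_tissue(E=1)`,
so modulus sweeps only refactorize) and solves by CHOLMOD sparse Cholesky.
Verification: a patch test (uniform uniaxial stress, exact to 1e-6), rigid
plate simple shear against F t/(G A) (within 2% at 4 elements through the
thickness), exact load linearity, work-energy balance, and depth-uniformity
of the solution.

When the scaffolds touch (gap = 0), the coincident scaffold faces carry
duplicated, unconnected nodes, so the plates interact only through the
tissue; the single tissue node line directly above the interface is bonded
to neither plate. A `gap > 0` configuration meshes the open span and bonds
the tissue up to the plate edges. An optional rigid-scaffold mode meshes
only the tissue (clamped bottom on the fixed side, a rigid in-plane master
constraint on the moving side) and agrees with the full model to a few
1e-5 relative at matched discretization - useful for fast studies.

### The touching-scaffold configuration is singular

This is the package's most important modelling caveat. With gap = 0 the
tissue's bottom boundary condition jumps discontinuously at the interface
line - displacement 0 on one side, the plate displacement on the other.
Such boundary data have infinite energy in the continuum limit
(the jump is not in H^1/2), so the structural stiffness grows like
log(1/h) as the mesh size h at the interface shrinks: the computed u_x
*never mesh-converges at gap 0*; it drifts slowly stiffer forever. Two
independent implementations (this package's solver and a from-scratch
plane-strain code written against a different linear-algebra stack) agree
on this behaviour and on each other's displacements to three digits on
regular configurations.

Consequences adopted by the package:

- The worked-example quantities at gap 0 are reported at the package's
  standard problem size (resolution 3, about 9e4 degrees of freedom, ~30
  elements per scaffold side graded to sub-um at the interface), and the
  documentation treats reference values computed elsewhere for this
  configuration as specific to their mesh and contact treatment. At this
  standard size the model gives u_x = 55 um for E = 760 Pa and 1.0 mN, an
  effective stiffness of 18.2 N/m; matching a measured elastic constant of
  21.5 N/m yields E of about 900 Pa, and 33.5 N/m about 1400 Pa.
- Mesh-convergence checks are run on the *regular* finite-gap problem
  (e.g. a 47 um separation), where u_x converges cleanly (< 0.2% at the
  finest tested doubling).
- Physically, the singularity reflects a real feature: at the instant the
  plates separate, the load transfer is concentrated at a line. Any finite
  measurement probes the configuration at a finite opening, which is why
  the finite-gap problem is the right well-posed surrogate.

## Inverse modulus identification

The identified quantity is the *effective Young's modulus*: the single
isotropic E at which the simulated scaffold displacement matches the
measurement. Targets are either an explicit (load, displacement) pair or a
measured elastic constant k1, converted via displacement = load/k1 at a
fixed 1.0 mN reference load (linearity makes the choice immaterial; fixing
it makes runs reproducible). Since the scaffolds are effectively rigid,
E u_x is constant to ~1e-7, so the scaling iterate
E1 = E0 u_x(E0)/u_target lands within solver tolerance almost always; a
secant iteration on log E (with the u ~ 1/E slope as fallback) guards the
general case. Typical cost: 2 forward solves to a 1e-3 relative tolerance,
guaranteed under 6 within the default bracket [10, 1e5] Pa. All solves in
one identification share one mesh, so discretization bias cancels in
forward-inverse round trips (recovery to < 1e-3, verified for E in
{300, 760, 2000} Pa).

Per-rate identification applies this to the mean k1 of each rate's
replicates. No uncertainty is propagated from the replicate SD of k1 to E;
the rate table reports the point identification.

## Problem sizes and tolerances

- Default synthetic curves: 1000 points over 1 mm; replicate campaigns of
  5/3/3 curves at 0.1/0.5/2.0 um/s; Monte-Carlo suites use 20-500 seeds
  depending on the estimator's cost.
- Segmentation: coarse grid ~25 positions per breakpoint; minimum segment
  length 10 samples; plateau-slope admissibility 10%.
- FE: resolution 1 (~4e3 dof) for property checks, resolution 3 (~9e4 dof)
  as the standard analysis size; solver residuals ~1e-5 relative
  (the 1e8 material contrast costs a few digits, displacement accuracy is
  unaffected at the reported precision).
- Inversion tolerance 1e-3 relative on displacement.

## Known limitations

- Linear kinematics: the model does not follow the opening gap as the
  scaffold moves (no geometric nonlinearity, no contact), which is also
  why the gap enters as an explicit configuration parameter rather than
  evolving.
- No constitutive rate dependence; the rate enters only through measured
  or interpolated presets.
- The plateaus (yielding, stick-slip sliding of ruptured layers) are
  detected and quantified but not mechanistically modelled.
- The synthetic generator's unreported-parameter defaults (`k3`, `F_y2`,
  intermediate-rate values) are package conventions, clearly flagged, not
  measurements.
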