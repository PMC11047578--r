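---
title: "Methods: reduced-order haemodynamics from image-derived centerlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-order haemodynamics from image-derived centerlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculate)
```

This vignette documents the models, numerical choices and their rationale
for every stage of the pipeline, and states honestly what the synthetic test
fixtures do — and do not — demonstrate about real patient data.

## 1. From voxel mask to skeleton graph

A segmented vascular volume enters as a binary 3D array with voxel spacing
in mm (`voxel_volume()`). `skeletonize()` shrinks it to one-voxel-wide
centerlines by **sequential simple-point thinning**: a foreground voxel may
be deleted only if its 3×3×3 neighbourhood has exactly one 26-connected
foreground component and exactly one 6-connected background component
touching a face neighbour — the classical local characterization of a
topology-preserving ("simple") deletion — and is not a curve endpoint
(≤ 1 foreground neighbour). Deletion proceeds in six directional border
subcycles (up/down/north/south/east/west) until stable, which keeps the
result centred and makes thinning idempotent on already-thin sets. The
connected-component count of the mask is provably preserved.

Thinning operates in index space; anisotropic spacings are accepted with a
warning because the thinning lattice then differs metrically from world
space. All downstream geometry is metric (mm, voxel centres).

Skeleton voxels become graph nodes, 26-adjacent pairs become edges.
`classify_and_split()` types the nodes (*terminal* = degree 1, *plain* =
degree 2, *bifurcation* = degree ≥ 3; an isolated voxel is a terminal by
convention), collapses each connected cluster of adjacent bifurcation
voxels to its centroid — thinning commonly leaves 2–3-voxel junction
cliques — and cuts the graph into maximal bifurcation-free paths, each
labelled with an arterial index. A pure cycle with no bifurcation becomes a
single closed segment and is reported via a message. `prune_skeleton()`
removes terminal-ended segments shorter than a user threshold (spur
artefacts of flat vessel ends), then re-splits; surviving segments keep the
smallest label they previously carried so labels are stable under pruning.

**Radii.** The imaging literature offers several local radius estimators;
we use the Euclidean distance transform: each node's radius is the distance
to the nearest background voxel centre, computed spacing-aware against the
background shell 26-adjacent to the foreground (the nearest background
voxel to any interior point always lies in that shell, so the restriction
is exact). Voxels outside the array count as background.

## 2. Centerline smoothing and resampling

Quantization noise of ±half a voxel corrupts discrete curvature estimates
catastrophically — on a helix with true curvature 0.1 /mm and 1 mm sample
spacing, the three-point polyline estimator is wrong by several times the
signal. `fit_spline_sfm()` therefore fits each coordinate and the radius
with a **degree-5 B-spline penalized least-squares smoother** in a
chord-length parameter (in mm), with the roughness penalty
λ₃∫(f‴)² + λ₄∫(f⁗)². Choices worth recording:

* **Parameter scale.** The chord parameter is kept in mm rather than
  normalized to [0, 1]; third/fourth-derivative penalties then act per mm,
  the penalty matrices stay well conditioned, and a fixed λ grid is
  meaningful across segments of different lengths.
* **Knots** at every 3rd data site (quintic, order 6); for n < 7 points a
  quintic fit is underdetermined and `smooth_skeleton()` falls back to
  linear resampling.
* **Penalty selection** by the penalized-regression AIC,
  n·log(RSS/n) + 2·edf summed over the fitted channels, where edf is the
  trace of the smoother matrix. The default grid is 13 log-spaced values
  10⁻⁴…10², searched on the diagonal λ₃ = λ₄ (a full 2D search is available
  via `full_grid = TRUE`; on the fixtures it changes the selected fit
  marginally at 169× the cost). RSS is floored at n·10⁻²⁴ so exactly
  interpolable channels (e.g. a constant radius) do not produce −∞ AIC.
* **Penalty matrices** are assembled exactly by 5-point Gauss–Legendre
  quadrature per inter-knot span (the integrands are piecewise polynomials
  of degree ≤ 4).

`resample_curve()` reparameterizes by arc length (adaptive quadrature of
the parametric speed, relative tolerance 10⁻⁶; inversion by root bracketing)
and places points at arc lengths 0, Δl, 2Δl, …, always including the final
endpoint. The default grid width is Δl = 2 mm. Consecutive spacing is exact
in arc length; only the final interval may be shorter.

## 3. Network assembly

`assemble_network()` validates the simulation topology: every segment end
attaches to exactly one junction, the single inlet, or a Windkessel
terminal; junctions join ≥ 2 ends; the contracted graph must be connected.
Junction endpoints are snapped to their common centroid when all lie within
1.5·Δl of it — skeleton and spline endpoints drift by about a voxel — and
assembly fails beyond that tolerance rather than silently deforming
geometry. Stenosis elements are declared per segment with an arc position,
a length and an **area severity** (1 − As/A0). NASCET grades are diameter
ratios; `severity_from_nascet()` converts via 1 − (1 − NASCET)².

## 4. The 1D–0D solver

### Governing equations and tube law

Mass and momentum averaged over the cross-section give

∂A/∂t + ∂Q/∂z = 0,  ∂Q/∂t + ∂(Q²/A)/∂z + (A/ρ)∂P/∂z + K_R·Q/A = 0,

closed by P − P0 = β(√(A/A0) − 1), β = E·h0/(r0(1−σ²)). With uniform
reference properties per segment the pressure-gradient term is conservative,
(A/ρ)∂P/∂z = ∂/∂z[β A^{3/2}/(3ρ√A0)], and the characteristic speeds are
u ± c with c = c0 (A/A0)^{1/4}, c0 = √(β/2ρ) — the Moens–Korteweg speed at
the reference area. The Riemann invariants are W± = u ± 4c.

### Numerical scheme

* **Interior:** Richtmyer two-step Lax–Wendroff (second order) on a
  Δs = 1 mm grid (each segment's Δs is adjusted so an integer number of
  cells fits its length). The friction source −K_R·Q/A is included at both
  half and full steps.
* **Time step:** fixed per run at CFL 0.5 against a conservative estimate
  of max(|u|+c) (wave speed with margin plus an inlet-velocity estimate),
  rounded so an integer number of steps fills a cycle; the realised Courant
  number is monitored every step and the solver aborts with a suggested dt
  if it exceeds 1. Area positivity is checked every step; failures abort
  with the segment and time rather than propagating NaNs.
* **Boundaries:** each coupled end receives the outgoing invariant W±
  evaluated at the foot of its characteristic (linear interpolation at the
  previous time level) *including the friction source along the
  characteristic path*; without that correction, terminal states carry an
  O(Δs) error visible as ~0.2% flow non-uniformity in steady tests.
* **Junctions:** unknowns are the end areas and all but one junction-inward
  flow; the last flow is defined as minus the sum of the others, so mass
  conservation holds to machine precision *by construction* (the measured
  per-step defect is exactly 0). Newton iteration (analytic Jacobian,
  scaled residuals < 10⁻¹³) enforces the characteristic relations and
  static-pressure continuity; total-pressure continuity (P + ½ρu²) is a
  config option. Both treatments are standard; the difference is O(ρu²) ≈
  a few hundred Pa at cerebral velocities.
* **Windkessel terminals:** RCR with implicit-Euler capacitor update,
  coupled through the outgoing characteristic by a scalar Newton solve.
* **Stenosis elements:** an internal interface splitting the host segment
  into two tubes with continuous flow Q and the Young pressure jump
  ΔP = (Kv·μ/(2r0·A0))Q + (Kt·ρ/2A0²)(A0/As − 1)²·Q|Q| +
  (Ku·ρ·Ls/A0)·dQ/dt, solved as a 3-unknown Newton system per step. Default
  coefficients: Kv = 32·(Ls/2r0)(A0/As)² (which reduces exactly to the
  Poiseuille drop of an Ls-long tube at zero severity), Kt = 1.52,
  Ku = 1.2 — all exposed in the element constructor.
* **Convergence:** cycles repeat until the maximum pressure change between
  consecutive cycles, normalised by the cycle's pressure scale, drops below
  10⁻³ (cap 20 cycles; non-convergence is flagged and warned, never
  silent). The converged cycle is returned at n_out + 1 uniformly spaced
  instants including both cycle endpoints, which makes trapezoidal cycle
  averages exact in the periodic sense.

### Friction coefficient

K_R is 22πν by default (a flat-ish velocity profile typical of large
arteries), with 8πν (Poiseuille) one switch away. The wall-shear
post-processing below assumes a Poiseuille profile; these two profile
assumptions are *not* mutually consistent, and the package exposes both
knobs rather than resolving the inconsistency — resolving it would require
a momentum-flux correction factor the model family does not carry.

### Default physical parameters

ρ = 1060 kg/m³, μ = 4 mPa·s, σ = 0.5, P0 = 85 mmHg, wall thickness
h0 = 0.1·r0 unless given absolutely. These are conventional large-artery
values, configurable globally and per segment; none is patient-calibrated.

## 5. Post-processing

V = Q/A (with Q in ml/s and A in mm², V is directly in m/s);
U(r) = 2V(1 − r²/R²); τ_w = 4μV/R. The radius entering τ_w is the
instantaneous R = √(A/π) by default — consistent with the lumen radius the
mesh module renders — with the reference r0 available via a flag. TAWSS is
the trapezoidal cycle mean of |τ_w| (magnitude convention; a signed mean is
a flag away). `map_solution_to_centerline()` interpolates the Δs solver
grid linearly onto the Δl centerline points, scaling arc positions
affinely between the two parameterizations; endpoint values map exactly and
a solver/centerline length mismatch above 5% is an error, not a warning.

## 6. Lumen meshes

Tangents come from central differences; the cross-sectional frame (nx, ny)
is propagated by **rotation-minimizing parallel transport** (the
double-reflection method), which carries zero twist on planar curves and
zero holonomy around planar loops — properties the tests assert. Ring
vertices sit at p + √(A/π)(nx·cos(2πl/k) + ny·sin(2πl/k)), l = 0…k−1
(k = 16 by default). Bands between consecutive rings pair each vertex with
the Euclidean-nearest vertex of the next ring (ties to the lower index); if
that pairing is not a constant circular offset the band falls back to the
constant offset derived from vertex 0, with a warning. Each band closes
with wraparound into 2k triangles, wound outward. Per open tube this gives
V = kN, F = 2k(N−1), E = 3kN − 2k and V − E + F = 0, with every interior
edge shared by exactly two faces.

Animated output recomputes ring radii from the instantaneous A(s,t) — the
lumen is time-varying — with a static option. Writers emit legacy ASCII VTK
PolyData and ASCII PLY with per-vertex scalars, a ParaView-style `.pvd`
collection index, and a JSON sidecar naming the scalar, its range and a
colormap; identical inputs produce byte-identical files. Tubes are left
open at junction ends; no junction capping surface is attempted.

## 7. Constant-WSS remodeling

Arteries adapt their caliber to restore wall shear stress after chronic
flow changes. With Poiseuille shear τ = 4μQ/(πr³), the constant-WSS fixed
point at fixed flow is r* = r(τ/τ*)^{1/3}; the update
r ← r(τ̄/τ*)^{ω/3} with relaxation ω (default 0.5) converges geometrically
with ratio (1 − ω) on that toy and remains stable on coupled networks where
flow redistributes as radii change. Targets are given per segment or
computed as the "baseline": segment-mean TAWSS of a reference run with all
stenoses removed. Convergence is a relative TAWSS error below `tol`
(default 2%); divergence (error growing three iterations running) aborts
with the trace. The loop adapts r0 (and A0 = πr0²) and keeps h0 fixed by
default, which *stiffens* β as vessels dilate; an `adapt_h0` flag scales h0
with the radius instead. Warm-starting each simulation from the previous
iteration's terminal capacitor pressures roughly halves the outer-loop
cost.

## 8. What the fixtures do and do not show

The generator module fixes all study conditions:

* **Voxel phantoms:** straight cylinders are voxelized exactly (no end
  caps) so the foreground count matches πr²L; Y and helix phantoms are
  painted as spheres along the analytic axis, which adds rounded caps.
  Ground-truth axis and curvature ship with every phantom.
* **Noisy centerlines:** uniform ±0.5 mm jitter per axis (optionally grid
  rounding) with a fixed seed — an idealization of quantization noise that
  is white, whereas real segmentation noise is spatially correlated.
* **Inflow:** a half-sine systole over 0.35 T and zero diastole,
  trapezoidally normalised so one beat integrates exactly to the stroke
  volume (defaults T = 1 s, SV = 12 ml — a cerebral-scale mean flow of
  12 ml/s). Real cerebral inflow has nonzero diastolic flow; the zero-flow
  diastole exaggerates pulse pressure.
* **Toy loop network:** 9 straight planar segments — root (r = 4 mm), two
  inlet branches (3 mm), two lateral terminal branches (2.5 mm), two
  communicating segments (1 mm) meeting at an anterior junction feeding two
  terminal branches (2 mm); lengths 20–60 mm; exactly one graph cycle.
  Terminal RCR values distribute a 12 ml/s mean inflow 5/5/1/1 between the
  lateral and anterior beds at ~90 mmHg mean pressure with venous pressure
  5 mmHg and a 0.6 s RC time constant; R1 is the characteristic impedance
  of the feeding vessel, capped at 0.2·R_total. The severity presets are
  "CS" (70% NASCET = 0.91 area severity) and "VRCA" (0.9 area severity), on
  the left inlet branch.

Passing tests on these fixtures demonstrate the *mechanisms* — pulse-wave
propagation at the analytic speed, exact junction mass balance, collateral
flow reversal through a loop, shear-homeostatic dilation — under clean,
symmetric, parameter-controlled conditions. They do not validate patient
anatomy, real terminal calibration, image segmentation quality, or the
magnitudes of any patient-specific quantity.

## 9. Problem sizes and runtimes

The validation suite runs the loop network (~290 solver nodes, ~9000 time
steps per cycle, converging in ~8 cycles) in a few seconds per simulation,
the remodeling loop in ~7 outer iterations, and the phantoms at 30–40
voxels per side. These sizes were chosen so the full suite and the
reproduction script each complete in about a minute while keeping every
assertion quantitative.

## 10. Known limitations

* One inlet per network; no closed-loop heart/venous/pulmonary circuit —
  inflow is prescribed, so cardiac afterload feedback is absent.
* Elastic (not viscoelastic) walls; uniform properties per segment.
* The momentum friction profile and the Poiseuille WSS assumption are
  inconsistent by construction (see §4); WSS magnitudes at bends and
  bifurcations are further outside the 1D model's reach.
* The splice of two tubes through a degree-2 junction reproduces the
  contiguous tube to ~10⁻⁵ relative (boundary discretization differs from
  the interior stencil), not to machine precision.
* Meshes are per-segment open tubes; junctions are not capped or blended.
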