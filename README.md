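# vasculate

Reduced-order (1D–0D) pulse-wave haemodynamics on vascular networks derived
from segmented medical images — headless and scriptable, from voxel mask to
dynamic 3D lumen meshes.

Full-scale 3D CFD of looping vascular territories such as the Circle of
Willis is too slow for routine clinical what-if questions ("what happens to
cerebral flow if this carotid stenosis is removed?"). One-dimensional models
answer them in seconds: each artery is an axisymmetric elastic tube, the
distal beds are lumped RCR circuits, and the coupled system reproduces pulse
wave propagation, collateral flow reversal and post-surgical flow
redistribution. `vasculate` implements the whole workflow for R users:

1. **Skeletonization** — topology-preserving 3D thinning of a binary vessel
   mask (26/6-connectivity simple-point deletion), node classification into
   *terminal / bifurcation / plain*, branch pruning, and local radii from the
   Euclidean distance to the background.
2. **Centerline smoothing** — penalized degree-5 B-spline fits per
   coordinate and radius with 3rd- + 4th-derivative roughness penalties,
   penalty weights selected by AIC, then arc-length resampling on a fixed
   grid width (Δl = 2 mm by default).
3. **1D–0D solver** — the cross-section-averaged continuity and momentum
   equations

   ```
   ∂A/∂t + ∂Q/∂z = 0
   ∂Q/∂t + ∂(Q²/A)/∂z + (A/ρ) ∂P/∂z + K_R Q/A = 0
   ```

   closed by the elastic tube law `P − P0 = β(√(A/A0) − 1)` with
   `β = E h0 / (r0 (1 − σ²))`, integrated by Richtmyer two-step
   Lax–Wendroff on a Δs = 1 mm grid. Junctions are coupled through
   characteristic invariants with exact mass conservation and static- (or
   total-) pressure continuity; outlets are RCR Windkessel elements;
   stenoses are Young-type 0D pressure-drop interfaces (viscous + turbulent
   + inertial terms).
4. **Post-processing** — mean velocity `V = Q/A`, Poiseuille wall shear
   stress `τ_w = 4 μ V / R`, TAWSS over the converged cycle, and mapping of
   the 1D fields onto 3D centerline coordinates.
5. **Remodeling** — constant-WSS adaptation: radii of designated segments
   iterate `r ← r (τ̄/τ_target)^(ω/3)` until TAWSS returns to its
   homeostatic target.
6. **Mesh export** — the lumen rebuilt as triangle tubes around the
   centerline (rotation-minimizing frames, ring vertices at
   `r = √(A(s,t)/π)`, nearest-vertex band triangulation), written as legacy
   VTK / PLY frame series with a ParaView collection index.

A `fixtures` module generates every synthetic input the package needs:
cylinder/Y/helix voxel phantoms with analytic ground truth, noisy
centerlines, a half-sine inflow waveform, and a toy looped
Circle-of-Willis-like network with severity presets (`"CS"`, 70% NASCET;
`"VRCA"`, 90% area stenosis).

## Worked example: carotid-style stenosis on a looped network

```r
library(vasculate)

cow   <- make_toy_cow(0)          # healthy loop network + config
sten  <- make_toy_cow(0.9)        # 90% area stenosis on the left inlet branch

sol0  <- simulate_network(cow$network,  cow$config)
sol9  <- simulate_network(sten$network, sten$config)
sol0
#> solution_field: 9 segments, 101 time samples over T = 1 s; converged after 8 cycles
#>   mass balance error 0.000998%; max junction defect 0 ml/s; max Courant 0.33

midQ <- function(sol, id) { q <- sol$segments[[as.character(id)]]$Q
                            mean(q[, ceiling(ncol(q)/2)]) }
midQ(sol0, cow$left_com)   #  0.933  ml/s  (healthy: left-to-anterior)
midQ(sol9, cow$left_com)   # -0.411  ml/s  (stenosed: compensatory reversal)
midQ(sol9, cow$left_inlet); midQ(sol9, cow$right_inlet)
#> 4.08 ml/s vs 7.83 ml/s   (imbalanced inlets under stenosis)
```

The mean flow in the left communicating segment reverses sign under the
stenosis — the right side perfuses the left territory through the loop — and
`simulate_network(remove_stenoses(sten$network), sten$config)` restores the
healthy, symmetric distribution (left/right inlet flows agree to ~1e-13).

Remodeling the overloaded collateral back to its baseline wall shear
stress:

```r
rem <- remodel_to_target_wss(sten$network, sten$config,
                             remodel_config(segments = 7, target = "baseline"))
rem$radius_scale          # 1.44  — collateral dilates
solution_wss(rem$solution)$segment_tawss[["7"]]  # back to ~4.4 Pa baseline
```

Export an animated lumen colored by flow rate:

```r
seg <- cow$network$segments[["1"]]
mp  <- map_solution_to_centerline(sol0, seg)
dyn <- bake_scalar_series(seg, mp, field = "Q", k = 16)
write_dynamic_mesh(dyn, "mesh_out")   # frame_####.vtk + series.pvd
```

A thin command-line wrapper ships in `exec/vasculate`
(`vasculate skeletonize|smooth|simulate|wss|mesh|remodel|fixtures ...`).

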