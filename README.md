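# membranewater

Trajectory analysis of water confined between stacked phospholipid
bilayers. When a membrane stack is dehydrated, the water that remains
is dominated by the interface and both its translational and its
rotational dynamics slow down by up to two orders of magnitude. This
package implements the standard analyses used to characterize that
slowdown from molecular-dynamics-style trajectories, together with
synthetic-trajectory generators with known ground truth, so every
estimator can be validated without running MD:

- **Lateral diffusion.** In-plane mean-square displacement
  MSD∥(τ) = ⟨|r∥(t₀+τ) − r∥(t₀)|²⟩ over all molecules and time
  origins (exact all-origin average via FFT), and the diffusion
  coefficient D∥ = slope/4 from an ordinary least-squares line in the
  diffusive regime (first 2 ps discarded by default), reported in
  nm²/ns.
- **Rotational relaxation.** The rank-1 dipolar correlator
  C(τ) = ⟨μ̂(t₀+τ)·μ̂(t₀)⟩ of the HOH-bisector direction, the
  model-free relaxation time τ_rot = ∫₀^∞ C(t) dt (trapezoidal
  quadrature with an analytic exponential tail), and a constrained
  three-population decomposition
  C(t) = f_fast e^(−t/τ_fast) + f_bulk e^(−t/τ_bulk) + f_irr e^(−t/τ_irr)
  with the fractions on the simplex (f_fast + f_bulk + f_irr = 1) and
  ordered time constants, fitted by deterministic multi-start
  Levenberg–Marquardt.
- **Hydrogen bonds.** Geometric criterion (d_OO < 3.5 Å and donor
  H–O–O angle < 30°, strict, minimum image), per-water bond-count
  distributions split into water–water and water–lipid partners, the
  intermittent bond correlator C_HB(τ) = ⟨n(t₀+τ)n(t₀)⟩/⟨n(t₀)⟩, its
  relaxation times τ_HB, and the slowdown factor
  κ = τ_HB(w–l)/τ_HB(w–w).
- **Interface geometry.** Per-leaflet 2-D periodic Voronoi
  tessellation of the head-group (P, N) atoms, the signed membrane
  distance ξ = z_water − z_generator, region classification
  (interior ξ < 0, first hydration layer 0 ≤ ξ < 5 Å, exterior
  ξ ≥ 5 Å), water density profiles ρ(ξ) and the interfacial mean
  density ρ̄_w = N_w m_w/(A_xy d), and region-resolved D∥ and τ_rot.
- **Synthetic data.** 2-D Brownian waters, rotational-diffusion
  dipoles, two-state (telegraph) bond processes, and a full layered
  membrane system, all deterministic given a seed and carrying their
  ground truth in the trajectory metadata.

Input is multi-model PDB (CRYST1 box) or XYZ frames plus a small YAML
topology descriptor naming the water O/H, head-group and
lipid-acceptor atoms; outputs are plain CSV tables.

## Worked example

```r
library(membranewater)

# Water-lipid HBs at full hydration persist 9.5x longer than
# water-water HBs (relaxation times 38 ps vs 4.0 ps):
slowdownFactor(38, 4.0)$kappa
#> [1] 9.5

# Recover a lateral diffusion coefficient from a Brownian fixture:
traj <- generateBrownian2D(D = 1, nMolecules = 300, nSteps = 3000,
                           dt = 0.1, box = c(30, 30, 30), seed = 10)
est <- estimateDiffusion(unwrapCoordinates(traj), nBlocks = 6)
est
#> DiffusionEstimate: D_par = 1.028 +/- 0.023 nm^2/ns (window 2-75 ps, R^2 = 1.0000, blocks errors)

# Three-population decomposition of a rotational correlator:
t <- seq(0, 1000, by = 0.1)
curve <- triexpCurve(t, taus = c(0.47, 3.2, 117),
                     fractions = c(0.04, 0.85, 0.11))
series <- new("CorrelationSeries", lags = t, values = curve,
              nPairs = rep(1, length(t)), kind = "acf")
fitTriexponential(series)
#> TriExpFit (fast / bulk-like / irrotational):
#>   tau = 0.47 / 3.2 / 117 ps
#>   f   = 0.0400 / 0.8500 / 0.1100 (sum = 1)
#>   residual norm = 4.59e-16
```

The fitted D∥ is the slope/4 of the in-plane MSD in nm²/ns with a
molecule-block standard error; the tri-exponential fit returns the
fast / bulk-like / irrotational fractions (summing to one by
construction) and their ordered time constants in ps.

A full end-to-end run (synthetic membrane → all tables) is

```r
cfg <- readRunConfig(NULL, outDir = "run1", seed = 1)
runFullAnalysis(cfg)
```

or, from a shell, `Rscript inst/scripts/mdwater.R all --seed 1 --out run1`.

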