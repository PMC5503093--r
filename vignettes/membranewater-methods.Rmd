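---
title: "Methods: water dynamics at stacked phospholipid membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water dynamics at stacked phospholipid membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranewater)
```

## The system and the observables

Stacked phosphatidylcholine bilayers confine a water slab whose
thickness is set by the hydration level ω (waters per lipid). As ω
decreases, an increasing share of the water sits at or inside the
head-group region, and both its in-plane diffusion and its dipolar
reorientation slow down dramatically. This package computes the four
families of observables used to dissect that slowdown from a
trajectory (positions in Å, times in ps, orthorhombic periodic box):

1. the in-plane mean-square displacement and lateral diffusion
   coefficient D∥ (nm²/ns),
2. the rank-1 dipolar correlation function, its model-free relaxation
   time τ_rot, and a three-population exponential decomposition,
3. hydrogen-bond structure and intermittent hydrogen-bond kinetics,
   split into water–water and water–lipid partners,
4. a Voronoi-based membrane distance ξ that classifies each water
   into membrane interior, first hydration layer, or exterior, with
   region-resolved dynamics.

## Translational dynamics

`msdParallel()` computes
MSD∥(τ) = ⟨|r∥(t₀+τ) − r∥(t₀)|²⟩ for the water center of mass
projected on the membrane (xy) plane, averaged over molecules and
**all** time origins. The all-origin average is evaluated exactly
with the FFT decomposition of the displacement sum; the test suite
checks it against the literal nested loop to 1e-10 relative. The
center of mass is mass-weighted over O + 2H by default
(`com = "oxygen"` uses the oxygen as proxy; for a rigid 3-site water
the two differ by a constant offset that cancels in displacements).

`fitDiffusion()` fits an ordinary least-squares line over a window of
the diffusive regime and reports D∥ = slope/4 (slope/6 in the 3-D
bulk mode). The first 2 ps are discarded — the ballistic/caging
transient — and the default window ends at a quarter of the largest
lag, where few origins remain and the curve gets noisy. Both choices
are configurable and echoed in the outputs.

Because neighbouring MSD lags share origins, the OLS standard error
understates the uncertainty badly; `estimateDiffusion()` therefore
replaces it with the standard error across disjoint molecule blocks
(default 5). The recovery tests use these block errors.

Trajectories must be unwrapped first (`unwrapCoordinates()`, which
accumulates minimum-image steps; exact whenever no molecule moves
half a box edge between frames — a violation is indistinguishable
from a legitimate wrap after the fact, so it is a documented
precondition rather than a runtime check). `msdParallel()` refuses
input whose consecutive-frame jumps exceed half the box.

## Rotational dynamics

The dipole direction is the HOH bisector (minimum-image hydrogens),
which coincides with the dipole axis of rigid 3-site water models and
needs no force-field file. `dipoleACF()` computes
C(τ) = ⟨μ̂(t₀+τ)·μ̂(t₀)⟩ (again exact all-origin averaging via FFT),
and `relaxationTime()` integrates it:

* **truncate** — plain trapezoidal quadrature; refused unless the
  correlator has decayed below 5% at the last lag (otherwise the
  integral is dominated by the unobserved tail).
* **exp-tail** (default) — quadrature is cut where the smoothed
  correlator first falls below a 1% floor (beyond that, true signal
  is negligible while accumulated noise in the quadrature is not),
  and a single exponential fitted to the final observed decade of the
  decay extends the integral analytically. The extrapolated share is
  reported as `tailFraction`.

The default is exp-tail because windows of a few hundred ps truncate
the slow decays badly: at low hydration τ_rot reaches hundreds of ps.
On sampled single exponentials the integral is exact to better than
1%, and on three-exponential curves it matches the analytic value
Σᵢ fᵢτᵢ to 2% (property-tested over 100 random parameter draws).

`fitTriexponential()` implements the three-population (fast,
bulk-like, irrotational) decomposition. The constraint
f_fast + f_bulk + f_irr = 1 is enforced **by construction** — the
fractions are a softmax of two free parameters, so they are
non-negative and sum to one to machine precision — and the time
constants are parameterized as ordered log-increments, which removes
label switching. A five-parameter multi-exponential fit is famously
ill-conditioned, so the optimizer (Levenberg–Marquardt,
`minpack.lm`) is restarted from a deterministic list of ten
log-spaced initializations and the best-residual solution is
returned; determinism keeps failures diagnosable. Unweighted
residuals are the default (weights are exposed). On noiseless curves
the fit inverts `triexpCurve()` to well under 1%.

## Hydrogen bonds

A water donor and an acceptor oxygen (another water's O, or a lipid
phosphate/ester O) are bonded when d_OO < 3.5 Å **and** the donor
O–H / O→O angle is < 30° — both strict, both minimum-image. Water is
always the donor toward lipid acceptors (those oxygens carry no H);
the acceptor set is whatever the topology descriptor lists, so
phosphate-only or phosphate+ester selections are a data choice, not
a code change. Detection uses a periodic cell list and is
property-tested against the O(N²) double loop on 100 random boxes
(the brute-force path stays available as `method = "brute"`).

Counting: a water's water–water count includes donated and accepted
bonds, with pairwise multiplicity capped at one (the rare geometry
where both hydrogens of one donor satisfy the criterion toward the
same acceptor still counts as one bond between that pair, though
each (H, acceptor) record is kept). Histograms run over 0..5 bonds
(overflow pooled into the top bin with a warning), and the joint
(n_wat, n_lip) table has the single-variable histograms as exact
marginals.

Kinetics use the **intermittent** correlator
C_HB(τ) = Σ n(t₀)n(t₀+τ) / Σ n(t₀): a bond may break and reform
between the two times and still count, which is what the product
form implies; no survival requirement. The pair universe is every
pair bonded in at least one analyzed frame — water–water pairs at
molecule level, water–lipid pairs at (molecule, acceptor-atom) level.
Normalization pools all pairs into a single ratio of sums (per-pair
averaging is available as an option). The relaxation time reuses the
same integral code as τ_rot, so the two agree bit-for-bit on
identical series, and the slowdown factor κ = τ_HB(w–l)/τ_HB(w–w) is
reported raw and rounded to two significant figures.

For a stationary two-state process the intermittent correlator does
not decay to zero but to the stationary occupancy; `relaxationTime()`
therefore accepts a `plateau` to subtract, and the telegraph
recovery tests use the known occupancy, giving the closed form
τ_c = (1/mean_on + 1/mean_off)⁻¹.

## Interface geometry

For each frame a 2-D Voronoi tessellation of the membrane plane is
built per leaflet from the head-group P and N atoms (pooled as
atom-level generators). Cell membership of a water's xy-projection is
equivalent to the nearest generator in 2-D periodic distance, which
is how it is computed (ties to the lowest atom id); the property
tests confirm equivalence with an explicit 9-image nearest search.
The water's leaflet is the one whose assigned generator is nearest in
|Δz|, and the membrane distance is signed per leaflet
(ξ = z_water − z_gen on the upper leaflet, the negative on the lower)
so that positive ξ always points into the water slab. Regions:
interior ξ < 0, first hydration layer 0 ≤ ξ < 5 Å, exterior
ξ ≥ 5 Å; the boundary values go to the upper region (half-open
bins — the printed thresholds leave the measure-zero boundaries
unassigned, so some convention is needed).

The density profile weights the ξ histogram to g/cm³ with the slab
volume A_xy × Δξ. The interfacial mean density ρ̄_w = N_w m_w/(A_xy d)
needs an interface width d, which is not uniquely defined for a soft
interface; the default takes the total width of the bins whose
density exceeds 1% of the profile maximum, and d is always reported
alongside ρ̄_w.

Region-resolved dynamics assign each (molecule, origin) pair to the
region occupied **at the origin** for the entire lag window. Origin
assignment is the simplest reproducible contract when molecules can
cross regions; the region field is re-evaluated on a configurable
frame stride. Fast regions relax in picoseconds while the interior
takes hundreds, so the per-region dipole correlator is evaluated on a
log-spaced lag grid; MSDs use a linear grid for the line fit. Errors
again come from molecule blocks. Regions with fewer than 10
contributing origins are skipped with a warning rather than reported
with meaningless error bars.

## The synthetic generators

The generators emulate the statistical structure the estimators
assume, with the ground truth recorded in the trajectory metadata:

* `generateBrownian2D()` — independent in-plane Gaussian steps with
  per-axis variance 2 D dt; rigid hydrogens ride along so the
  topology is complete.
* `generateRotationalDiffusion()` — per-step random rotation vectors
  with component variance dt/τ, the discretization of isotropic
  rotational diffusion whose rank-1 correlator decays as exp(−t/τ)
  (the observable actually analyzed); dt ≥ τ/2 is refused.
* `generateHBTelegraph()` — the exact discrete skeleton of the
  continuous-time two-state chain, so the sampled process has
  exactly exponential dwell statistics and the closed-form
  correlator π + (1−π)e^(−t/τc).
* `generateMembraneSystem()` — two leaflets of jittered-lattice head
  groups (P, N, plus two acceptor oxygens each), waters placed by a
  layered density profile over ξ and given region-dependent Brownian
  and rotational dynamics. Waters keep their initial z (no
  cross-region exchange), so origin-region assignment is exact and
  parameter recovery is clean. Density bands whose edges sit on a
  region boundary are pulled back by `regionMargin` (default three
  head-jitter standard deviations) so that head-group roughness
  cannot flip a water's measured region across a boundary — the
  generated region labels then stay recoverable by construction.

Default study conditions: 16 lipids per leaflet on an 8 Å lattice
(0.5 Å jitter), leaflets at z = ±15 Å in a 60 Å box, 240 waters, 600
ps at 0.1 ps spacing. The per-region truths use the fully hydrated
region-resolved values (D = 0.19/0.81/4.10 nm²/ns and
τ_rot = 270/37/3.3 ps for interior/first layer/exterior), and the
trajectory length was chosen as at least twice the slowest relaxation
time so the interior correlator is integrable with a modest tail.
These sizes are desk-scale by design: production MD behind such
numbers runs tens of nanoseconds with thousands of waters, so
absolute statistical errors here are larger, and the tests compare
against ground truth through the estimators' own block standard
errors rather than at fixed percentages.

What the fixtures deliberately do **not** model: water exchange
between regions, membrane undulations or head-group motion (the
scaffold is rigid), any energetics, and consistency between the
telegraph bond processes and 3-D geometry (the geometric HB kinetics
of the membrane fixture emerge from its rotating waters instead).
Passing recovery tests therefore validates the estimators, not the
realism of any particular force field or sampling protocol.

## Numerical choices and degenerate inputs

* Correlation and MSD inner sums use zero-padded FFTs; they are
  algebraically identical to the nested loops and are tested to
  1e-10 relative.
* Unit conversions: positions Å, times ps; D converted once at the
  reporting boundary (1 Å²/ps = 10 nm²/ns).
* `C(0)` is set to 1 exactly for normalized correlators (it is 1 up
  to rounding anyway) so downstream normalizations are stable.
* Non-decayed correlators: `truncate` raises an unreliable-integral
  error; `exp-tail` raises it only when no decaying tail can be
  fitted (e.g. C ≡ 1).
* Degenerate water geometry (opposed hydrogens, broken molecules)
  raises explicit dipole errors rather than returning NaN.
* Voronoi ties and the ξ region boundaries use fixed deterministic
  conventions (lowest id; half-open bins), so reruns are identical.
* All generators take a mandatory seed; the pipeline seeds once per
  run and writes a config hash into every metadata file, and
  identical configurations reproduce byte-identical CSVs.

## Known limitations

Orthorhombic boxes only (the stacked-membrane geometry); no binary
MD formats (multi-model PDB and XYZ with a YAML role descriptor); no
Legendre-P₂ correlators or stretched exponentials; no reactive-flux
HB rate constants; no area-per-lipid or curvature analysis. The
three-exponential decomposition is reported with its residual norm
because even noiseless fits of sums of exponentials are
ill-conditioned — interpreting its parameters as literal populations
is a modelling choice, not something the fit can establish.
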