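---
title: "Alternating-projections SAR optimization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alternating-projections SAR optimization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The planning problem

A ring of N phased antennas drives a total field
E(r) = Σₙ bₙ eₙ(r), where eₙ is antenna n's field under unit excitation and
b ∈ ℂᴺ are the feedings. Deposited power is the specific absorption rate
SAR(r) = ½ σ(r)/ρ(r) |E(r)|² (peak-phasor convention; the ½ is dropped for
RMS phasors — `compute_sar()` refuses to guess and requires the flag).
Planning quality is summarized by:

* **HTQ** — mean SAR over the hottest 1 % of the healthy volume (V1, at
  least one voxel, ties broken by a stable sort) divided by mean tumor SAR.
  "Healthy" here includes the transition shell — everything outside the
  tumor — per the standard definition.
* **Vχ%H** — the percentage of healthy volume with SAR above χ % of the
  tumor maximum. V10%H tracks diffuse spillover, V50%H hot spots.

Both are invariant under global rescaling of b, so they measure pattern
shape, not power.

## The alternating projections loop

Sampling the fields on M tissue voxels and stacking Cartesian components
(x block, then y, then z) gives the 3M×N matrix E_N. The set of realizable
fields is its column space; the set of acceptable fields is the two-level
mask {|E|² ≥ thlow on tumor voxels, |E|² ≤ thup on outer healthy voxels,
unconstrained transition shell between r_t and r_h}. `run_apa()` alternates:

1. clip: rescale each violating voxel's 3-component complex vector so its
   intensity sits exactly on the violated threshold (pure magnitude scaling —
   per-component phases preserved; the factor is √(th/|E|²) because the
   thresholds are intensities). The transition shell is never touched. A
   zero-magnitude tumor voxel has no direction to scale along; it is left
   unchanged and counted.
2. project: b = E_N† E_clipped via the cached truncated-SVD pseudo-inverse
   (singular values below rcond·σ_max with rcond = 1e−10 are dropped;
   E_N† is computed once per run).
3. normalize: b ← C b with C = √(2R₀P₀/‖b‖²), fixing ‖b‖²/(2R₀) = P₀
   exactly. The textbook constant P₀/(‖b‖²/2R₀) is a power ratio; its square
   root is the amplitude scale that actually enforces the constraint.
4. reconstruct E = E_N b and evaluate HTQ on this — always physically
   realizable — field, with the full 3-component magnitude even though the
   target populates only one component (the mask constrains deposited power,
   which is polarization-agnostic).

The returned excitation is the iterate with the minimum recorded HTQ, not
the last one. Stopping (all thresholds are package defaults, the cap is the
conventional one):

* hard cap `max_iter = 4000`;
* plateau: best HTQ not improved by a relative `plateau_tol = 1e−4` for
  `plateau_window = 50` consecutive iterations;
* out-of-mask divergence: the clip count rising strictly for
  `oom_persistence = 20` consecutive iterations;
* fixed point: nothing clipped and the field unchanged (relative change
  < 1e−12) — an early exit for already-feasible targets.

The loop contains no randomness; identical inputs give bit-identical traces.

## Adaptive threshold search

Rather than hand-picking (thlow, thup), `run_threshold_sweep()` derives both
from one Gaussian **intensity** profile A₀·exp(−d²/2σ₀²) centered on the
tumor. Interpreting the profile as an intensity (V²/m²) is forced by unit
consistency: A₀ = 10⁴ V²/m² and the thresholds are compared against |E|².
The target field is its square root with zero phase on the dominant
polarization component (ties in `dominant_component()` break x < y < z).
For each candidate thup ∈ (0, A₀):

* σ₀ = r_h·[2 ln(A₀/thup)]^(−1/2), so the profile crosses thup exactly at
  r_h;
* thlow = A₀·exp(−r_t²/2σ₀²), the same profile at r_t (hence thlow > thup).

A₀ should not exceed what the array can deliver;
`estimate_peak_intensity_bound()` gives the Cauchy–Schwarz bound
2R₀P₀·maxᵣΣₙ|eₙ(r)|², attained exactly for N = 1 and for identical cophased
antennas (both tested). The default candidate set — 10 log-spaced thup in
[0.1, 0.9]·A₀ — is a package choice; candidates are evaluated independently,
so the sweep is order-invariant.

Each candidate's APA result is scored by (V10%H, V50%H); `select_knee()`
keeps the nondominated set and picks the point with the largest
perpendicular distance to the chord between the extreme nondominated points
after min–max normalization of both axes ("knee"). Distance ties go to the
smaller V50%H; a single nondominated point is its own knee. The
distance-to-chord rule is one of several defensible knee definitions; it is
deterministic and scale-free, which is what the sweep needs.
`check_knee_stability()` re-runs the sweep under ±10 % perturbations of A₀
and r_h as a verification aid, not an assertion.

## PSO benchmark

`run_pso()` is a plain global-best particle swarm over 2N parameters
(amplitude ∈ [0, amax] with reflective bounds; phase wrapped modulo 360°),
each particle power-normalized before evaluation so the objective is
scale-invariant by construction. Swarm size defaults to 100 (common in
SAR-optimization practice); inertia 0.729 and cognitive = social = 1.49445
are the standard constriction values, chosen because the benchmark
literature rarely reports its hyperparameters; stopping mirrors the APA
plateau constants for comparability. The run is a pure function of the seed;
the seed is recorded in the result. The package reports APA-vs-PSO
comparisons but asserts no ordering between them: which method wins on a
given field matrix is an empirical matter, not a theorem.

## Surrogate fields: what they emulate and what they do not

Real planning uses full-wave solver exports; the JSON field container
(`read_field_container()`) is the import path, with a bit-exact round-trip
(doubles serialized as %.17g strings) and schema/version validation. For a
self-contained desk-scale loop, `synthesize_surrogate_fields()` emulates an
N-antenna ring around a lossy cylinder: each antenna contributes
A·exp(−(α+jβ)d)/d with α, β from the standard lossy-medium closed forms of a
single reference tissue (default muscle) at the ring frequency, a dominant z
component tapered by (1+sin²θ)/2 of the source–voxel direction, and a fixed
8 % transverse leakage with deterministic per-antenna phases — reproducing
the order-of-magnitude z-dominance of ring arrays (the taper floor of ½
keeps the dominant axis ≥ 6× each transverse component). Source distance is
floored at one voxel spacing (a guard; antennas sit outside tissue). The
source amplitude default (2 V) was fixed a priori so the constructive-
interference bound at a deep-seated tumor is of order 10⁴ V²/m² at 1 W,
making the conventional A₀ = 10⁴ V²/m² feasible.

Not emulated: heterogeneous refraction and standing waves, antenna coupling
and mismatch, the waterbolus as an EM medium, near-field reactive terms.
Consequently a green optimizer test establishes correct algorithm mechanics
(projections, normalization, mask semantics, metric accounting) — not
clinical performance on real anatomy, which requires imported solver fields.

## Bioheat solver and calibration

`solve_pennes_steady()` solves the steady Pennes equation
0 = ∇·k∇T − ρ_b C_{p,b} ω_s (T − T_a) + SAR·ρ·P0_scale on the tissue voxels
(ρ_b = 1060 kg/m³, C_{p,b} = 3890 J/kg/°C, T_a = 37 °C; metabolic heat
omitted as negligible next to the external source). Perfusion tables use the
clinical unit mL/min/kg; the sink needs 1/s, so
ω_s = ω·ρ_tissue·10⁻⁶/60 — the conversion is explicit because it is a
classic silent-unit bug. Discretization: 7-point finite volume,
harmonic-mean face conductivities, convective (Robin) faces modeled as a
half-cell conduction resistance in series with the film coefficient (so
h → ∞ recovers a fixed face temperature; the 1-D slab test exploits this),
insulated where no boundary condition applies. The sparse system is solved
directly (Matrix); the relative balance residual is attached to the result
and asserted < 1e−8. Defaults for the fixture: waterbolus convection
h = 82 W/m²/°C at 20 °C on the exterior surface; an interior cavity (e.g.
trachea, h = 50, 30 °C) is expressible as a mask-selected surface.

T90/T50/T10 are nearest-rank order statistics: Tq is the largest observed
temperature reached or exceeded by at least q % of region voxels,
`sort(T, decreasing)[ceiling(q·n/100)]`, which guarantees T90 ≤ T50 ≤ T10.

`calibrate_input_power()` uses the linearity of the steady problem: with
T_hom the zero-source solution, T(P) = T_hom + P·(T₁ − T₀ per voxel), and
the calibration statistic (tumor T90 by default — the field's convention
when a paper says "42 °C was reached in the tumor" without naming the
statistic; the argument makes it explicit) is monotone in P. The scalar
equation is solved by bracketing + uniroot and confirmed by one full
re-solve.

## Degenerate inputs and numerical conventions

* Pseudo-inverse rank 0, all-zero field matrices, zero tumor SAR, empty
  regions: classed errors (`apahtp_degenerate_error`), never NaN results.
* Voxel membership is by voxel-center test (no partial volumes): region
  volumes are countable and converge with an O(spacing) shell error, tested
  on the cylinder. Equal-volume voxels make "1 % of volume" = 1 % of count —
  a documented simplification relative to FEM meshes.
* The tumor region for partitioning is the union of tumor-labeled voxels
  and the r_t ball, so imported irregular tumors are covered and r_t acts as
  a lower bound.
* Whether the Vχ%H denominator includes the transition shell is ambiguous in
  the field; both scopes are implemented (`healthy_scope`), reports label
  the scope, and the default (include it) matches the HTQ convention.
* R₀ = 50 Ω is a convention (the reference input resistance is rarely
  printed); it is stored as container metadata and configurable everywhere.
* All lengths are mm in configs and types; SI conversion happens only inside
  the bioheat assembly and the surrogate propagation terms.

## Known limitations

Single-frequency (non-dispersive) tissue properties; no antenna design,
coupling, or S-parameters; no transient heating or CEM43 dose; no
discrete-vasculature thermal models; no anatomical segmentation import
beyond the field container + label volume route; the PSO benchmark is one
representative meta-heuristic configuration, not a tuned competitor.
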