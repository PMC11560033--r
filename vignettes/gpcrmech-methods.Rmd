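---
title: "Methods: quaternion-based analysis of GPCR activation in stressed membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quaternion-based analysis of GPCR activation in stressed membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrmech)
```

## What the package computes

`gpcrmech` re-implements, as tested and reusable R functions, the analysis
machinery used in steered molecular-dynamics (SMD) studies of GPCR
mechanosensitivity, modelled on the angiotensin II type 1 receptor (AT1).
The canonical activation of a GPCR opens transmembrane helix 6 (TM6)
outward and moves TM7 inward; mechanical membrane stress (surface tension)
and anionic lipids can instead stabilize alternative conformations with an
open TM7. The package provides the quantitative pieces of that analysis:

* a **quaternion description of helix reorientation** — the rotation taking
  the TM6 axis from its inactive to its current orientation, carried as
  `Q = (cos(θ/2), sin(θ/2)·u)` with `u` the normalized cross product of the
  two axes;
* **conformational-state classification** from the Cα marker distances
  TM3–TM6 (BW 3.50–6.34) and TM3–TM7 (BW 3.50–7.55);
* the **lateral pressure profile** `π(z) = (pxx + pyy)/2 − pzz` reduced
  from per-slab pressure-tensor time series, with drift correction,
  time averaging and 3-point smoothing;
* membrane property measures: peak-to-peak **bilayer thickness**, **area
  per lipid** with the protein footprint subtracted, the acyl-chain
  **order parameter** `S_CH = ⟨3cos²θ − 1⟩/2`, and the surface-tension
  relation `γ = Lz(Pz − PT)`;
* protein **cross-section area profiles** `A(z)` and the **work integral**
  `W = ∫ δA(z) π(z) dz` that converts a conformational area change into an
  energetic cost against the membrane;
* **lipid–receptor interaction detectors**: H-bonds between lipid head
  oxygens and the C-terminal basic residues (BW 7.58, 7.59, 7.61, 7.62),
  and the four-inequality internal-lipid criterion;
* a **toy steering simulator** and **synthetic-data generators** that
  produce trajectories, bilayers and pressure series with known ground
  truth, so every analysis operation can be validated end to end.

## Ballesteros–Weinstein arithmetic

A `bw_scheme()` stores the seven x.50 anchor residues (default: the AT1
assignment N46, D74, R126, W153, P207, P255, P299). A label `h.xx` resolves
to `anchor(h) + (xx − 50)` by pure arithmetic; positions beyond 7.50 (the
helix-8 region, e.g. 7.58–7.62) use the same offset rule. No coordinate
access is involved, so the mapping is exact and strictly monotone within a
helix.

## Helix axes and quaternions

The helix axis is computed by the bisector construction: for each interior
Cα the bisector `b_i = (p_{i−1} − p_i) + (p_{i+1} − p_i)` points radially
toward the axis, and cross products of successive bisectors are parallel to
the axis — exactly so for an ideal helix. We chose this over a raw
principal-component fit because PCA of a helical point cloud carries a
partial-turn phase bias (up to ~1.7° for a 17-residue segment), which would
dominate the sub-degree angles the steering analysis needs to resolve. The
axis sign is disambiguated N→C by the projection of the difference between
the half-trace centroids.

`rotation_quaternion(a, b)` uses `θ = atan2(‖a×b‖, a·b)` for stability near
0° and 180°. Degenerate cases are deterministic: parallel axes give the
identity; antiparallel axes give a 180° rotation about the lowest-index
canonical basis vector not parallel to the input, orthogonalized. The
scalar part is kept non-negative so θ ∈ [0°, 180°].

```{r}
a <- helix_axis(ideal_helix(17))
q <- rotation_quaternion(a, apply_rotation(axis_angle_quaternion(35, c(1, 0, 0)), a))
quaternion_angle(q)
```

## The toy steering simulator

The SMD protocol is emulated on a single angular coordinate: a harmonic
restraint `U = ½ k θ_dev²` whose target orientation ramps linearly in angle
from the identity to the target over the pull phase (default 20 ns), then
is removed for the relaxation phase (default 70 ns). The engine's published
force constant, 5000 kcal/(mol·rad²) ≈ 1.52 kcal/(mol·deg²), is the
default. Whether the engine's orientation restraint is harmonic in θ_dev or
in `1 − |q·q_target|` is not documented; we fixed the toy model to the
harmonic-in-angle form, the simplest choice consistent with the printed
unit conversion, and the one with a closed-form deterministic limit
(tracking lag `friction·v/k` behind a ramp of angular velocity `v`) used in
the tests. The dynamics is overdamped Langevin,
`dθ = (k/friction)(θ_target − θ)dt + √(2D dt)·ξ`, with defaults
`friction = 0.05 kcal·ns/(mol·deg²)` and `dt = 0.01 ns` so the 20 ns ramp
is well resolved; steps with `k·dt/friction > 0.5` are rejected as
unstable. The companion TM3 restraint of the original protocol (target
orientation fixed at the identity) is represented by the fixed laboratory
frame and is not simulated. This module validates schedule/restraint logic
only; it makes no claim of reproducing atomistic SMD trajectories.

## State classification

The TM7 position is classified from the TM3–TM7 distance averaged over the
analysis window (default 60–90 ns, the final 30 ns of the standard 90 ns
protocol — a windowed mean, not a per-frame majority):
pre-active `< 16 Å`, non-canonical `16–19 Å`, atypical `≥ 19 Å` (at or
beyond the inactive-state distance). Heatmap export uses a finer four-bin
code splitting the atypical range at 21 Å. The published rule leaves
equality at the edges uncovered; we use lower-closed intervals
(`16 → non-canonical`, `19 → atypical`, `21 → yellow`), consistent with the
atypical state being defined as *equal to or larger than* the inactive
distance. Heatmap bins are computed per frame (not window-smoothed); the
windowed mean enters only the three-state summary.

## Lateral pressure pipeline

Input is a documented TSV of per-slab diagonal pressure-tensor elements
(time, slab index, z, pxx, pyy, pzz, in bar) plus a sidecar (time, Lz,
z_P); the native MD-engine log is not parsed, keeping the pipeline
engine-agnostic. The pipeline (1) computes raw `π(z,t)`, (2) shifts each
instantaneous profile so the lipid-phosphorus barycenter z_P(t) maps to
z = 0, resampling by linear interpolation onto the fixed grid
(nearest-slab shifting is available via `drift_mode = "nearest"`),
(3) averages over `t ≥ t_min` (default 20 ns, allowing the box to
stabilize), and (4) applies a 3-point running mean whose endpoints average
the two available points. The cell height Lz is recorded for the
surface-tension check `γ = Lz(Pz − PT)` only; pressures are taken as
already normalized to bar by the producing engine. Unit constants are
centralized: 1 bar·Å = 0.01 dyn/cm and 1 bar·Å³ = 1.4393e-5 kcal/mol.

Bilayer thickness is the peak-to-peak distance of the pooled phosphorus z
histogram (default bin 0.5 Å), with each leaflet mode refined by a
parabolic fit through the top bin and its neighbours; a distribution with
no second mode at least 10 Å from the first is rejected as unimodal.

## Cross-section areas and the work integral

`A(z)` is measured by slicing each protein atom's van der Waals sphere at
the slab center (disk radius `√(R² − Δz²)`, not the maximal sphere radius —
consistent with 0.2 Å slabs being thin relative to atomic radii) and
counting occupancy-grid cells (default 0.1 Å) whose centers fall inside any
disk. Default radii: H 1.2, C 1.7, N 1.55, O 1.52, S 1.8, P 1.8 Å. The
estimator is validated against analytic disk areas and Monte-Carlo
disk-union sampling; its discretization error is O(cell²) but oscillates
with the cell size, so convergence is checked coarse-vs-fine rather than
per-step monotone. Any constant offset relative to other area definitions
cancels in the difference profile `δA(z)`. Multi-frame profiles average 15
snapshots regularly spaced over the final 30 ns (both configurable) after
rigid-body least-squares superposition of each frame's Cα trace onto the
first selected frame. `W = ∫ δA(z) π(z) dz` is a trapezoidal integral over
the intracellular 0–20 Å range by default, with the pressure profile
linearly resampled onto the area grid.

## Contact detectors

The H-bond rule mirrors the cutoff semantics of the common visualization
tooling: donor–acceptor heavy-atom distance ≤ 3.5 Å and the angle between
the donor→hydrogen and donor→acceptor directions ≤ 30°, both inclusive.
Counting is per donor–acceptor atom pair, so a residue making two
simultaneous bonds contributes two. Donors are the side-chain N–H groups of
Lys/Arg at BW 7.58, 7.59, 7.61, 7.62; acceptors are lipid head oxygens
(atom names matching `^O`). A lipid phosphorus in the intracellular leaflet
is *internal* when all four strict inequalities hold: d(P, Cα3.50) < 15 Å,
d(P, Cα7.56) < 12 Å, and each below d(Cα3.50, Cα7.56) — the relative pair
excludes external lipids near the TM5–TM6 cleft. Equality at any cutoff is
not internal. The residue-side reference atoms are Cα (configurable).

## Statistics

Distances and areas (approximately normal across replicas) are compared
with `welch_ttest()` — Welch's unequal-variance form by default, since the
replica groups are small with unequal spread; the pooled-variance form is
available behind a flag. Spread, skewed quantities (H-bond counts, internal
fractions) use `ranksum_test()`, which enumerates exactly when the pooled
sample has ≤ 12 tie-free observations and otherwise uses the normal
approximation with continuity and tie correction. Both granularities of
replica reporting are supported through `replica_summary()` rows (one per
replica), which can be grouped per initial snapshot downstream. Raw
p-values are reported; no multiple-testing correction.

## What the generators emulate — and what they do not

The generators encode the geometric and statistical structure the analyses
measure, under the study's stated conditions as defaults:

* a 7-helix bundle with the AT1 BW anchors, marker distances settable
  exactly (initial TM3–TM7 distance 20 Å, the inactive value);
* a TM6 opening of 35° ramped over 20 ns and held through a 70 ns
  relaxation, sampled by default as 12 equidistant frames over 90 ns;
* TM7 scenarios calibrated to the published representative end states:
  inward → 14.7 Å (pre-active), outward → 23.2 Å (atypical);
* two head-group leaflets at 38.8 Å separation (the NPT thickness), PC:PG
  mixing (0.9 emulating the 9:1 mixed bilayer), and an optional lipid
  placed to satisfy — or near-miss — the internal criterion in a programmed
  fraction of frames;
* pressure series built from a four-Gaussian `π(z)` (positive head peaks,
  negative interface peaks) whose integral is set directly; −2000 bar·Å
  over a 100 Å box corresponds to the applied tension of 20 dyn/cm;
  white tensor noise and linear leaflet drift are optional.

They do **not** model acyl-chain conformers, force-field energetics,
correlated noise, helix flexibility (the steered segment moves rigidly), or
the coupling between protein conformation and the pressure profile. A
passing round trip therefore demonstrates that the analysis operations
recover what they are defined to measure — not that the biology of the
original simulations is reproduced. In particular, state fractions per
condition, H-bond means and work values from the μs-scale campaigns are
not desk-scale reproducible and are not asserted anywhere; the package
instead verifies the printed analytic examples (the 35° quaternion, the
force-constant conversion, the 50 Å² → 1000 Å³ volume, the classification
of 14.7/17.0/23.2 Å) and the self-consistency properties.

Every generator draws its randomness inside a scoped seed
(`generator_spec(seed = ...)`), restoring the caller's RNG state, so
outputs are bitwise reproducible and independent of call order.

## Problem sizes and tolerances used in the tests

The suite exercises reduced-scale systems chosen so every property holds
with margin while each file runs in seconds: 12–60 frame trajectories,
20–200 lipids per leaflet, 100 pressure slabs with up to 2000 time points,
Monte-Carlo disk-union oracles with 10⁶ samples over 12 random clusters,
and 1000 random axis pairs for the quaternion/arccos identity. Geometry
identities are asserted at 1e-9, PDB round trips at the format's 0.001 Å
precision, generator round trips at 0.1–0.2 of the programmed unit, and
the area estimator at 1–2% of the analytic value.

## Known limitations

* The multi-model PDB reader handles standard ATOM/HETATM records with a
  single-character chain identifier; no mmCIF, no bond perception, no
  hydrogen placement.
* The cross-section estimator is a sliced union-of-disks; it is not a
  solvent-excluded surface and does not claim bit-compatibility with other
  area scripts — only differences δA(z) are interpreted.
* The steering simulator is one-dimensional in the rotation angle; the
  full rigid-body orientation dynamics is out of scope.
* The exact atom roster of externally deposited trajectory files may vary;
  the loader accepts protein-only or protein+lipid rosters but requires
  the roster to be identical across models of one file.
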