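---
title: "Reverse-biomimetic reconstruction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-biomimetic reconstruction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebiom)
```

This vignette is the package's own account of its methods: what each stage
computes, which parameters matter and why their defaults are what they are,
what the synthetic generators emulate (and deliberately do not), and where
a design decision was genuinely open.

## 1. The reconstruction problem

Digitising a skeletal structure yields noisy, multi-view point clouds.
Recovering a functional digital model from them requires more than
surfacing: the *features that carry function* — articular (condylar)
surfaces, tooth cusps, principal anatomical directions — must be
identified, because joints, occlusal contacts, and alignment conventions
are all defined in terms of them. `rebiom` implements that chain for two
model systems: tooth crowns (cusp anatomy) and the human hand (27 bones,
21 modelled rotational degrees of freedom).

## 2. Curvature estimation and surface classification

### 2.1 Principal curvatures

`estimate_principal_curvatures()` fits an osculating paraboloid
`z = ax² + bxy + cy² + dx + ey` over each vertex's `ring`-neighbourhood in
the local tangent frame and eigen-decomposes the shape operator of the
graph. The default `ring = 2` (roughly 19 neighbours on a regular
triangulation) balances noise averaging against feature blurring: on the
analytic icosphere fixture the relative error of k₁, k₂ is below 5%, and
the classification accuracy criterion (≥ 95% of interior vertices correct
on sphere/plane/cylinder/saddle) passes with this default. Vertices with
fewer than five usable neighbours are flagged undefined and later inherit
the nearest defined class.

**Sign convention.** Curvatures are signed so that a region bulging along
the *outward* normal has k₁, k₂ < 0. This makes H < 0 mean "convex", which
is the orientation the HK classification table assumes; it is the one
convention the table implies but never states, so it is fixed here once
and tested on the analytic fixtures.

### 2.2 HK and SC classification

`hk_classify()` maps the sign pattern of (H, K) to eight shape cells, with
the geometrically impossible cell H = 0 ∧ K > 0 labelled `invalid`.
`sc_classify()` uses the shape index
S = −(2/π)·arctan((k₁+k₂)/(k₁−k₂)) and curvedness C = √((k₁²+k₂²)/2).
S is undefined at flat points (k₁ = k₂ = 0, where C = 0); at non-flat
umbilics the 0/0 form is resolved by continuity to ±1.

Where the class boundaries sit was a genuinely open decision. The critical
points S = 0, ±0.5, ±1 are where classification changes: the critical
values themselves are classes (cap/cup, ridge/rut, saddle) and the open
intervals between them supply the rest. Because exact critical values are
never attained by estimated curvatures, `sc_classify()` recognises each
interior critical point within a band `eps_s` (default 0.05). This choice
makes SC agree with HK *cell for cell* — K = 0 (developable) corresponds
exactly to S = ±0.5 and H = 0 to S = 0 — which is tested as an invariant.
An alternative (binning at the odd eighths with criticals as bin centres)
was rejected because it breaks that correspondence near the developable
boundaries.

**Zero thresholds.** `classify_field()` derives `eps_h = eps_c = 0.05·s`
and `eps_k = 0.05·s²` from the robust curvature scale
`s = MAD(C)` of the field itself. Basing the K-threshold on `s²` (not on
the MAD of K) matters: on a cylinder the entire K field is estimation
noise, and a threshold derived from it would classify the cylinder as
saddle. The 5% factor is a package default, recovered by the
parameter-recovery tests rather than taken from any published value.

## 3. Region segmentation and cusp extraction

`segment_regions()` flood-fills same-class connected components and merges
components below `min_vertices` (default 20) into their largest-area
neighbour, ties to the lowest id. `extract_cusps()` then emits one record
per apex: local maxima of the projection along the region's mean outward
normal, restricted to region-interior vertices (so convex rims and collars
do not count), with two cleanup rules — records must protrude above their
boundary loop (non-negative prominence) and two apexes closer than 10% of
the bounding-box diagonal are deduplicated by non-maximum suppression.
Enumerating *all* interior local maxima (rather than one apex per region)
makes the count robust when noise bridges two neighbouring cusp caps into
a single region.

For noisy scans the documented preprocessing is Taubin λ/µ fairing
(`taubin_smooth()`, 50 iterations at the default λ = 0.5, µ = −0.53)
before curvature analysis. With it, the cusp count on the molar (8) and
premolar (6) presets is stable across independent noise realisations at a
noise amplitude of 1% of the crown diameter — the regime the segmentation
robustness tests exercise.

## 4. Long-bone features and joint centres

`partition_bone_features()` samples the cross-section area profile along
the primary RGE axis and takes the two interior local minima nearest each
extremity as the anatomical necks, splitting the bone into head, shaft
(the `"end"` of the head/end/base naming is accepted as a synonym), and
base. The extremity with the larger maximal cross-section is labelled the
head — true for metacarpal/phalanx anatomy — with an override for atypical
bones. Cylinders (no necks) either raise an error or fall back to a
single-feature labelling, by configuration. Compact (carpal-like) bones
are out of this function's scope and are treated as single regions.

`rge_frame()` computes the centroid and axes from the **solid** inertia
tensor (not vertex covariance) because the centre of gravity is a solid
property; vertex covariance is the flagged fallback for open meshes. Axes
are ordered by spatial extent rather than eigenvalue so flat, wide bones
still get a stable primary axis, and each axis is flipped so the vertex
with the largest absolute projection has positive projection (an arbitrary
but deterministic and rigid-equivariant rule; downstream comparisons are
written sign-aware).

`fit_cor()` estimates joint centres of rotation: algebraic least-squares
sphere fit refined by Gauss–Newton for two-axis joints, and a
circle-in-a-plane fit (PCA plane + Kåsa seed + refinement) for hinge
joints' condylar profiles. How the original workflow derived CORs from
cross-sections is not published; least-squares fitting is this package's
commitment, validated purely by parameter recovery: exact on exact data,
mean centre error below 0.05 mm on noisy hemispheres (σ = 0.05 mm, 500
points), and exact recovery of the generator's condylar centre on the
synthetic bone. The articular cap is isolated with
`head_condyle_points()` (distal half of the head feature) plus an optional
trimmed refit (`trim`), because the neck-side rim of the head feature is
not articular surface.

## 5. B-spline modelling

Curves and surfaces are clamped cubic B-splines (the industry default;
degree is configurable). Curves use chord-length parameterisation with
pinned endpoints. Surfaces are tensor-product fits over the projection of
the region onto its two principal directions — a height-field assumption;
regions that are not height fields (full condylar caps) should be split
first, and the fit report's deviations make violations visible. The
objective is penalised least squares with a second-difference
(thin-plate-style) penalty on the control net; λ defaults to 1e-3 and is
dimensionless under uniform scaling because data and penalty terms scale
identically. The reported deviations come from dense surface resampling;
refinement monotonicity (finer nets fit better) and the fairing trade-off
(larger λ: smoother net, larger misfit) are tested as properties rather
than against any published values. `stitch_and_validate()` samples patch
boundaries, pairs each with the closest boundary of another patch (within
a quarter of the assembly diagonal), and reports the worst gap.

## 6. The hand model

### 6.1 Structure

The skeleton has 27 bones — 8 carpals, 5 metacarpals, 14 phalanges (the
thumb has no middle phalanx) — and 15 articulating joints: 9 revolute
(PIP, DIP, thumb IP) and 6 universal (four finger MCPs, thumb MCP, thumb
CMC), totalling 21 rotational DoF. The published joint count (9 + 6)
cannot by itself connect 19 non-carpal bones to the wrist in a tree, and
the exact split of the six universal joints across MCP/CMC is ambiguous;
this package resolves both by fixing the finger metacarpals rigidly to
the carpal block (their CMC joints are anatomically near-immobile) and
giving the thumb its CMC universal + MCP universal + IP revolute chain
(5 thumb DoF within the 21). The carpal block itself is fixed, as in an
underactuated prosthetic wrist. The anatomical enumeration (4 DoF per
finger, 5 for the thumb, 6 for the wrist = 27) is reported separately by
`enumerate_dof(mode = "anatomical")`.

### 6.2 Dynamics

Joint laxity is modelled as a linear torsional spring–damper per
articulation axis:

I·θ̈ = τ(t) − k·(θ − θ₀) − c·θ̇ + limit penalty,

integrated by classical fixed-step RK4 and *decoupled per axis* — a
deliberate simplification of fully coupled rigid-body dynamics that keeps
the model closed-form testable (the step response is compared against the
analytic damped oscillator to 10⁻⁴ rad). The per-axis inertia is the
inertia of the distal sub-chain about the joint axis at rest, frozen
during simulation. The limit penalty is a one-sided spring of stiffness
`limit_gain·k` (default 400·k), sized so that plausible torques violate
the range of motion by less than 0.5°.

**Parameters.** No spring/damper values are published for this kind of
model. Stiffness defaults to k = 50 N·mm/rad per axis. Damping is
specified as a damping *ratio* ζ = 0.7 per joint (c = 2ζ√(kI) per axis)
rather than a single absolute coefficient: chain inertias span four orders
of magnitude between the thumb CMC and a small DIP, so any single c makes
some joints essentially rigid and others unstable for explicit
integration, whereas a common ζ gives every joint the same response
character. An absolute c (N·mm·s/rad) is accepted as an override
wherever a measured value exists.

### 6.3 Clinical scoring

The Kapandji test counts 11 thumb-opposition targets (positions 0–10).
Targets are derived procedurally from the skeleton's rest geometry:
positions 0–1 on the radial side of the index, 2–5 the index→small
fingertips, 6–8 the small-finger DIP/PIP/MCP creases, 9–10 proximal palm
points along the small metacarpal. A position is achieved when the thumb
tip passes within the 5 mm default tolerance; the score is the highest n
with positions 1..n all achieved. The generator places the skeleton in a
natural semi-flexed resting posture and pronates the thumb column so that
all 11 rest-geometry targets lie inside the thumb's reachable workspace;
the reference trajectory is then constructed by damped-least-squares
inverse kinematics over the five thumb axes and touches every target by
construction.

The Fugl-Meyer battery checks seven hand positions (full extension, full
flexion, hook, key, tripod, spherical, cylindrical grips) as per-joint
angle bands *relative to the rest pose*; the bands are package defaults
chosen to be mutually exclusive at the neutral pose (the all-zero pose
passes only full extension) and internally consistent with the bundled
reference poses. No published band values exist; the battery therefore
validates internal consistency, not agreement with any clinical dataset.

Spherical-grip forces distribute a prescribed total (400–600 N is the
adult male maximum grip range; 475 N is the worked default) over the
fingertip contacts of a grasp pose by sum-constrained non-negative least
squares on the net force-and-torque residual, solved exactly by
active-set enumeration with a tiny ridge that selects the minimum-norm
solution among degenerate optima (so a fully symmetric grasp shares the
load equally). Published per-digit forces from the original multibody
solver are not reproduction targets — that solver and its parameters are
unavailable — so the conserved-total, symmetry and scale-consistency
properties stand in.

## 7. Synthetic fixtures: what they emulate, and what they do not

The generators produce *parametric idealisations*, not anatomical
replicas: lathed long bones (superellipse cross-section, half-cosine neck
blends with minima exactly at the specified stations, a true spherical
condyle), Gaussian-bump occlusal crowns (8 cusps for molars, 6 for
premolars; incisors are deliberately parameterised rather than preset
because their cusp count is anatomically ambiguous), icosphere carpals,
and a scanner emulator adding Gaussian noise along the normal (default
σ = 0.05 mm, the class of desktop structured-light scanners), dropout and
per-view rigid mis-registration with ground-truth transforms.

Their ground truth is analytic (solid-of-revolution integrals for CoG and
volume, closed-form condyle centres, known cusp apexes), so recovery
tests measure the pipeline, not the mesh. What passing those tests does
**not** show: robustness to real scanner artefacts (structured outliers,
specular dropout bands, registration drift), to cortical-bone surface
texture, or to anatomical shape variation across individuals. Claims here
are about the algorithms under controlled conditions.

## 8. Numerical choices and degenerate inputs

- Welding tolerance 1e-6 mm; watertightness = every edge shared by
  exactly two faces; winding auto-corrected when the signed volume is
  negative.
- Point-in-mesh parity rays use a fixed oblique direction to avoid
  edge-grazing degeneracies on lathed/gridded meshes.
- Sphere fits reject coplanar inputs with advice to use circle mode;
  unpenalised surface fits reject rank-deficient systems with advice to
  raise λ.
- Degenerate RGE frames (spherically symmetric bodies) are flagged
  `degenerate` but still return an orthonormal triple.
- The problem sizes used throughout the test-suite — bones of ~3,000
  vertices, crowns of ~4,300, 10 noise seeds per robustness battery,
  0.05 s dynamic simulations at dt = 1e-4 s — are the package's chosen
  desk-scale study conditions; every quantitative claim above is tied to
  them.

## 9. Known limitations

- Dynamics are per-axis decoupled; no inter-joint coupling, gravity, or
  contact mechanics beyond the grip-force solver's static balance.
- Surface fitting assumes height-field regions; trimmed-NURBS topology
  and B-rep kernels are out of scope (solid export is a stitched mesh).
- The scanner emulator's noise is i.i.d. Gaussian along the normal;
  real structured-light error fields are spatially correlated.
- Carpal bones are simplified compact blobs fixed in a block; wrist
  kinematics are not modelled.
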