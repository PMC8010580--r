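---
title: "Ion-arc planning and radiobiology in hadronarc: models, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-arc planning and radiobiology in hadronarc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hadronarc` simulates spot-scanning hadron arc (SHArc) treatments — full
360-degree rotational delivery of a single-energy ion beam — against
conventional static single- and multi-field particle plans, for protons,
helium-4 and carbon-12 ions on cylindrical water phantoms. It asks the
questions a treatment-planning study asks: can a monoenergetic arc cover a
deep-seated target at prescription, where does the dose-averaged LET
concentrate, what does an organ at risk next to the target receive, and how
much tumor control is lost when the target core is hypoxic.

This vignette documents the models, their parameters, the numerical choices,
and what the package's synthetic scenarios can and cannot say about real
treatments.

## The beam model

Pencil-beam physics tables are built from first principles rather than from a
measured beam database.

* **Stopping power and range.** Bethe stopping power in water with mean
  excitation energy I = 75 eV and the Barkas effective charge
  Zeff = Z(1 − exp(−125 β Z^(−2/3))); no shell or density corrections. Below
  1 MeV/u the stopping power is held constant, which affects only the last
  ~0.1 mm of track. Ranges come from numerical integration of A/S(E); they
  satisfy the A/Z² inter-ion scaling to within 2%. A 150 MeV proton ranges
  ~158 mm, matching standard range tables to a few percent — adequate, since
  the study's energy-selection tolerance is ±4%.
* **Depth dose.** The central-axis integrated depth dose per primary is the
  stopping-power term broadened by Gaussian range straggling
  (σ_R = k·R^0.935/√A with k set so σ_R = 1.2 mm at R = 100 mm for protons),
  attenuated exponentially by nuclear interactions (interaction lengths
  850 / 450 / 255 mm for p / He / C), plus fragment build-up groups that grow
  linearly to the peak and decay exponentially beyond it (one He-like group
  for helium; an He-like + H-like pair for carbon; a short-ranged
  secondary-proton group, truncated at the peak, for protons). Carbon tables
  add a 1.5 mm Gaussian ripple-filter spread. Fragment groups carry fixed
  representative energies, so their LET and radiation quality are constant
  with depth — a deliberate single-group simplification of the true fragment
  spectra.
* **End-of-range resolution.** The pristine depth grid is refined
  logarithmically over the last 3 mm of range, where the stopping power
  changes by an order of magnitude inside one voxel. Without this the
  dose-averaged LET at the Bragg peak is underestimated by ~40%: the
  near-stopping primaries carry a large share of the local dose at very high
  LET, and a uniform 0.5 mm grid simply misses them.
* **Lateral spread.** σ(z) = sqrt(σ0² + σ_MCS(z)²) with initial spot sigmas
  5.1 / 3.4 / 2.5 mm (p / He / C) at isocenter and a multiple-Coulomb-
  scattering term c·z·(z/R)^0.8 (c = 0.025 / 0.013 / 0.008). Protons spread
  visibly more than carbon at equal fractional depth, which is what makes the
  proton arc's penumbra and OAR sparing worse.

The table builder guarantees the structural invariants the rest of the
pipeline relies on: component dose fractions sum to one at every depth, the
primary track LET is non-decreasing up to its maximum, and the stored R80 is
reproduced by rebuilding the table.

## Effective dose: the mMKM

Per-fraction RBE-weighted dose uses the modified microdosimetric kinetic
model with domain radius R_d = 0.3 μm, nucleus radius R_n = 3.6 μm and photon
reference (α/β)x = 2 Gy (α_x = 0.05 Gy⁻¹, β_x = 0.025 Gy⁻²). The
saturation-corrected dose-mean specific energy per event, z1D*, is computed
from a Kiefer–Chatterjee amorphous track: core radius 0.0116·β μm, penumbra
radius 0.0616·E^1.7 μm, 1/r² penumbra normalized so the track integral equals
the LET. The domain-averaged specific energy z(b) at impact parameter b is an
arc-overlap quadrature of the radial dose, and

z1D* = z0² ∫ (1 − exp(−z(b)²/z0²)) b db / ∫ z(b) b db,

with the saturation parameter z0 = (R_n/R_d)² / sqrt(β_x (1 + (R_n/R_d)²))
≈ 75.6 Gy determined by the nucleus radius. This construction vanishes with
LET, rises with LET at fixed charge, and decreases again at very high LET
(overkill), which is the qualitative behaviour the model must have. Then
α_ion = α_x + β_x·z1D* and β_ion = β_x (the standard quadratic-term choice,
with α_x as the zero-LET intercept; both are configuration defaults, not
refits). z1D*(ion, E) is tabulated on 45 log-spaced energies in 1–1000 MeV/u
and spline-interpolated.

Mixed fields mix dose-weighted: ᾱ = Σ d_j α_j / D and √β̄ = Σ d_j √β_j / D.
Effective dose is the positive root of α_x·x + β_x·x² = ᾱD + β̄D². Because
every field component shares β_ion = β_x, the normoxic β̄ is exactly β_x; the
hypoxic one is not (each component divides β by its own HRF²).

## The hypoxia reduction factor

Radio-resistance under hypoxia is a dose-modifying factor on the LQ
parameters. For photons HRF_ph(pO2) = (mK + pO2)/(K + pO2) with m = 2.94 and
K = 0.129% O2: m-fold resistance at anoxia, none at full oxygenation. For
ions the protection of hypoxic cells shrinks with ionization density,
parameterized by the radiation quality RQE = (Zeff/β)²:

HRF_ion(RQE, pO2) = (a·HRF_ph(pO2) + RQE^γ) / (a + RQE^γ),

with a = 2.988e6 and γ = 2.169. The half-way point sits at RQE = a^(1/γ) ≈
970 — between the Bragg-peak RQE of protons (~40) and carbon (~10⁴), which is
why only carbon meaningfully defeats hypoxia at the peak. Hypoxic LQ
parameters are α/HRF and β/HRF², applied per field component with the
component's own RQE; the LQ-based inverse (the iso-effect dose ratio at fixed
survival) recovers the applied HRF exactly at any survival level, a property
the tests enforce to 1e-10. Δ_OER,RBE = D_RBE / D_OER,RBE summarizes the
effective-dose loss per voxel.

## Scenarios

Case A is a water cylinder (H = 200 mm, r = 100 mm) with a coaxial
cylindrical target (H = 60 mm, r = 30 mm) at isocenter and an r = 5 mm core
used for LET statistics. Case B adds a cylindrical OAR (r = 10 mm, H =
60 mm — dimensions are the package's own choice, the study prints none) on
the +x side with a 5 mm surface gap. The hypoxia map assigns 9
logarithmically spaced pO2 levels from 5% (outer ring) to 0.25% (r ≤ 5 mm
core) over equal-width radial shells between r = 30 and r = 5 mm, and 21%
outside the target: the log spacing is read as applying to the levels, the
shells being equal-width in radius. The core is given the target's full
height; its volume is then (5/30)² ≈ 2.8% of the target.

Grids keep only voxel centers inside the phantom circle, stored as (in-plane
point × axial slice) matrices. Scenario generation is deterministic.

## Planning

Spots cover the target's beam's-eye-view projection plus one spacing of
margin, at 4.8 / 2.4 / 2.4 mm lateral spacing for p / He / C. SHArc uses 360°
in 2° steps with a single energy whose R80 equals the 100 mm isocenter depth
(118.14 / 118.51 / 218.52 MeV/u nominally; the analytic beam model inverts to
within ~3% of these). A subarc variant modulates R80 by ±6 mm in 2 mm steps
over 14° subarcs. Static 1F/2F/3F plans use the conventional 90°, 0°/180°
and 0°/90°/180° configurations **with an energy stack** spanning the target
depth extent (layer spacing 6 / 4 / 4 mm): a single-energy static field
cannot cover a 60 mm-deep target, and the clinically meaningful static
comparator places its highest LET at the distal edge, which only a stack
reproduces. This is a deliberate design choice for the static reference
plans.

The optimizer minimizes quadratic penalties on per-fraction effective dose:
target coverage between 97% and 106% of the 3 GyRBE prescription plus a weak
uniform-dose anchor at prescription inside that band, a lateral fall-off
shell interpolating from prescription at the target surface to 0.25 GyRBE at
5 mm, a 0.5 GyRBE OAR maximum (case B) and a weak 0.25 GyRBE normal-tissue
objective on a seeded sample of normal-tissue columns. The
effective-dose dependence is nonconvex, so the mixed-field ᾱ of every
objective voxel is frozen per outer iteration, objectives are converted to
per-voxel physical-dose bounds, and the quadratic subproblem is solved by
projected-gradient descent with a curvature-matched step and backtracking
(accepted iterates never increase the objective). Initialization is uniform
weights scaled to the mean target physical-dose requirement; ᾱ is
scale-invariant, which makes that starting point well-defined.

Dose influence is never materialized for full plans: the lateral Gaussian
kernel is separable, so one angle's dose is Gu·W·Gvᵀ per depth-σ bin
(σ(depth) quantized into 6 bins), giving matrix-product forward and adjoint
passes. Hand-built influence matrices are supported for fixture problems and
are how the optimizer contract (exact single-spot recovery, monotone
descent) is tested.

Clinical minimum fluence per spot (5.8e5 / 1.3e5 / 1.5e4 particles for
p / He / C) is enforced by staged pruning: spots below 1/3, 2/3 and then the
full threshold are removed in three rounds, the surviving weights rescaled to
conserve fluence, and one re-optimization pass run per round; the final round
optimizes with the threshold as a hard floor in the projection, so delivered
plans satisfy weight = 0 or weight ≥ threshold exactly. Finished plans are
renormalized — all weights scaled by one factor so the mean target effective
dose equals the prescription, the usual clinical monitor-unit convention;
the mixed-field ᾱ is scale-invariant, so this rescale is exact and cheap.

## Evaluation

DVH and LET-volume histograms are cumulative (V(x) = volume fraction ≥ x;
default bin 0.01 GyRBE), Dx% their inverse. LET_D per voxel is the
dose-weighted mean over every spot and field component. Localization metrics
(where LET_D,max sits) consider only voxels above 10% of the prescription
effective dose so that near-zero-dose voxels cannot define maxima.

TCP follows the Poisson voxel model TCP = Π exp(−S_i^n v_i p) over target
voxels with clonogen density p = 1e4 cells/mm³ and the actual voxel volume;
n = 10 fractions of the 3 GyRBE plan is the package default (the fraction
number is a free choice here; TCP50 is reported as a total effective dose so
shifts are comparable across n). TCP50 scales the per-fraction dose at fixed
fraction number (fraction-size scaling; the alternative of scaling n was
rejected to keep the LQ quadratic term consistent) and brackets TCP = 0.5 by
root finding; hypoxic TCP uses the per-voxel hypoxic mixed LQ parameters,
and both hypoxic and normoxic TCP50 are expressed on the normoxic
RBE-weighted dose axis.

## Problem sizes and numerical choices

The package's study-resolution runs use 2 mm voxels on the central ±10 mm
slab of the geometry (`slab_half_height = 10`), 3 outer re-linearizations and
~20 inner iterations; the full 200 mm grid is available through the same
interface. The slab is the package's standard evaluation domain for the
cylindrical cases: all structures are translation-invariant over the central
60 mm, so slab metrics (mean target dose, core LET percentiles, OAR maxima)
equal their full-height counterparts away from the target's axial ends,
while end effects (the target's axial dose fall-off) are deliberately out of
view. Unit tests use 4 mm voxels and ±8 mm slabs.

Other numerics: beam tables use 0.5 mm depth grids (log-refined at end of
range); σ(depth) quantization uses 6 bins, which perturbs individual pencil
kernels by well under the 2% normalization tolerance the tests enforce;
z1D* quadratures use 140 impact parameters × 160 radial nodes; R80 inversion
brackets around the CSDA-based estimate and solves to 1e-4 relative;
zero-dose voxels propagate as NA in LET_D and are excluded (and counted) in
Δ_OER histograms; TCP is computed in log space.

## What the synthetic scenarios do and do not show

The phantom study reproduces the mechanism-level claims: monoenergetic arcs
concentrate the Bragg peaks — and therefore LET_D and the hypoxia
protection — in the target core, while static fields pile LET at their distal
edges; carbon benefits most because its peak RQE crosses the HRF fall-off.
The scenarios are homogeneous water with symmetric targets: nothing here
validates range accuracy in heterogeneous anatomy, robustness to setup/range
error (a single-energy arc is known to be sensitive to both), deliverability
(gantry-synchronized spill structure), or the absolute RBE scale, whose
model and tissue-parameter uncertainty is on the order of 20-30% for carbon.
Fragment spectra are one- or two-group effective models: fragment tails have
the right magnitude and low radiation quality, but no isotope resolution.
Passing tests therefore demonstrate internal consistency and
order-of-magnitude physical fidelity, not clinical accuracy.

## Known limitations

* Static reference plans are idealized IMPT stacks without clinical energy
  constraints or absolute spot-number limits.
* The proton halo (nuclear secondaries at large radius) is off by default;
  proton OAR doses in tight geometries are optimistic.
* The hypoxia model's constants (m, K, a, γ) are taken as given, not refit.
* One fraction scheme (n = 10) is the TCP default; absolute TCP values are
  illustrative, only shifts and orderings are study endpoints.
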