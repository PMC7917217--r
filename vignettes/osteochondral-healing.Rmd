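---
title: "Mechanoregulated simulation of osteochondral defect healing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanoregulated simulation of osteochondral defect healing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ocdheal` simulates the repair of a focal osteochondral defect — a lesion
through the articular cartilage into the underlying bone — in an axisymmetric
finite-element model of a knee femoral condyle, and lets scaffold material
stiffness and strut architecture be screened for their effect on the
mechanics-dependent healing outcome.

One simulated iteration corresponds to one day and couples two sub-models:

1. **Mechanics.** A staged axisymmetric Biot poroelastic analysis of the
   condyle: a 1 s soil-loading step ramps a 0.637 MPa pressure (800 N over
   the 20 mm-radius proximal surface) followed by a 0.5 s consolidation step
   with zero pore pressure on the defect mouth. Healthy cartilage is
   compressible neo-Hookean (C10 = 2.14 MPa, D1 = 0.399), the meniscus is a
   transversely isotropic poroelastic ring (circumferential modulus 100 MPa,
   radial/axial 0.5 MPa), the tibial plateau a rigid line; all contacts are
   frictionless normal-penalty pairs. Per defect element the octahedral shear
   strain γ (%) and seepage fluid speed v (mm/s) are sampled as the
   element-wise maximum over the consolidation increments.
2. **Mechanoregulation + cell dynamics.** The stimulus S = γ/a + v/b
   (a = 3.75 %, b = 3×10⁻³ mm/s) classifies each of the 40 × 40 defect
   lattice elements into bone resorption (S < 0.01), bone (0.01 ≤ S < 1),
   cartilage (1 ≤ S < 3) or fibrous tissue (S ≥ 3). Four continuous cell
   populations (MSCs, osteoblasts, chondrocytes, fibroblasts) evolve daily:
   MSC diffusion (tissue-dependent coefficients, granulation 0.80 down to
   bone/scaffold 0.01 mm²/day), 5 %/day S-dependent differentiation, 5 %
   favored-phenotype mitosis, 15 % disfavored apoptosis, constant 15 % MSC
   proliferation, and 10 % osteoblast loss under the resorption fate.
   Elements hold at most N_max = 100 cells (scaffold struts N_max·P/100 for
   porosity P).
3. **Homogenization.** Each defect element's poroelastic properties (E, ν,
   hydraulic conductivity, void ratio, grain bulk modulus) are the
   space-fraction-weighted arithmetic means of its constituents (empty + MSC
   space = granulation; osteoblast = cancellous bone by default; scaffold
   fraction = scaffold material), feeding the next day's solve.

```{r}
library(ocdheal)
cfg <- simulation_config("empty_marrow", days = 50,
                         control = mech_control(backend = "full"))
res <- run_healing(cfg)
res$series[50, ]      # final tissue composition, % of the defect
table(res$fate)       # day-50 fate map
```

## Geometry parametrization

Only two geometric quantities are fixed by printed values: the defect
(5 mm radius × 5 mm depth, abutting the symmetry axis) and the load
calibration, which pins the loaded top radius at 20 mm
(0.637 MPa × π·20² ≈ 800 N). The remaining outline exists only graphically
in the source model, so it is parametrized with defaults chosen once:

* **Layers.** Cartilage 4.25 mm, subchondral plate 0.5 mm (the defect wall
  is cartilage over most of its depth, as in the source model's defect-region
  sketches). The defect abuts cancellous bone over its base and the proximal
  0.25 mm of its lateral border — these 41 lattice elements are the marrow
  MSC source.
* **Articular recess and mouth conformity.** The articular surface is flat
  to r = 12 mm and recedes by 1 mm (cosine profile) toward the rim, where
  the meniscus ring (r = 17–23 mm) fills the gap down to the tibial
  plateau. The fresh granulation filling the defect is given a 0.1 mm
  conformity gap against the plateau: the soft repair surface only becomes
  load-bearing once the joint closes that gap, so early load flows around
  the defect through the intact cartilage annulus. The cartilage thickness,
  recess and conformity gap were calibrated once against the reported
  day-1/day-5 strain environment of the empty defect (γ around 10 % over
  the mid defect, around 20 % distally, below 1 % proximally, a high peak
  at the defect–cartilage–subchondral interface, and a
  resorption-permissive spot at the proximal-central base) and then frozen;
  they were not revisited against outcome quantities.
* **Strut defaults.** Ring radii 1.5/2.625/3.875 mm with 0.25 mm width
  (lattice-aligned) give a total annular cross-section of 12.57 mm², chosen
  so the axial stiffness of the scaffold structure at E = 0.1/10/1000 MPa
  and of the biphasic variant lands on the published 0.25/24.5/2445/50 N/mm
  values (within 3 %) via K = E·A/L.

## Numerical choices

* **Discretization.** 8-node serendipity displacement elements with bilinear
  corner pore pressures (2×2 reduced Gauss integration), the stated mixed
  element pair of the source model; the defect is an exact structured
  40 × 40 grid at 0.125 mm seed (1600 elements), coarsening geometrically to
  at most 0.8 mm elsewhere. The MSC diffusion sub-problem uses 4-node
  bilinear elements on the same lattice, zero-flux boundaries, backward
  Euler with 10 sub-steps/day; the marrow supply enters solely through the
  daily source-replenishment rule.
* **Time stepping.** Backward Euler throughout; 4 sub-increments for the
  loading ramp, 10 for consolidation, with automatic bisection of a
  sub-increment when Newton fails to converge.
* **Nonlinear solve.** Modified Newton with a lazily refreshed sparse LDL'
  factorization (the sign-flipped Biot system is symmetric quasi-definite),
  refreshed whenever the contact active set changes; backtracking line
  search on the residual norm and a 0.5 mm per-iteration displacement cap
  guard the very compressible neo-Hookean cartilage (K = 2/D1 ≈ 5 MPa)
  against overshoot. Penalty stiffness 10⁵ MPa/mm keeps contact penetration
  below ~10⁻³ mm.
* **Unit conventions.** γ is consumed in percent (a is printed as 3.75 %);
  v is the seepage velocity |q|/n (Darcy flux over porosity n = e/(1+e)).
  Hydraulic conductivity (mm/s) converts to mobility with the unit weight
  of water 9.81×10⁻⁶ N/mm³.
* **Biot terms.** α = 1 − K_dr/K_grain clamped to [0, 1] and storage
  (α − n)/K_grain clamped at ≥ 0: the subchondral plate's printed moduli
  make α marginally negative, and the scaffold's K_grain = 0 is read as
  "grains not limiting" (α = 1, no storage). Both readings are flagged here
  because the printed constants do not resolve them.
* **D1 units.** The hyperelastic compressibility constant is printed with
  pressure units; the conventional 1/MPa reading (D1 = 0.399 → bulk modulus
  ≈ 5 MPa) is implemented. This makes healthy cartilage strongly
  compressible, which the solver safeguards (line search, step cap) were
  added to handle.

## Design choices the source leaves open

* **Intra-day ordering** is diffuse → differentiate → mitosis/apoptosis →
  replenish (configurable via `step_day(order =)`). The workflow figure of
  the source model does not resolve it; placing replenishment last makes
  the marrow boundary exactly full at the start of each day.
* **Resorption fate** applies only the 10 % osteoblast loss; chondrocytes
  and fibroblasts in such elements neither divide nor apoptose.
* **Mitosis at capacity** is clipped: a favored phenotype in a full element
  keeps only what fits, and MSC proliferation is clipped to the remaining
  capacity.
* **Strut capacity** N_max·P is read with P as a percentage (P = 50 → 50
  cells/element), the only reading that keeps strut capacity below N_max.
* **Bone row.** Osteoblast-occupied space takes the cancellous-bone
  property row (the defect sits in cancellous bone); configurable to the
  subchondral row.
* **Sampling instant** for γ and v is the element-wise maximum over the
  consolidation increments, following the tradition of the stimulus model
  family; end-of-load and end-of-consolidation sampling are available in
  `mech_control()`.
* **Quantification** is the unweighted mean of per-element space fractions
  (axisymmetric 2πr volume weighting is computed as an alternative).

## What the surrogate backend does and does not show

`mech_control(backend = "surrogate")` with `surrogate_field()` drives the
cell model from analytic γ/v fields, bypassing the FE solve. It exercises
diffusion, differentiation, capacity handling and the composition
bookkeeping exactly, and admits closed-form checks (constant-fate runs
follow a scalar recursion). It cannot show anything about the strain
redistribution feedback — the defining coupling of the full model — nor
about contact or consolidation physics.

## Verification

The mechanics kernel is checked against closed forms: uniaxial elastic
compression (γ_oct = (2√2/3)(1+ν)σ/E, exact for the element), Terzaghi
one-dimensional consolidation (analytic series, < 2 % at mid-height), and
zero-load null fields. Diffusion conserves total cell number to solver
precision (the element-to-node projection pair is adjoint); a cell-centred
explicit finite-difference oracle reproduces the 5-day MSC invasion front.
The scaffold FE stiffness matches the series/parallel spring closed form,
and the coupled runs are deterministic and bitwise resume-equivalent.

Problem sizes used in the shipped test-suite runs: the full condyle mesh is
about 4600 elements (14 000 nodes, 32 000 unknowns), solved once per
simulated day; healing runs in the acceptance checks use 50 or 100
iterations; verification columns use 20–160 elements.

## Known limitations

* The condyle outline, meniscus wedge and strut cross-sections are
  parametrized reconstructions calibrated to printed anchor values, not
  traced geometry; absolute strain magnitudes inherit that uncertainty.
* The defect lattice resolution is fixed by the cell model (1600 elements at
  0.125 mm). Halving the seed (with the surround held fixed) still shifts
  the defect-average γ by roughly 15%: the shear boundary layers along the
  soft-tissue walls are only marginally resolved, so stimulus values of
  borderline elements — and through the thresholds, some fate calls — carry
  a resolution uncertainty of that order.
* Small-strain kinematics everywhere except the hyperelastic cartilage;
  defect strains above ~30 % are outside the theory's comfort zone even
  though the stimulus thresholds only need the ordering.
* Contact is nodal penalty on conforming interfaces; no large sliding.
* Cell counts are deterministic continuua; no stochastic agent variant.
* One mechanics solve per day ignores diurnal load history.
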