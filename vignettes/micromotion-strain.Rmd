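---
title: "Modeling micromotion-induced brain strain around intracortical probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling micromotion-induced brain strain around intracortical probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical problem

Chronically implanted intracortical microelectrodes move relative to the
surrounding brain tissue by 1--25 µm with every heartbeat, breath and head
movement. The resulting strain in the peri-implant tissue is widely regarded
as a driver of the glial scarring that degrades recordings over months. The
strain cannot be measured in vivo at these scales, so it is estimated with
finite-element models of the probe--tissue interface.

`micromotionfem` is a self-contained implementation of such a model: a
rectangular probe shank (a Michigan-style electrode, 1125 × 125 × 25 µm, or
a 63 µm-thick compliant variant) embedded in a 1500 × 1500 × 1500 µm block
of brain tissue, loaded by a prescribed tangential displacement of the probe
top face, solved as static small-strain linear elasticity, and postprocessed
into the quantities the field compares across probe materials: the maximum
Von Mises strain in the tissue, its location along the shank, values
normalized to a stiff silicon baseline, and strain-decay profiles away from
the probe surface.

## Model and assumptions

Brain tissue is modeled as homogeneous, isotropic and linear elastic
(E = 6 MPa, ν = 0.45 by default). This is a deliberate simplification:
cortical gray matter is viscoelastic and nonlinear, but for comparative
statics across probe materials the linear model is the accepted baseline,
and for small strains the discrepancy with nonlinear laws is reported in
the literature to be on the order of a percent. Note that the *linearity*
of the model means every computed strain scales exactly with the applied
displacement; strains larger than a few percent reported at 10--20 µm
displacements are linear extrapolations, not physically valid large-strain
solutions.

The probe is a rectangular shank of one of four materials
(`material_catalog()`):

| material | E (MPa) | ν | note |
|---|---|---|---|
| silicon | 2×10⁵ | 0.278 | "stiff" baseline |
| polyimide | 2.7×10³ | 0.33 | flexible polymer backbone |
| PVAc-NC | 12.7 | 0.3 | post-insertion (softened) state |
| hypothetical | = brain E | 0.33 | mismatch-free reference |
| brain | 6 | 0.45 | tissue |

PVAc-NC is a polyvinyl-acetate cellulose-nanocrystal composite that is stiff
(5.2 GPa) during insertion and softens to 12.7 MPa in situ; only the
softened state is simulated (the pre-insertion constants are catalogued for
reference).

**The brain-modulus ambiguity.** Sources for this configuration state the
brain modulus both as 6,000 kPa (6 MPa) and as 6 kPa in different places,
and tie the "hypothetical" probe modulus to it. We default to 6 MPa and
keep both the brain modulus and the hypothetical-probe coupling
configurable (`brain_E` in `case_config()`), so either reading can be run;
nothing in the pipeline depends structurally on the choice.

**Contact** between probe and tissue is bonded (no slip, no separation),
realized exactly by a conforming mesh in which probe and tissue share the
interface nodes.

**Boundary conditions.** The four perimeter edges of the tissue bottom face
are fixed in all components; a displacement `d` along +x (across the probe
width, perpendicular to the shank axis) is prescribed on every node of the
probe top face, with the other two components left free. Displacements
outside the 0--60 µm micromotion range trigger a warning. The probe top
face is flush with the tissue top surface and the probe is fully embedded
(tip at 1125 µm); tissue depth and embedment are exposed in
`domain_spec()` because published figures do not state them numerically —
the defaults make the tissue block a symmetric 1500 µm cube.

## Discretization

The all-box geometry is meshed with a deterministic graded tensor-product
grid of 8-node (trilinear) hexahedra. Grid lines are placed on every probe
boundary; element size is `h_near` (default 4 µm) at the probe--tissue
interfaces and grows geometrically (`ratio`, default 1.3) away from them up
to `h_max` (default 60 µm), with at least 3 (by default 8) elements through
the probe thickness and aspect ratios bounded by 20. Identical parameters
produce a bit-identical mesh. The defaults give 117k elements for the
25 µm probe and 140k for the 63 µm probe over the full domain — the
resolution band at which the production runs are reported.

Tetrahedral meshes are common for this geometry in commercial tools; we use
structured hexahedra because they make the meshing dependency-free and
reproducible and, at matched resolution, give comparable strain fields.

**Near-incompressibility.** At ν = 0.45 trilinear hexahedra lock
volumetrically. The element therefore uses the mean-dilatation B-bar
treatment: the volumetric rows of the strain-displacement matrix are
replaced by their element average, with full 2×2×2 Gauss quadrature on the
deviatoric part. The distorted-mesh patch test (constant-strain
reproduction to 1e-10) passes with B-bar, which guarantees consistency.

**Quarter-domain symmetry.** Under the centred geometry and tangential
load, the solution is mirror-(anti)symmetric in x and z: `u_y = u_z = 0` on
the x = 0 plane and `u_z = 0` on the z = 0 plane. Case runs therefore solve
the quadrant x ≥ 0, z ≥ 0 on exactly one quadrant of the full grid (4×
fewer unknowns); the test suite checks quarter and full solutions agree to
solver precision. `symmetry = "none"` forces the full domain.

**Solver.** Dirichlet dofs are eliminated; the reduced symmetric
positive-definite system is factorized with supernodal sparse Cholesky
(CHOLMOD via the Matrix package), which is deterministic; a
Jacobi-preconditioned conjugate-gradient path (tolerance 1e-8) is available
as a cross-check. Relative residuals of the direct path are ~1e-13.

## Strain postprocessing

Strain tensors are evaluated at element centroids from the displacement
gradient, **without nodal averaging**: averaging smooths exactly the local
maxima the study compares, and the smoothing radius would become an
uncontrolled parameter. Commercial postprocessors typically report
nodal-extrapolated, averaged values; their maxima can differ substantially
from centroid maxima on the same field (see *Reproducibility limits*).

The comparison metric is the Von Mises (equivalent) strain
$$\varepsilon_{eq} = \frac{1}{1+\nu_{eff}}\sqrt{\tfrac12\left[(\varepsilon_1-\varepsilon_2)^2+(\varepsilon_2-\varepsilon_3)^2+(\varepsilon_3-\varepsilon_1)^2\right]}$$
over principal strains. The effective Poisson ratio is a reporting
convention, not physics; we default to each element's material ν (0.45 in
tissue), the common commercial convention, and expose `vm_nu_eff` because
reported reference values depend on this unstated choice.

Reported maxima are taken over **tissue elements only**; probe-interior
strains are excluded. The location of the maximum is classified by thirds
of the embedded length (top / mid / tip), with raw coordinates always
reported alongside so the rule is auditable.

Strain profiles sample the field along a line perpendicular to the probe
thickness face (+z) at three section heights (tip, mid-shank, tissue
surface), reporting per-5 µm-bin maxima over the tissue elements the line
crosses; mid and top sections start at 62.5 µm from the shank axis.
`decay_span()` reports the distance at which a profile falls below a
fraction (default 1%) of its probe-adjacent value.

## Mesh-sensitivity protocol

`run_sensitivity()` re-solves a case at 1 µm on a ladder of `h_near` values
and tabulates the strain at four fixed monitoring points — two 10 µm off
the tip interface, two 10 µm off the top interface — plus the global
tissue maximum. Convergence (`converged_at()`, default 5% for the stiff
probe, 2% for the compliant) is judged **at the monitoring points only**:
the global maximum sits at re-entrant probe corners where linear
elasticity is singular, so it grows without bound under refinement and is
recorded as a trend, never used as a stopping criterion.

## Verification fixtures

Because the production geometry has no analytic solution, the solver is
gated by four fixtures with exact references, generated in code
(`verify_all()`):

* **patch test** — arbitrary linear displacement imposed on the boundary of
  a deterministically distorted mesh; interior displacements and the
  constant strain tensor must be reproduced to 1e-10 (this catches
  integration and mapping errors; it caught a Jacobian-transpose bug during
  development);
* **uniaxial block** — homogeneous stretch with free lateral faces, exact
  at any ν including 0.45 (exercises B-bar);
* **cantilever** — prescribed tip deflection of a slender beam checked
  against the Timoshenko tip stiffness within 5%, plus the t³ bending-
  stiffness law within 10% (exercises the bending that drives the
  probe-thickness effect; requires near-unit element aspect ratios, hence
  the 80×8×4 default mesh);
* **bimaterial bar** — two blocks in series at ν = 0, exact strain
  partition ε₁/ε₂ = E₂/E₁ to 1e-8 (exercises two-material interfaces, the
  core of probe--tissue mismatch). ν = 0 is chosen to make the 1D oracle
  exact rather than realistic.

These fixtures emulate the *mechanics* the study relies on — they do not
emulate tissue heterogeneity, anisotropy, viscoelasticity, or the insertion
wound, so passing them validates the solver, not the biological fidelity of
the model.

## Reproducibility limits of the headline maxima

The acceptance script compares computed values against previously reported
results for this configuration. Two findings from this implementation
matter when reading those comparisons:

1. **The absolute maxima are not mesh-convergent.** Every reported maximum
   sits either at a re-entrant corner of the probe or at the perimeter of
   the loaded top face, where linear elasticity is singular. Their numeric
   values are therefore set by element size, element type and sampling
   convention (centroid vs nodal-averaged), none of which are stated with
   the reference values. Ratios between cases cancel some, but not all, of
   this sensitivity.

2. **Under these exact boundary conditions the tissue block is softly
   suspended.** With only the bottom-face perimeter edges fixed, a stiff
   probe drags the whole tissue block with it (the far wall moves ~0.3 µm
   per 1 µm of probe motion), so deep-tissue strains remain of order
   10⁻³ per µm of micromotion, and the largest strains concentrate where
   the loaded probe top meets the free tissue surface. Reference values of
   order 10⁻¹ per µm, with the maximum at the probe tip and decreasing
   strongly for compliant probes, are not reproduced by this model as
   specified; we verified this is robust to plausible re-readings of the
   setup (fully fixed bottom face, fixed side walls, load along the
   thickness direction, reduced load patches). The package reports what
   the stated model computes; the deterministic structure — exact
   linearity in d, invariance of the argmax location with d, strain decay
   away from the probe, stiff ≫ compliant adjacent to the tip — is
   reproduced and tested.

## Problem sizes and runtimes

Production case runs use the default mesh (117k/140k full-domain elements,
solved as ~30k-element quarter domains, ~100k unknowns; 10--25 s per case
on one core). The test suite and examples use a coarser study mesh
(h_near = 8 µm, ~33k full-domain elements) where only deterministic
structure, not absolute convergence, is being exercised; sensitivity
ladders in tests are coarser still. These sizes were chosen so a complete
verification cycle runs in minutes on a laptop core while production runs
stay within the resolution band stated above.

## Known limitations

* Linear kinematics: strains beyond a few percent are extrapolations.
* No viscoelasticity, poroelasticity, tissue heterogeneity or anisotropy.
* No insertion mechanics or pre-insertion PVAc-NC stiffness transition.
* Rectangular shank only (no tapered or pointed tips); sharp corners make
  absolute maxima mesh-defined (see above).
* Bonded contact only; no slip, separation or friction at the interface.
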