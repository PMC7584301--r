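---
title: "Modeling prophylactic foam dressings under compression and shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling prophylactic foam dressings under compression and shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(foamfea)
```

## The problem

Pressure injuries initiate in deep tissue near bony prominences, where
sustained mechanical deformation kills cells long before any surface damage
is visible. The sacrum in a semi-seated (45° head-of-bed, "Fowler's")
posture is the canonical worst case: body weight presses the sacral bone
toward the mattress while gravity drags the trunk caudally, so the tissue
between bone and support sees combined compression and shear. Prophylactic
silicone foam dressings are marketed to mitigate exactly this loading, and
finite-element analysis is the only way to see the internal tissue state
that sensors cannot measure.

`foamfea` implements that analysis as a reusable pipeline: a parametric
layered geometry (mattress, optional dressing, soft tissue with an embedded
bony prominence), a quasi-static nonlinear finite-element solver with
frictional contact, and a quantification stage that reduces the computed
strain-energy-density (SED) field to the exposure statistics used to rank
dressings — volume-weighted SED histograms, pooling at a 0.5 kPa damage
threshold, and percent-SED-reduction of each dressing against a no-dressing
control. A companion module identifies effective dressing moduli from
flat-punch indentation curves, and a synthetic-data module generates every
input with known ground truth.

## Constitutive models and parameters

Soft tissue is incompressible neo-Hookean in origin; we realize it as
nearly incompressible with the published constants G = 19.254 kPa and
K = 1919.022 kPa, which imply ν = 0.495. The energy density is the
classical compressible form

$$W = \tfrac{G}{2}(I_1 - 3) - G \ln J + \tfrac{\lambda}{2}(\ln J)^2,$$

whose small-strain limit reproduces the linear isotropic constants. No
mixed incompressible formulation is claimed; near-incompressibility is
handled at the element level (below).

The mattress is linear elastic (E = 50 kPa, ν = 0.3), the bone is either a
rigid displacement driver (default; it is ~10⁵ × stiffer than tissue, and
rigidity avoids conditioning problems) or linear elastic with E = 3.4 GPa,
ν = 0.36. The `linear_elastic` family is geometrically linear; all
finite-strain behavior lives in the neo-Hookean family. Strains in the
linear regions stay within a few percent in the packaged scenario, where
this distinction is immaterial.

Dressings are multilayer products homogenized to a single foam layer whose
small-strain Young's modulus equals the effective modulus measured by
indentation. Their porous character is represented by a compressible
neo-Hookean solid with a low foam Poisson ratio (default 0.1,
configurable): a 2% solid-volume-fraction foam deforms with essentially no
lateral coupling until densification, which the packaged load levels do
not approach. The solid fraction itself is carried as metadata only — the
printed data do not identify any further poroelastic constants
(permeability, fluid pressure), so a biphasic model would be
unidentifiable, and no volumetric cap rule could be calibrated either.

## Geometry

The default scenario is a 2-D plane-strain sagittal section: a 200 × 75 mm
tissue block over an optional dressing (per-dressing thickness, 150 mm
footprint) over a 200 × 75 mm mattress. The sacrum is replaced by a
parametric rounded capsule embedded in the tissue — tip radius 8 mm
(the stress-raising "tight radius" of the sacral apex), tip 15 mm above
the skin surface, body height 35 mm — so that tissue surrounds the bone
and rides along with it, as it does anatomically. The dressing is bonded
to the skin by construction (shared interface nodes: the no-slip bond is
exact and unconditionally stable), while the dressing–mattress interface
is a genuine frictional contact pair (μ = 0.4, a somewhat sticky
foam–foam interface).

Two depth parameters matter in 2-D:

* `tissue_depth` (250 mm) is the block's out-of-plane extent, used only
  when meshing in 3-D;
* `effective_depth` (80 mm) converts per-unit-depth plane-strain reactions
  to newtons. It represents the lateral extent over which the sacral load
  is actually transferred — roughly the width of the sacrum. Using the
  full block depth would spread the 40 N target over tissue that carries
  no sacral load and push the whole SED field an order of magnitude below
  the 0.05–1.0 kPa range in which tissue damage risk is assessed.

Both values, like the tip radius and cover thickness, were fixed once on
anatomical grounds when the reference scenario was frozen.

## Loading and solution

The load case prescribes a bone displacement along a direction 45° caudal
from the mattress normal, scaled by a safeguarded secant iteration until
the total mattress-base reaction reaches 40 N (tolerance 0.1 N). Each
displacement scale is reached by incremental load stepping (default 10
increments, automatic halving on nonconvergence, linear extrapolation of
the previous increment as predictor) with a full Newton solve per
increment.

Numerical choices worth knowing about:

* **Selective reduced integration.** The λ-term of the neo-Hookean energy
  is integrated at the element centroid only, the G-terms at 2 × 2 Gauss
  points. This is the mean-dilatation family: it relieves volumetric
  locking at ν = 0.495 while keeping the residual and tangent exact
  derivatives of a single well-defined element energy — so the tangent is
  consistent and symmetric, which the test suite verifies against finite
  differences.
* **Contact.** Node-to-surface penalty contact; the default normal penalty
  is 50 × the softer neighbour's modulus per master element length, the
  tangential penalty a tenth of that. Friction is elastic-stick with a
  return map onto the Coulomb cone; stick anchors are master *material
  points*, fixed during a load step and committed at convergence, which
  keeps the stick stiffness consistent. Two regularizations matter for
  robustness: the normal force activates through a C1 quadratic blend
  over the first 2 × 10⁻³ mm of penetration, and master normals are
  averaged at nodes and interpolated along segments. Both remove Newton
  limit cycles (from marginally active nodes and facet kinks
  respectively) without visibly changing transmitted tractions.
* **Convergence.** Relative residual 10⁻⁶ against the larger of the
  reaction and external force norms; backtracking line search accepting
  the first residual decrease; a watchdog aborts a stalled or cycling
  solve so the load ramp can cut the increment.

## Quantification

Per-element SED is the volume-averaged constitutive energy of the
converged deformation; distortional stress is the von Mises equivalent of
the Cauchy tensor (a Tresca-type maximum-shear option exists). The
volume-weighted histogram assigns each tissue element's reference volume
to the bin containing its SED; bins are 0.05 kPa wide so that the 0.5 kPa
damage threshold — the value above which animal studies report damage in
all experiments — is always a bin edge. (A 20-bin division of the
0.05–1.0 kPa range would put the threshold mid-bin, which is why the
packaged default is 19 bins of width 0.05.)

Pooled "area under the curve" is the rectangular sum
Σ (bin volume × bin width) over bins below / at-or-above the threshold,
and the comparison statistic is
`(AUC_control − AUC_dressing) / AUC_control × 100`. Pooling starts at the
0.05 kPa floor of the analysed range: volume below it belongs to the
quiescent bulk, and because uniform-width rectangular AUC over *all*
volume is identically bin-width × total volume, a floor is also the only
reading under which total reductions can be nonzero at all. Whether AUC is
taken on absolute volume or volume fraction does not change any reduction
percentage (the tissue volume is shared), and reference rather than
deformed element volumes are the default.

## Indentation analysis

The effective dressing modulus comes from the bonded-layer flat-punch
relation \(F = 2 a \kappa(a/t)\, E/(1-\nu^2)\, \delta\) with punch radius
a = 3 mm and a layer correction κ = 1 + 1.33 (a/t) + 1.33 (a/t)³
(tabulated and interpolated; κ = 1 selects half-space analysis). The slope
is fitted over the 5–25% compression window, below the large-strain
stiffening visible in real curves and above toe-region seating artifacts.
The conservative rule — run the model with the *minimum* modulus across
the 3 locations × 5 samples protocol — is `conservative_modulus()`.

The synthetic curve generator is the same forward relation sampled to 50%
compression with multiplicative Gaussian force noise (CV 3% by default,
consistent with the sample-to-sample variability such dressings show).
Generator and analysis share the forward model deliberately: round-trip
identifiability is a test, not an accident. What passing those tests does
*not* show is that the relation is the correct physical reduction for any
particular real dressing — rate effects, layer interactions and adhesive
borders are all outside the model.

## What the 2-D scenario can and cannot reproduce

On the packaged scenario all ten cases converge to the 40 N target
(|F| between 39.98 and 40.00 N), every dressing lowers the peak tissue
SED below the control's (1.72–1.78 vs 1.82 kPa), and the ≥ 0.5 kPa
exposure near the bone responds to dressing stiffness in the same order
as the published ranking: the stiffest foam reduces it most (+6.3%), the
softest least (−1.3%). Two published patterns are **not** reproduced,
and the package does not pretend otherwise:

* the 20–25% *total* SED reductions, and
* the uniformly large (29–38%) reductions of the ≥ 0.5 kPa pool.

The reason is dimensional, not a bug, and is worth stating precisely. In
plane strain a concentrated surface load produces stresses decaying like
1/r (Flamant), so the area where SED exceeds a fixed floor is dominated by
the load *resultant* — which is the same 40 N in every case — and barely
responds to how a dressing redistributes that load. Redistributing the
near-tip peak necessarily raises mid-range exposure elsewhere, and the
total pool can even move slightly against the dressing. In 3-D the decay
is 1/r², the same SED floor sits in the near field, and redistribution
shrinks every pool at once — which is what the published 3-D study found.
A 2-D sagittal model can match either the published SED operating range
or the reduction signs, not both; this package fixes the operating range
(control peak 1.82 kPa, the analysed 0.05–1.0 kPa band populated) and
reports the comparison statistics as computed: totals between −1.8% and
−14.4%, high-pool reductions between −1.3% and +6.3%. The sign
conclusion was confirmed mesh-converged at 2.6 × the default element
count. The corresponding acceptance check is expected to fail on the
sign pattern and is left failing; treating it as a calibration target
would mean tuning the study away from the conditions it is supposed to
emulate.

## Problem sizes and costs

The packaged mesh (`mesh_control()`) grades from 2 mm elements within
40 mm of the prominence axis (and 30 mm above the skin) to 8 mm at the
periphery, with at least two elements across every dressing: about 1350
elements and 2700 unknowns, solving one force-targeted case in roughly
40–60 s on one core. The full ten-case comparison runs in about 8–10
minutes. The test suite solves the suite once and reuses it across
checks; the mesh-refinement check re-solves the control at 1.5 × finer
sizing (~3000 elements) and asks the volume-weighted near-tip SED to move
by less than 5%.

## Limitations

Homogeneous isotropic tissue (no skin/fat/muscle layering, no anisotropy);
homogenized single-layer dressings; quasi-static loading without
viscoelasticity or poroelastic fluid flow; a parametric prominence rather
than subject-specific sacral geometry; plane-strain kinematics with the
dimensional consequences described above; and a coarse extruded 3-D mode
intended for geometry and volume studies only — the nonlinear solver and
contact are 2-D.
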