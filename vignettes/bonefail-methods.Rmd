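---
title: "From CT segmentation to simulated failure load: models and design choices"
author: "bonefail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CT segmentation to simulated failure load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bonefail)
```

## What the package computes

Automatic bone segmentations feed patient-specific finite-element (FE)
simulations that estimate the load at which a femur or vertebra fails.
`bonefail` implements that chain — CT pre-processing, quantitative-CT (QCT)
density calibration, voxel-based hexahedral FE with an
elastic–perfectly-plastic material, and failure-load extraction — together
with the experiment that motivates it: perturbing a segmentation by one or
two voxels of erosion or dilation and measuring how much the simulated
failure load moves. Everything runs on synthetic phantoms with known ground
truth, so each stage has an exact or closed-form oracle.

The full chain is

1. calibrate HU → density (g/cm³) on phantom rods of known equivalent
   density (`fitHuDensity`, `huToDensity`);
2. map density to Young's modulus with a bone-type-specific law
   (`densityToModulus`);
3. mesh the segmentation with one 8-node brick per voxel (`buildHexMesh`);
4. compress quasi-statically under displacement control
   (`applyAxialCompressionBC`, `solveNonlinear`);
5. read the failure load off the load–displacement curve (`failureLoad`).

`runFailurePipeline` executes 1–5; `runSensitivity` repeats them for the
five perturbation variants and `batchReport` aggregates bones with a
Friedman test and Dunn post-hoc comparisons against the reference
segmentation.

## The synthetic phantoms

`generateBonePhantom` voxelises analytic solids by a voxel-centre-in-solid
test, which makes expected voxel counts exactly computable by brute force.
The femur-like object is a cortical tube with a hemispherical head cap and a
marrow canal along the shaft; the vertebra-like object is a shell-plus-core
cylinder. Tissue classes take constant HU means (defaults: cortical 1200,
trabecular 300, marrow 0, soft tissue 40 — plausible CT values, all
configurable), optional osteolytic lesions replace intensities inside the
bone without touching the ground-truth mask, additive Gaussian noise is the
only acquisition artefact modelled, and calibration rods of known density
run alongside the bone. The default grid spacing is 0.78 × 0.78 × 0.67 mm,
a typical resampled clinical hip-CT voxel.

What the phantoms deliberately do **not** contain: trabecular
microarchitecture, beam hardening, scanner kernels, partial-volume blur
beyond voxelisation, or anatomically realistic femoral geometry (neck
angles, curvature). Tests passing on phantoms therefore demonstrate the
correctness of the *pipeline machinery* — calibration algebra, mesh
bookkeeping, constitutive model, criterion logic, ordering behaviour — not
clinical accuracy on real anatomy.

## Pre-processing

`resampleVolume` maps grids by centre-of-extent alignment
(`shape = round(extent/target)`, trilinear for intensities, strict
nearest-neighbour for masks). `splitAndFlip` cuts a bilateral volume at the
mid-gap between the two bone bounding boxes and mirrors the left half;
bones in `generateHipVolume` are placed symmetric about the voxel-lattice
mid-plane so mirror-identical specs are voxelwise-testable.
`normalizeIntensity` is a per-volume z-score — the one normalisation that
needs no population statistics.

`registerAffine` minimises the mean-squared intensity difference with a
three-level block-mean pyramid and BFGS. Three robustness measures proved
necessary and are defaults: (i) both volumes are pre-smoothed with a
separable [1 2 1]/4 kernel, because piecewise-constant phantoms otherwise
leave an interpolation-error floor at sharp interfaces that biases the
optimum; (ii) the coarsest level is initialised by an exhaustive search over
integer coarse-voxel shifts, which keeps BFGS in the global basin; (iii) the
12-parameter affine polish (finest level only) is accepted only if it beats
the translation-only fit, rejecting the degenerate "map everything to
background" minimum of the MSE metric. The transform maps reference-space
world coordinates into moving space (pull-back convention). Parameter
recovery is only well-posed on scenes that break the phantom's rotational
symmetry, so registration tests use a bone plus an off-axis rod with
soft-tissue margins wider than the applied shifts (content clipped at the
field-of-view edge biases any intensity metric).

## Segmentation stand-in and perturbation

The trained networks that produce automatic segmentations in practice are
out of scope here; `segmentBone` (threshold, cavity filling, minimum
component size) is the pluggable stand-in, and any externally produced
NIfTI mask can be substituted. On a noiseless phantom, thresholding midway
between soft tissue and trabecular HU reproduces the ground-truth mask
exactly, which is the property the tests pin down. `postprocessMask`
mirrors the usual island-removal clean-up (binary opening plus a component
size filter).

`perturbMask` is the study's variability model: iterated binary erosion or
dilation, 0–2 iterations, acting in voxel space with the 6-connected cross
by default so that "one pixel" is literal along each axis (the 26-connected
box is available; which kernel the original analyses used is not
documented, so both are offered).

## Density calibration and material laws

Calibration is an ordinary least-squares line from rod HU means to known
densities; negative calibrated densities clamp to zero. Two laws map
density to modulus:

* femur: \(E = 14900\,\rho_{QCT}^{1.86}\) MPa,
* vertebra: \(E = 3230\,\rho_{QCT} - 34.7\) MPa,

with \(\rho_{QCT}\) in g/cm³. Both are floored at `eFloor` (default
0.01 MPa): the vertebral line crosses zero near 0.0107 g/cm³, and
over-segmented soft-tissue voxels (density clamped to 0) must not create
singular elements — this is also what makes dilated masks nearly harmless
mechanically, soft voxels adding almost no stiffness or strength. Poisson's
ratio defaults to 0.3 (standard in bone FE). Plasticity is J2
(von Mises) perfect plasticity with yield stress \(\sigma_y = E\,\epsilon_y\)
per element and \(\epsilon_y = 1.5\%\) by default. For femurs the published
nonlinear constitutive curve is not reproduced in the source material, so
the femoral model uses the same elastic–perfectly-plastic law with a
configurable yield strain; this is a stand-in, stated as such.

## The finite-element solver

Meshing is one trilinear hexahedron per in-mask voxel with shared nodes,
element density copied from the voxel and modulus from the law; a
disconnected mask warns and keeps its largest component, so fragmenting
erosions still solve. The element uses 2 × 2 × 2 Gauss quadrature; its
stiffness block is symmetric PSD with exactly six rigid-body modes (tested
by eigenanalysis), and all elements share one unit-modulus block scaled by
each element's E.

Displacement is applied in increments (default 0.1% of bone height) to the
node layer within `layerMm` of the top of the mesh along the loading axis;
the bottom layer is the support. Two support modes exist:

* `"clamped"` — the support layer is fixed on all axes, matching the null
  displacement condition used in practice for the distal femoral diaphysis;
* `"pinned"` — the support is fixed axially with minimal lateral pins
  (3-2-1 rule), i.e. frictionless platens. Clamping suppresses the
  incompressible plastic lateral flow of short homogeneous columns and
  inflates their apparent strength, so the closed-form uniaxial oracles
  (elastic \(EA\delta/L\), plastic plateau \(\sigma_y A\)) and the
  constitutive-curve driver use pinned supports, where they are exact.

Equilibrium at each increment starts from the initial-stiffness (modified
Newton) iteration: the elastic stiffness is factorised once per mesh
(sparse Cholesky) and reused, with the radial-return mapping supplying the
exact internal force at each iterate. Because that iteration converges only
linearly, it is capped at 12 sweeps; if the residual is still above
tolerance the solver switches to full Newton steps with the algorithmically
consistent tangent of the return map
(\(D = K\,\mathbf{1}\otimes\mathbf{1} + 2G\,\tfrac{\sigma_y}{q_{tr}}
[P - \tfrac{3}{2 q_{tr}^2} s_{tr} s_{tr}^T]\) at plastic points),
assembled sparsely and refactorised per iteration, with a small diagonal
shift as a fallback for the tangent's deviatoric semi-definiteness.
Convergence requires the free-dof residual below 10⁻⁶ of the reaction-force
norm, with an overall cap of 200 iterations per increment (the linearly
convergent phase needs more than a pure Newton budget would); non-convergence
is an error reporting step and residual. Reactions are summed over the
driven nodes' axial components and reported positive in compression.

Failure is criterion-based: femurs take the maximum load over the simulated
range; vertebrae take the load at the step where applied displacement
reaches 1.9% of bone height (linearly interpolated between steps, an error
if never reached).

## The sensitivity experiment

`femurSensitivityCase` builds the study condition: a noiseless femur
phantom with geometry drawn per seed (outer radius 5–6.5 mm, cortex
1.8–2.4 mm, height 30–36 mm at 1.6 mm isotropic voxels — a reduced-scale
femur that keeps each mesh at roughly one to four thousand elements),
three calibration rods beside the bone, and the grid cropped flush to the
bone's axial extent. Three design choices deserve explanation:

* **Flush cropping.** If dilation can extend the mesh along the loading
  axis, the platen node layers (defined relative to each mesh's own extent)
  shift between variants, changing the free span and the effective contact
  and confounding the comparison; cropping flush makes dilation purely
  lateral, so every variant is loaded between the same planes and
  monotonicity of the failure load in added material follows from energy
  and limit-load arguments.
* **Pinned platens and a collapse-dominated regime.** The runs drive to 2%
  of bone height — several times the yield strain over the free span — so
  the failure load approximates the plastic collapse load of the weakest
  cross-section, a quantity insensitive to column length and end effects.
  Clamped ends would add frictional-confinement strength that depends on
  the variant's aspect ratio; frictionless platens remove that artefact.
* **No noise in these cases.** With noise the minimum cross-section along
  the free span becomes a random variable, and variants whose platen planes
  free one extra slice sample one extra draw of it, which can mask the
  sub-percent strengthening from a dilated soft ring. The noiseless cases
  isolate exactly the morphological effect under study. Noisy phantoms are
  exercised elsewhere in the suite.

Under these conditions erosion removes load-bearing cortical material and
collapses the failure load, while dilation adds a ring of soft-tissue
density whose floored modulus contributes almost nothing — the asymmetry
between under- and over-segmentation, and the ordering
FL(erode²) ≤ FL(erode¹) ≤ FL(none) ≤ FL(dilate¹), is asserted over ten
seeded geometries in the test suite.

## Metrics and statistics

Dice is `2|A∩B|/(|A|+|B|)` with two empty masks defined as agreeing.
The Hausdorff distance is computed between boundary-voxel centres in world
units — equivalent to the filled-volume definition for the maximum and far
cheaper; a percentile variant (e.g. HD95) is available but the default is
the true maximum, matching a "maximum error" reading. The Friedman test is
delegated to `stats::friedman.test` (midranks, tie-corrected chi-square)
with one added degenerate case — a completely tied matrix returns statistic
0 and p = 1, where the tie correction would otherwise produce 0/0 — and is
cross-checked in the tests against an independently coded rank formula.
Dunn's post-hoc comparisons are formed only against the reference column,
with Bonferroni adjustment over those k−1 comparisons (the original
analysis names no correction; Bonferroni over the presented comparisons is
the conservative reading).

## Numerical choices and degenerate inputs

* Voxel indices are 1-based throughout (R convention); world position is
  `origin + (index − 1) · spacing`, axis order (x, y, z), z cranio-caudal.
* Erosion treats out-of-grid voxels as background, so masks touching the
  grid edge erode there too; dilation cannot grow past the grid.
* Masks resample with nearest-neighbour only; intensity volumes default to
  trilinear with out-of-grid fill taken from the input's minimum.
* The BC node layers use strict inequalities, so a layer of exactly one
  voxel selects exactly the end plane of nodes.
* Zero-variance volumes cannot be normalised or registered; empty masks
  cannot be meshed or measured with the Hausdorff distance; erosion that
  empties a mask is an error, but inside `runSensitivity` a failed variant
  is recorded as an NA row and the study continues.
* Coincident boundary points are snapped to distance exactly 0 to keep the
  identity variant's HD at 0 despite floating-point cancellation.

## Problem sizes in the shipped tests

The suite and the acceptance script are sized for a single CPU: column
oracles up to 1000 elements, sensitivity femurs of roughly 1–4 × 10³
elements across ten geometries, registration scenes near 40³ voxels, 10⁴
Friedman replicates, and 10³ calibration-recovery replicates. These sizes
are the package's chosen study conditions; all scale up by changing the
specs.

## Known limitations

Small-strain theory without geometric nonlinearity or contact; a voxel
hexahedral mesh for vertebrae as well (the tetrahedral meshing used in some
vertebral workflows is approximated by ~1 mm voxel bricks of equal element
volume); perfect plasticity for femurs in place of an unpublished nonlinear
curve; a threshold segmenter in place of trained networks; phantoms without
trabecular structure. The sensitivity machinery itself is agnostic to all
of these — any better segmenter, mesh or law can be slotted in behind the
same interfaces.
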