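# bonefail

Segmentation quality propagates into biomechanics: when a femur or vertebra
is segmented from CT and fed into a finite-element (FE) simulation, every
voxel of over- or under-segmentation changes the predicted failure load —
the load in newtons at which the bone is declared to fail. `bonefail` is an
R package for quantifying that propagation. It implements the full
CT-to-failure-load chain and a sensitivity study that perturbs a
segmentation by one or two voxels of erosion or dilation and measures the
effect on the simulated strength, exercised end-to-end on synthetic
phantoms with known ground truth.

It is aimed at researchers in computational bone biomechanics and medical
image analysis who need a tested, self-contained reference implementation
of the simulation side of such studies.

## The model

Intensities are calibrated against in-scan phantom rods of known
equivalent density, giving QCT density ρ<sub>QCT</sub> (g/cm³) per voxel.
Density maps to Young's modulus by bone type:

* femur: E (MPa) = 14900 ρ<sub>QCT</sub><sup>1.86</sup>
* vertebra: E (MPa) = 3230 ρ<sub>QCT</sub> − 34.7

Each segmented voxel becomes one 8-node hexahedral element carrying its
voxel's density and modulus. The material is linear elastic–perfectly
plastic (small-strain J2 plasticity) with yield stress σ<sub>y</sub> = E ε<sub>y</sub>
and yield strain ε<sub>y</sub> = 1.5%. Axial compression is applied as an
incremental prescribed displacement on the top node layer with the bottom
layer supported; at each increment equilibrium is solved by modified-Newton
iteration on the factorised elastic stiffness, with consistent-tangent
Newton steps when plasticity makes that stall. Failure is the maximum load
over the simulation for femurs, and the load at 1.9% total height
reduction for vertebrae.

Around the solver sit the study's supporting stages: phantom generation
(femur- and vertebra-like objects, osteolytic lesions, calibration rods,
acquisition noise), pre-processing (resampling, bilateral splitting and
mirroring, affine co-registration, z-score normalisation), a threshold
segmentation stand-in with island-removal post-processing, morphological
perturbation (erode/dilate × 1–2, the variability model), Dice and
Hausdorff agreement metrics, and Friedman/Dunn statistics across bones.

## Worked example

One femur case of the sensitivity study: generate a phantom with known
ground truth and calibration rods, segment it automatically, then simulate
the failure load for the automatic mask and its four morphological
variants.

```r
library(bonefail)

cs   <- femurSensitivityCase(seed = 1)          # phantom + rods, geometry drawn per seed
auto <- segmentBone(cs$volume, huThreshold = 170, minComponentVoxels = 100)
cfg  <- pipelineConfig("femur", rodLayout = cs$rodLayout,
                       stepFrac = 0.005, maxFrac = 0.02, support = "pinned",
                       bcLayerVoxels = (cs$outerRadiusMm + 3.5 * cs$spacing) / cs$spacing)
runSensitivity(cs$volume, auto, cs$mask, cfg)
```

```
SensitivityReport (femur), reference FL 18343.8 N
 variant       dsc    hd_mm failure_load_N  abs_diff_N   pct_diff failed
  erode2 0.2731481 4.800000       67.71973 18276.04023 99.6308296  FALSE
  erode1 0.6448683 2.771281     3212.11683 15131.64313 82.4893215  FALSE
    none 1.0000000 0.000000    18343.75996     0.00000  0.0000000  FALSE
 dilate1 0.7682801 1.600000    18378.98650    35.22653  0.1920355  FALSE
 dilate2 0.6025848 3.200000    18420.71694    76.95698  0.4195268  FALSE
```

Reading the table: the noiseless automatic segmentation equals the ground
truth (`none`: Dice 1, zero Hausdorff distance, zero failure-load
difference). Eroding it strips the load-bearing cortical shell and the
failure load collapses by 82–99%; dilating it adds only soft-tissue-density
voxels, which are nearly inert mechanically, so the failure load rises by
well under 1%. This is the under- vs over-segmentation asymmetry the
sensitivity study is designed to expose. The calibration fitted from the
rods on this phantom recovers its generating line
(`rho = 0.001 * HU + 0`, r² = 1).

`batchReport()` aggregates such reports over many bones into mean ± SD per
variant plus a Friedman test and Dunn comparisons against the reference
segmentation.

## Layout

* `R/` — S4 classes (`CTVolume`, `BoneMask`, `HexMesh`, `SolveResult`, …),
  generators, pre-processing, segmentation, metrics, calibration, FE
  solver, pipeline.
* `tests/testthat/` — oracle-based unit and property tests per module plus
  the acceptance suite.
* `vignettes/bonefail-methods.Rmd` — the models, their assumptions, the
  numerical design choices, and known limitations.
* `inst/cli/bonefail.R` — thin command-line front end
  (`phantom`, `segment`, `perturb`, `metrics`, `run`, `sensitivity`).
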