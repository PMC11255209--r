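#' @import methods
#' @importFrom stats rnorm sd lm coef residuals pnorm quantile
NULL

## ---------------------------------------------------------------------------
## Voxel grids
## ---------------------------------------------------------------------------

#' Virtual parent of voxel-grid objects
#'
#' A 3-D scalar field on a regular, axis-aligned, possibly anisotropic grid.
#' World position of voxel (i, j, k) (1-based) is
#' \code{origin + (c(i, j, k) - 1) * spacing}, axis order (x, y, z) with z the
#' cranio-caudal direction.
#'
#' @slot data 3-D array of voxel values.
#' @slot spacing numeric(3), voxel edge lengths in mm, strictly positive.
#' @slot origin numeric(3), world coordinates (mm) of the centre of voxel
#'   (1, 1, 1).
#' @keywords internal
setClass("VoxelGrid",
  representation("VIRTUAL",
    data = "array", spacing = "numeric", origin = "numeric"))

.validVoxelGrid <- function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values")
  if (length(msg)) msg else TRUE
}
setValidity("VoxelGrid", .validVoxelGrid)

#' CT-like scalar volume
#'
#' Carries CT intensities (Hounsfield units), calibrated densities
#' (g/cm^3) or normalised intensities, together with the grid geometry.
#'
#' @slot units character, one of \code{"HU"}, \code{"g/cm3"},
#'   \code{"normalized"}.
#' @seealso [ctVolume()]
#' @export
setClass("CTVolume", contains = "VoxelGrid",
  representation(units = "character"))

setValidity("CTVolume", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@data)))
    msg <- c(msg, "volume data must be finite")
  if (length(object@units) != 1L ||
      !object@units %in% c("HU", "g/cm3", "normalized"))
    msg <- c(msg, "units must be one of 'HU', 'g/cm3', 'normalized'")
  if (length(msg)) msg else TRUE
})

#' Binary segmentation mask
#'
#' A 0/1 field aligned to a [CTVolume-class] (same shape, spacing, origin).
#'
#' @seealso [boneMask()]
#' @export
setClass("BoneMask", contains = "VoxelGrid")

setValidity("BoneMask", function(object) {
  v <- unique(as.vector(object@data))
  if (!all(v %in% c(0, 1)))
    return("mask values must all be 0 or 1")
  TRUE
})

#' Construct a CT-like volume
#'
#' @param data 3-D numeric array.
#' @param spacing numeric(3), voxel size in mm (default the study's median
#'   CT voxel size, 0.78 x 0.78 x 0.67 mm).
#' @param origin numeric(3), world position (mm) of the first voxel centre.
#' @param units intensity units; \code{"HU"} for raw CT.
#' @return A [CTVolume-class].
#' @examples
#' v <- ctVolume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' voxelSpacing(v)
#' @export
ctVolume <- function(data, spacing = c(0.78, 0.78, 0.67),
                     origin = c(0, 0, 0), units = "HU") {
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), units = units)
}

#' Construct a binary mask
#'
#' @param data 3-D array of 0/1 (or logical) values.
#' @inheritParams ctVolume
#' @return A [BoneMask-class].
#' @export
boneMask <- function(data, spacing = c(0.78, 0.78, 0.67),
                     origin = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  new("BoneMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

## ---------------------------------------------------------------------------
## Transforms, calibration, material laws
## ---------------------------------------------------------------------------

#' Affine spatial transform
#'
#' Maps reference-space world coordinates x (mm) to moving-space coordinates
#' via \code{matrix \%*\% x + translation}.
#'
#' @slot matrix 3x3 linear part (invertible).
#' @slot translation numeric(3), mm.
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix", translation = "numeric"))

setValidity("AffineTransform", function(object) {
  msg <- character(0)
  if (!all(dim(object@matrix) == c(3L, 3L)))
    msg <- c(msg, "matrix must be 3x3")
  else if (abs(det(object@matrix)) < 1e-12)
    msg <- c(msg, "matrix must be invertible")
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' @rdname AffineTransform-class
#' @param matrix 3x3 linear part.
#' @param translation numeric(3) offset in mm.
#' @export
affineTransform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  new("AffineTransform", matrix = matrix,
      translation = as.numeric(translation))
}

#' HU-to-density calibration
#'
#' The affine map from CT intensity (HU) to QCT-equivalent bone density
#' (g/cm^3), fitted by ordinary least squares on calibration-phantom rods.
#'
#' @slot slope (g/cm^3)/HU, positive.
#' @slot intercept g/cm^3.
#' @slot fitR2 coefficient of determination of the rod fit.
#' @seealso [fitHuDensity()]
#' @export
setClass("DensityCalibration",
  representation(slope = "numeric", intercept = "numeric", fitR2 = "numeric"))

setValidity("DensityCalibration", function(object) {
  msg <- character(0)
  if (object@slope <= 0) msg <- c(msg, "slope must be positive")
  if (object@fitR2 < 0 || object@fitR2 > 1 + 1e-12)
    msg <- c(msg, "fitR2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname DensityCalibration-class
#' @param slope,intercept,fitR2 calibration parameters.
#' @export
densityCalibration <- function(slope, intercept, fitR2 = 1) {
  new("DensityCalibration", slope = as.numeric(slope),
      intercept = as.numeric(intercept), fitR2 = as.numeric(fitR2))
}

#' Density-to-elasticity material law
#'
#' Maps QCT density (g/cm^3) to Young's modulus (MPa), plus the parameters of
#' the elastic-perfectly-plastic constitutive model. Two families are
#' supported: the femoral power law E = 14900 rho^1.86 and the vertebral
#' linear law E = 3230 rho - 34.7.
#'
#' @slot kind \code{"femur_power"} or \code{"vertebra_linear"}.
#' @slot coefficient MPa (14900 or 3230 by default).
#' @slot exponent dimensionless power (1.86; ignored for the linear law).
#' @slot offset MPa (-34.7 for the linear law; 0 for the power law).
#' @slot yieldStrain dimensionless yield strain (default 0.015).
#' @slot poissonRatio dimensionless (default 0.3).
#' @slot eFloor MPa, minimum modulus assigned to any element (default 0.01).
#' @seealso [femurLaw()], [vertebraLaw()], [densityToModulus()]
#' @export
setClass("MaterialLaw",
  representation(kind = "character", coefficient = "numeric",
    exponent = "numeric", offset = "numeric", yieldStrain = "numeric",
    poissonRatio = "numeric", eFloor = "numeric"))

setValidity("MaterialLaw", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("femur_power", "vertebra_linear"))
    msg <- c(msg, "kind must be 'femur_power' or 'vertebra_linear'")
  if (object@coefficient <= 0) msg <- c(msg, "coefficient must be positive")
  if (object@yieldStrain <= 0) msg <- c(msg, "yieldStrain must be positive")
  if (object@poissonRatio < 0 || object@poissonRatio >= 0.5)
    msg <- c(msg, "poissonRatio must lie in [0, 0.5)")
  if (object@eFloor <= 0) msg <- c(msg, "eFloor must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname MaterialLaw-class
#' @param kind law family.
#' @param coefficient,exponent,offset law parameters (MPa scale).
#' @param yieldStrain,poissonRatio,eFloor plasticity/elasticity parameters.
#' @export
materialLaw <- function(kind = c("femur_power", "vertebra_linear"),
                        coefficient = NULL, exponent = 1.86, offset = NULL,
                        yieldStrain = 0.015, poissonRatio = 0.3,
                        eFloor = 0.01) {
  kind <- match.arg(kind)
  if (is.null(coefficient))
    coefficient <- if (kind == "femur_power") 14900 else 3230
  if (is.null(offset))
    offset <- if (kind == "femur_power") 0 else -34.7
  new("MaterialLaw", kind = kind, coefficient = coefficient,
      exponent = exponent, offset = offset, yieldStrain = yieldStrain,
      poissonRatio = poissonRatio, eFloor = eFloor)
}

#' @rdname MaterialLaw-class
#' @param ... passed on to [materialLaw()].
#' @export
femurLaw <- function(...) materialLaw("femur_power", ...)

#' @rdname MaterialLaw-class
#' @export
vertebraLaw <- function(...) materialLaw("vertebra_linear", ...)

## ---------------------------------------------------------------------------
## Phantom specifications
## ---------------------------------------------------------------------------

#' Synthetic bone phantom specification
#'
#' Analytic geometry (cylinders/tubes, with a hemispherical head cap for the
#' femur-like kind) voxelised by a voxel-centre-in-solid test, so oracle voxel
#' counts are exact. HU defaults are plausible CT class means: cortical 1200,
#' trabecular 300, marrow 0, soft tissue 40.
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot spacing numeric(3) mm per axis.
#' @slot boneKind \code{"femur"} (tube + hemispherical cap + marrow canal) or
#'   \code{"vertebra"} (shell + core cylinder).
#' @slot outerRadiusMm,corticalThicknessMm,heightMm,marrowRadiusMm geometry, mm.
#' @slot huCortical,huTrabecular,huMarrow,huSoftTissue tissue class means, HU.
#' @slot noiseSd additive Gaussian noise SD, HU.
#' @slot seed integer RNG seed.
#' @seealso [phantomSpec()], [generateBonePhantom()]
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
    boneKind = "character", outerRadiusMm = "numeric",
    corticalThicknessMm = "numeric", heightMm = "numeric",
    marrowRadiusMm = "numeric", huCortical = "numeric",
    huTrabecular = "numeric", huMarrow = "numeric", huSoftTissue = "numeric",
    noiseSd = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (!object@boneKind %in% c("femur", "vertebra"))
    msg <- c(msg, "boneKind must be 'femur' or 'vertebra'")
  if (length(object@gridShape) != 3L || any(object@gridShape < 3L))
    msg <- c(msg, "gridShape must be three values >= 3")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (object@corticalThicknessMm >= object@outerRadiusMm)
    msg <- c(msg, "corticalThicknessMm must be smaller than outerRadiusMm")
  hu <- c(object@huCortical, object@huTrabecular, object@huMarrow,
          object@huSoftTissue)
  if (any(!is.finite(hu))) msg <- c(msg, "HU means must be finite")
  if (!(object@huCortical >= object@huTrabecular &&
        object@huTrabecular > object@huSoftTissue))
    msg <- c(msg, "need huCortical >= huTrabecular > huSoftTissue")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Build a phantom specification
#'
#' If \code{gridShape} is omitted it is sized to hold the geometry plus a
#' two-voxel background margin on every side.
#'
#' @param boneKind phantom family.
#' @param spacing voxel size, mm.
#' @param outerRadiusMm,corticalThicknessMm,heightMm,marrowRadiusMm geometry
#'   (mm). \code{marrowRadiusMm} applies to the femoral shaft only; default
#'   0.35 x outer radius for femurs, 0 for vertebrae.
#' @param huCortical,huTrabecular,huMarrow,huSoftTissue tissue means (HU).
#' @param noiseSd additive Gaussian noise SD (HU); 0 disables noise.
#' @param seed RNG seed used when noise is drawn.
#' @param gridShape optional integer(3) grid size.
#' @return A [PhantomSpec-class].
#' @examples
#' sp <- phantomSpec("femur", spacing = c(1, 1, 1), outerRadiusMm = 6,
#'                   corticalThicknessMm = 2, heightMm = 25)
#' sp
#' @export
phantomSpec <- function(boneKind = c("femur", "vertebra"),
                        spacing = c(0.78, 0.78, 0.67),
                        outerRadiusMm = if (boneKind == "femur") 12 else 15,
                        corticalThicknessMm = if (boneKind == "femur") 3 else 1,
                        heightMm = if (boneKind == "femur") 80 else 30,
                        marrowRadiusMm = NULL,
                        huCortical = 1200, huTrabecular = 300, huMarrow = 0,
                        huSoftTissue = 40, noiseSd = 0, seed = 1L,
                        gridShape = NULL) {
  boneKind <- match.arg(boneKind)
  if (is.null(marrowRadiusMm))
    marrowRadiusMm <- if (boneKind == "femur") 0.35 * outerRadiusMm else 0
  if (is.null(gridShape)) {
    margin <- 2 * spacing
    extent <- c(2 * outerRadiusMm, 2 * outerRadiusMm, heightMm) + 2 * margin
    gridShape <- as.integer(ceiling(extent / spacing))
  }
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), boneKind = boneKind,
      outerRadiusMm = outerRadiusMm,
      corticalThicknessMm = corticalThicknessMm, heightMm = heightMm,
      marrowRadiusMm = marrowRadiusMm, huCortical = huCortical,
      huTrabecular = huTrabecular, huMarrow = huMarrow,
      huSoftTissue = huSoftTissue, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' Osteolytic lesion specification
#'
#' A sphere of locally reduced intensity inside the bone, emulating an
#' osteolytic metastasis. Lesions change intensities only, never the mask.
#'
#' @slot center numeric(3), 1-based voxel coordinates of the lesion centre.
#' @slot radiusMm sphere radius, mm.
#' @slot huLesion replacement intensity (below trabecular HU for osteolytic).
#' @export
setClass("LesionSpec",
  representation(center = "numeric", radiusMm = "numeric",
                 huLesion = "numeric"))

setValidity("LesionSpec", function(object) {
  msg <- character(0)
  if (length(object@center) != 3L)
    msg <- c(msg, "center must be three voxel coordinates")
  if (object@radiusMm <= 0) msg <- c(msg, "radiusMm must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname LesionSpec-class
#' @param center voxel coordinates (1-based).
#' @param radiusMm radius in mm.
#' @param huLesion replacement HU.
#' @export
lesionSpec <- function(center, radiusMm, huLesion = 20) {
  new("LesionSpec", center = as.numeric(center), radiusMm = radiusMm,
      huLesion = huLesion)
}

#' Calibration rod layout
#'
#' Rods of known equivalent density running along one axis, emulating an
#' in-scan QCT calibration phantom.
#'
#' @slot rods data.frame with columns \code{centerXMm}, \code{centerYMm}
#'   (world mm, in the plane perpendicular to \code{orientation}),
#'   \code{radiusMm}, \code{density} (g/cm^3, strictly increasing) and
#'   \code{huMean}.
#' @slot orientation axis (1, 2 or 3) along which the rods run.
#' @export
setClass("RodLayout",
  representation(rods = "data.frame", orientation = "integer"))

setValidity("RodLayout", function(object) {
  msg <- character(0)
  need <- c("centerXMm", "centerYMm", "radiusMm", "density", "huMean")
  if (!all(need %in% names(object@rods)))
    msg <- c(msg, paste("rods needs columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@rods) < 2L) msg <- c(msg, "need at least 2 rods")
    if (any(diff(object@rods$density) <= 0))
      msg <- c(msg, "rod densities must be strictly increasing")
  }
  if (!object@orientation %in% 1:3)
    msg <- c(msg, "orientation must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' @rdname RodLayout-class
#' @param rods data.frame describing the rods (see slot documentation).
#' @param orientation rod axis.
#' @export
rodLayout <- function(rods, orientation = 3L) {
  new("RodLayout", rods = rods, orientation = as.integer(orientation))
}

## ---------------------------------------------------------------------------
## Segmentation perturbation
## ---------------------------------------------------------------------------

#' Morphological perturbation specification
#'
#' Iterated binary erosion or dilation, one voxel layer per iteration, used
#' to emulate under- and over-segmentation. The default structuring element is
#' the 6-connected cross (one voxel layer literal along each axis); the
#' 26-connected box is available.
#'
#' @slot op \code{"none"}, \code{"erode"} or \code{"dilate"}.
#' @slot iterations 0, 1 or 2 (the sensitivity-study grid).
#' @slot connectivity 6 or 26.
#' @seealso [perturbMask()]
#' @export
setClass("PerturbationSpec",
  representation(op = "character", iterations = "integer",
                 connectivity = "integer"))

setValidity("PerturbationSpec", function(object) {
  msg <- character(0)
  if (!object@op %in% c("none", "erode", "dilate"))
    msg <- c(msg, "op must be 'none', 'erode' or 'dilate'")
  if (!object@iterations %in% 0:2)
    msg <- c(msg, "iterations must be 0, 1 or 2")
  if (!object@connectivity %in% c(6L, 26L))
    msg <- c(msg, "connectivity must be 6 or 26")
  if (length(msg)) msg else TRUE
})

#' @rdname PerturbationSpec-class
#' @param op,iterations,connectivity see slot documentation.
#' @export
perturbationSpec <- function(op = c("none", "erode", "dilate"),
                             iterations = 1L, connectivity = 6L) {
  op <- match.arg(op)
  if (op == "none") iterations <- 0L
  new("PerturbationSpec", op = op, iterations = as.integer(iterations),
      connectivity = as.integer(connectivity))
}

## ---------------------------------------------------------------------------
## FE structures
## ---------------------------------------------------------------------------

#' Voxel-based hexahedral mesh
#'
#' One 8-node brick element per in-mask voxel, with nodes shared between
#' adjacent voxels and per-element density and Young's modulus.
#'
#' @slot nodes n x 3 matrix of node world coordinates, mm.
#' @slot elements m x 8 integer connectivity (node indices).
#' @slot elementDensity g/cm^3 per element.
#' @slot elementModulus MPa per element (floored at the law's eFloor).
#' @slot spacing voxel edge lengths, mm (all elements share them).
#' @slot law the [MaterialLaw-class] used to assign moduli.
#' @seealso [buildHexMesh()]
#' @export
setClass("HexMesh",
  representation(nodes = "matrix", elements = "matrix",
    elementDensity = "numeric", elementModulus = "numeric",
    spacing = "numeric", law = "MaterialLaw"))

setValidity("HexMesh", function(object) {
  msg <- character(0)
  m <- nrow(object@elements)
  if (ncol(object@elements) != 8L) msg <- c(msg, "elements must be m x 8")
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be n x 3")
  if (length(object@elementDensity) != m ||
      length(object@elementModulus) != m)
    msg <- c(msg, "element fields must have one value per element")
  if (m > 0 && (max(object@elements) > nrow(object@nodes) ||
                min(object@elements) < 1L))
    msg <- c(msg, "element connectivity references missing nodes")
  if (length(msg)) msg else TRUE
})

#' Displacement-controlled compression boundary conditions
#'
#' @slot fixedNodes node indices held at the support (minimum coordinate end).
#' @slot drivenNodes node indices receiving the prescribed axial displacement
#'   (maximum coordinate end).
#' @slot axis loading axis (1, 2 or 3).
#' @slot stepMm displacement increment, mm.
#' @slot maxMm total prescribed displacement, mm.
#' @slot support \code{"clamped"} (all axes of the fixed set zero) or
#'   \code{"pinned"} (axial constraint plus minimal lateral pins, i.e.
#'   frictionless platens).
#' @seealso [applyAxialCompressionBC()]
#' @export
setClass("BoundaryConditions",
  representation(fixedNodes = "integer", drivenNodes = "integer",
    axis = "integer", stepMm = "numeric", maxMm = "numeric",
    support = "character"))

setValidity("BoundaryConditions", function(object) {
  msg <- character(0)
  if (length(object@fixedNodes) == 0L || length(object@drivenNodes) == 0L)
    msg <- c(msg, "fixed and driven node sets must be nonempty")
  if (length(intersect(object@fixedNodes, object@drivenNodes)))
    msg <- c(msg, "fixed and driven node sets must be disjoint")
  if (object@stepMm <= 0) msg <- c(msg, "stepMm must be positive")
  if (object@maxMm < object@stepMm) msg <- c(msg, "maxMm must be >= stepMm")
  if (!object@support %in% c("clamped", "pinned"))
    msg <- c(msg, "support must be 'clamped' or 'pinned'")
  if (length(msg)) msg else TRUE
})

#' Result of a displacement-controlled solve
#'
#' @slot displacements applied displacement magnitude per step, mm.
#' @slot reactions axial reaction force per step, N (compression positive).
#' @slot failureLoad extracted failure load, N (NA until a criterion is
#'   applied).
#' @slot failureStep step index of the failure load.
#' @slot criterion \code{"femur_max_load"} or
#'   \code{"vertebra_height_reduction"}.
#' @slot iterations equilibrium iterations used per step.
#' @seealso [solveNonlinear()], [failureLoad()]
#' @export
setClass("SolveResult",
  representation(displacements = "numeric", reactions = "numeric",
    failureLoad = "numeric", failureStep = "numeric",
    criterion = "character", iterations = "integer"))

setValidity("SolveResult", function(object) {
  if (length(object@displacements) != length(object@reactions))
    return("displacements and reactions must have equal length")
  TRUE
})

## ---------------------------------------------------------------------------
## Metric / report containers
## ---------------------------------------------------------------------------

#' Segmentation agreement report
#'
#' @slot dsc Sorensen-Dice coefficient in [0, 1].
#' @slot hdMm Hausdorff distance, mm.
#' @seealso [maskMetrics()]
#' @export
setClass("MetricReport", representation(dsc = "numeric", hdMm = "numeric"))

setValidity("MetricReport", function(object) {
  msg <- character(0)
  if (object@dsc < -1e-12 || object@dsc > 1 + 1e-12)
    msg <- c(msg, "dsc must lie in [0, 1]")
  if (object@hdMm < 0) msg <- c(msg, "hdMm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Bundles the choices needed for an end-to-end failure-load run: bone kind
#' (selects the material law and failure criterion), density calibration
#' (fitted from rods if not supplied), solver settings and output directory.
#'
#' @slot boneKind \code{"femur"} or \code{"vertebra"}.
#' @slot law [MaterialLaw-class].
#' @slot calibration [DensityCalibration-class] or NULL (fit from rods).
#' @slot rodLayout [RodLayout-class] or NULL.
#' @slot bcAxis loading axis.
#' @slot bcLayerVoxels thickness of the driven/fixed node layers, in voxels
#'   along the loading axis.
#' @slot stepFrac displacement increment as a fraction of bone height
#'   (default 0.001, i.e. 0.1\%).
#' @slot maxFrac total displacement as a fraction of bone height.
#' @slot support support mode passed to [applyAxialCompressionBC()].
#' @slot hdPercentile Hausdorff percentile (1 = maximum).
#' @slot outputDir character or NA; when set, intermediates are written there.
#' @slot seed integer seed recorded in the run manifest.
#' @seealso [runFailurePipeline()], [runSensitivity()]
#' @export
setClass("PipelineConfig",
  representation(boneKind = "character", law = "MaterialLaw",
    calibration = "ANY", rodLayout = "ANY", bcAxis = "integer",
    bcLayerVoxels = "numeric", stepFrac = "numeric", maxFrac = "numeric",
    support = "character", hdPercentile = "numeric", outputDir = "character",
    seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character(0)
  if (!object@boneKind %in% c("femur", "vertebra"))
    msg <- c(msg, "boneKind must be 'femur' or 'vertebra'")
  wantKind <- if (object@boneKind == "femur") "femur_power" else
    "vertebra_linear"
  if (object@law@kind != wantKind)
    msg <- c(msg, sprintf("law kind '%s' inconsistent with boneKind '%s'",
                          object@law@kind, object@boneKind))
  if (is.null(object@calibration) && is.null(object@rodLayout))
    msg <- c(msg, "either a calibration or a rod layout must be supplied")
  if (object@stepFrac <= 0 || object@maxFrac < object@stepFrac)
    msg <- c(msg, "need 0 < stepFrac <= maxFrac")
  if (length(msg)) msg else TRUE
})

#' @rdname PipelineConfig-class
#' @param boneKind bone type; selects law family and failure criterion.
#' @param law material law (defaults to the family matching boneKind).
#' @param calibration optional [DensityCalibration-class].
#' @param rodLayout optional [RodLayout-class] used to fit the calibration.
#' @param bcAxis,bcLayerVoxels,stepFrac,maxFrac,support solver settings.
#' @param hdPercentile Hausdorff percentile used in reports.
#' @param outputDir optional output directory.
#' @param seed seed recorded in the manifest.
#' @export
pipelineConfig <- function(boneKind = c("femur", "vertebra"), law = NULL,
                           calibration = NULL, rodLayout = NULL,
                           bcAxis = 3L, bcLayerVoxels = 2.6,
                           stepFrac = 0.001,
                           maxFrac = if (boneKind == "femur") 0.01 else 0.025,
                           support = "clamped", hdPercentile = 1,
                           outputDir = NA_character_, seed = 1L) {
  boneKind <- match.arg(boneKind)
  if (is.null(law))
    law <- if (boneKind == "femur") femurLaw() else vertebraLaw()
  new("PipelineConfig", boneKind = boneKind, law = law,
      calibration = calibration, rodLayout = rodLayout,
      bcAxis = as.integer(bcAxis), bcLayerVoxels = bcLayerVoxels,
      stepFrac = stepFrac, maxFrac = maxFrac, support = support,
      hdPercentile = hdPercentile, outputDir = outputDir,
      seed = as.integer(seed))
}

#' Segmentation-sensitivity report
#'
#' Per-variant (erode x2, erode x1, none, dilate x1, dilate x2) segmentation
#' agreement against the reference mask and failure-load differences against
#' the reference-mask failure load.
#'
#' @slot table data.frame with one row per variant.
#' @slot referenceFL reference-mask failure load, N.
#' @slot boneKind bone type the report refers to.
#' @seealso [runSensitivity()], [batchReport()]
#' @export
setClass("SensitivityReport",
  representation(table = "data.frame", referenceFL = "numeric",
                 boneKind = "character"))
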