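#' @name accessors
#' @title Accessors for voxel grids and FE objects
#' @description Slot access goes through these accessors; user code should
#'   never reach into slots directly.
#' @param x object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("intensityUnits", function(x) standardGeneric("intensityUnits"))
#' @rdname accessors
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' @rdname accessors
#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))
#' @rdname accessors
#' @export
setGeneric("meshElements", function(x) standardGeneric("meshElements"))
#' @rdname accessors
#' @export
setGeneric("elementDensity", function(x) standardGeneric("elementDensity"))
#' @rdname accessors
#' @export
setGeneric("elementModulus", function(x) standardGeneric("elementModulus"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' Extract the failure load from a solved load-displacement curve
#'
#' @param result a [SolveResult-class].
#' @param criterion \code{"femur_max_load"} (curve maximum) or
#'   \code{"vertebra_height_reduction"} (load at 1.9\% height reduction).
#' @param boneHeightMm bone height along the loading axis, mm; required for
#'   the vertebral criterion.
#' @param heightReduction height-reduction ratio triggering vertebral failure
#'   (default 0.019).
#' @return Failure load in N (compression positive), with attribute
#'   \code{"step"} giving the step index at (or just after) failure.
#' @export
setGeneric("failureLoad",
  function(result, criterion = c("femur_max_load",
                                 "vertebra_height_reduction"),
           boneHeightMm = NULL, heightReduction = 0.019)
    standardGeneric("failureLoad"))

## ---------------------------------------------------------------------------
## Methods
## ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("volData", "VoxelGrid", function(x) x@data)
#' @rdname accessors
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
#' @rdname accessors
setMethod("gridDim", "VoxelGrid", function(x) dim(x@data))
#' @rdname accessors
setMethod("intensityUnits", "CTVolume", function(x) x@units)
#' @rdname accessors
setMethod("voxelCount", "BoneMask", function(x) sum(x@data != 0L))

#' @rdname accessors
setMethod("meshNodes", "HexMesh", function(x) x@nodes)
#' @rdname accessors
setMethod("meshElements", "HexMesh", function(x) x@elements)
#' @rdname accessors
setMethod("elementDensity", "HexMesh", function(x) x@elementDensity)
#' @rdname accessors
setMethod("elementModulus", "HexMesh", function(x) x@elementModulus)

#' @rdname accessors
setMethod("reactions", "SolveResult", function(x) x@reactions)
#' @rdname accessors
setMethod("displacements", "SolveResult", function(x) x@displacements)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume %d x %d x %d voxels [%s]\n", d[1], d[2], d[3],
              object@units))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g mm, origin (%.3g, %.3g, %.3g)\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@origin[1], object@origin[2], object@origin[3]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BoneMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoneMask %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(object@data != 0L)))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g mm\n",
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "DensityCalibration", function(object) {
  cat(sprintf(
    "DensityCalibration: rho = %.6g * HU + %.6g (g/cm^3), r^2 = %.4f\n",
    object@slope, object@intercept, object@fitR2))
})

setMethod("show", "MaterialLaw", function(object) {
  if (object@kind == "femur_power")
    cat(sprintf("MaterialLaw femur_power: E(MPa) = %g * rho^%g\n",
                object@coefficient, object@exponent))
  else
    cat(sprintf("MaterialLaw vertebra_linear: E(MPa) = %g * rho %+g\n",
                object@coefficient, object@offset))
  cat(sprintf("  yield strain %.3g, Poisson %.3g, E floor %.3g MPa\n",
              object@yieldStrain, object@poissonRatio, object@eFloor))
})

setMethod("show", "HexMesh", function(object) {
  cat(sprintf("HexMesh: %d hexahedral elements, %d nodes\n",
              nrow(object@elements), nrow(object@nodes)))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g mm, E in [%.4g, %.4g] MPa\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              min(object@elementModulus), max(object@elementModulus)))
})

setMethod("show", "SolveResult", function(object) {
  n <- length(object@reactions)
  cat(sprintf("SolveResult: %d steps, final displacement %.4g mm\n",
              n, if (n) object@displacements[n] else NA))
  cat(sprintf("  peak reaction %.6g N", if (n) max(object@reactions) else NA))
  if (!is.na(object@failureLoad))
    cat(sprintf("; failure load %.6g N (%s)", object@failureLoad,
                object@criterion))
  cat("\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec (%s-like): R %.3g mm, cortex %.3g mm, height %.3g mm\n",
    object@boneKind, object@outerRadiusMm, object@corticalThicknessMm,
    object@heightMm))
  cat(sprintf("  grid %s at %.3g x %.3g x %.3g mm, noise SD %.3g HU, seed %d\n",
              paste(object@gridShape, collapse = " x "), object@spacing[1],
              object@spacing[2], object@spacing[3], object@noiseSd,
              object@seed))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: DSC %.4f, HD %.4g mm\n", object@dsc,
              object@hdMm))
})

setMethod("show", "SensitivityReport", function(object) {
  cat(sprintf("SensitivityReport (%s), reference FL %.6g N\n",
              object@boneKind, object@referenceFL))
  print(object@table, row.names = FALSE)
})
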