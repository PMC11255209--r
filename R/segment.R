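## Classical threshold segmentation (pluggable stand-in for any externally
## produced mask), island-removal post-processing, and the erosion/dilation
## perturbation operator driving the sensitivity study.

#' Threshold-based bone segmentation
#'
#' Voxels at or above the HU threshold are kept, interior cavities are
#' filled, and connected components smaller than \code{minComponentVoxels}
#' are dropped. Deterministic; any externally produced mask (e.g. a network
#' prediction read from NIfTI) can be used in its place downstream.
#'
#' @param volume a [CTVolume-class] in HU (not normalised).
#' @param huThreshold segmentation threshold, HU. On noiseless phantoms the
#'   midpoint between soft-tissue and trabecular HU recovers the ground
#'   truth.
#' @param minComponentVoxels smallest component retained, voxels.
#' @return A [BoneMask-class].
#' @export
segmentBone <- function(volume, huThreshold, minComponentVoxels = 1L) {
  if (intensityUnits(volume) == "normalized")
    stop("segmentBone expects a volume in HU, not normalized units",
         call. = FALSE)
  bin <- volume@data >= huThreshold
  if (any(bin)) {
    bin <- .fillHoles(bin)
    comp <- .labelComponents(bin)
    keep <- which(comp$sizes >= minComponentVoxels)
    bin <- array(comp$labels %in% keep, dim(bin))
  }
  if (!any(bin))
    stop("no bone found at threshold", call. = FALSE)
  boneMask(array(as.integer(bin), dim(bin)), voxelSpacing(volume),
           gridOrigin(volume))
}

#' Morphological post-processing of a segmentation
#'
#' Binary opening (one erosion followed by one dilation with the default
#' structuring element) and removal of connected components smaller than
#' \code{minIslandVoxels}, mirroring the island-removal clean-up applied to
#' network predictions. The output is always contained in the dilation of the
#' input; an empty mask passes through unchanged.
#'
#' @param mask a [BoneMask-class].
#' @param minIslandVoxels smallest island retained after opening.
#' @param connectivity structuring element (6 or 26).
#' @return A [BoneMask-class].
#' @export
postprocessMask <- function(mask, minIslandVoxels = 1L, connectivity = 6L) {
  m <- .maskLogical(mask)
  if (any(m)) {
    m <- .dilateOnce(.erodeOnce(m, connectivity), connectivity)
    if (any(m)) {
      comp <- .labelComponents(m)
      keep <- which(comp$sizes >= minIslandVoxels)
      m <- array(comp$labels %in% keep, dim(m))
    }
  }
  boneMask(array(as.integer(m), dim(m)), voxelSpacing(mask),
           gridOrigin(mask))
}

#' Erode or dilate a mask to emulate segmentation variability
#'
#' Iterated binary erosion or dilation, one voxel layer per iteration with
#' the 6-connected cross by default (so "one pixel" is literal along each
#' axis; erosion and dilation act in voxel space, ignoring anisotropic
#' spacing). \code{op = "none"} or 0 iterations returns the mask unchanged;
#' erosion output is contained in the input, which is contained in the
#' dilation output.
#'
#' @param mask a [BoneMask-class].
#' @param spec a [PerturbationSpec-class], or NULL to use \code{op} /
#'   \code{iterations} / \code{connectivity} directly.
#' @param op,iterations,connectivity shortcut arguments used when
#'   \code{spec} is NULL.
#' @return A [BoneMask-class].
#' @examples
#' cube <- boneMask(array(1L, c(10, 10, 10)), spacing = c(1, 1, 1))
#' voxelCount(perturbMask(cube, op = "erode", iterations = 1))  # 8^3 = 512
#' @export
perturbMask <- function(mask, spec = NULL, op = c("none", "erode", "dilate"),
                        iterations = 1L, connectivity = 6L) {
  if (is.null(spec)) {
    spec <- perturbationSpec(match.arg(op), iterations, connectivity)
  }
  validObject(spec)
  m <- .maskLogical(mask)
  if (spec@op == "none" || spec@iterations == 0L) return(mask)
  for (i in seq_len(spec@iterations)) {
    m <- if (spec@op == "erode") .erodeOnce(m, spec@connectivity)
         else .dilateOnce(m, spec@connectivity)
  }
  if (spec@op == "erode" && !any(m))
    stop("mask vanished under erosion", call. = FALSE)
  boneMask(array(as.integer(m), dim(m)), voxelSpacing(mask),
           gridOrigin(mask))
}
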