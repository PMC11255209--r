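## Synthetic CT phantoms: analytic bone-like solids voxelised by a
## voxel-centre-in-solid test, so expected voxel counts have exact
## brute-force oracles.

## Tissue codes: 0 background, 1 cortical, 2 trabecular, 3 marrow.
.boneTissueCodes <- function(spec, dm, spacing, origin, centerXY, zBase) {
  co <- .coordArrays(dm, spacing, origin)
  R <- spec@outerRadiusMm
  t <- spec@corticalThicknessMm
  r2 <- (co$x - centerXY[1])^2 + (co$y - centerXY[2])^2
  z <- co$z
  codes <- array(0L, dm)
  if (spec@boneKind == "femur") {
    zCap <- zBase + spec@heightMm - R      # cap centre; dome tops at zBase+height
    inShaft <- r2 <= R^2 & z >= zBase & z <= zCap
    capD2 <- r2 + (z - zCap)^2
    inCap <- capD2 <= R^2 & z > zCap
    solid <- inShaft | inCap
    cortical <- (inShaft & (r2 >= (R - t)^2 | z <= zBase + t)) |
                (inCap & capD2 >= (R - t)^2)
    marrow <- inShaft & r2 <= spec@marrowRadiusMm^2 & z >= zBase + t
    codes[solid] <- 2L
    codes[marrow & solid] <- 3L
    codes[cortical] <- 1L
  } else {
    zTop <- zBase + spec@heightMm
    solid <- r2 <= R^2 & z >= zBase & z <= zTop
    cortical <- solid & (r2 >= (R - t)^2 | z <= zBase + t | z >= zTop - t)
    codes[solid] <- 2L
    codes[cortical] <- 1L
  }
  codes
}

.checkGeometryFits <- function(spec, dm, spacing, centerXY, zBase) {
  ext <- dm * spacing                       # world extent of the grid
  need <- c(centerXY[1] + spec@outerRadiusMm + spacing[1],
            centerXY[2] + spec@outerRadiusMm + spacing[2],
            zBase + spec@heightMm + spacing[3])
  low <- c(centerXY[1] - spec@outerRadiusMm - spacing[1],
           centerXY[2] - spec@outerRadiusMm - spacing[2],
           zBase - spacing[3])
  ax <- c("x", "y", "z")
  for (i in 1:3) {
    if (need[i] > ext[i] || low[i] < 0)
      stop(sprintf(
        "phantom geometry exceeds the grid along %s (needs %.1f mm, grid %.1f mm)",
        ax[i], need[i] - min(low[i], 0), ext[i]), call. = FALSE)
  }
  invisible(TRUE)
}

.applyLesions <- function(vol, codes, lesions, spacing, origin) {
  if (!length(lesions)) return(vol)
  dm <- dim(vol)
  co <- .coordArrays(dm, spacing, origin)
  for (les in lesions) {
    validObject(les)
    cIdx <- les@center
    if (any(cIdx < 1) || any(cIdx > dm))
      stop("lesion center lies outside the grid", call. = FALSE)
    cLin <- cIdx[1] + (cIdx[2] - 1) * dm[1] + (cIdx[3] - 1) * dm[1] * dm[2]
    if (codes[cLin] == 0L)
      stop("lesion center lies outside the bone interior", call. = FALSE)
    cw <- origin + (cIdx - 1) * spacing
    sphere <- (co$x - cw[1])^2 + (co$y - cw[2])^2 + (co$z - cw[3])^2 <=
      les@radiusMm^2
    hit <- sphere & codes != 0L
    if (!any(hit))
      stop("lesion sphere does not intersect the bone", call. = FALSE)
    vol[hit] <- les@huLesion
  }
  vol
}

#' Generate a synthetic bone phantom
#'
#' Builds a CT-like volume and its ground-truth mask for a femur-like
#' (cortical tube + hemispherical head cap + marrow canal) or vertebra-like
#' (shell + trabecular core) object surrounded by soft tissue. With
#' \code{noiseSd = 0} every voxel equals the mean intensity of its tissue
#' class; identical spec and seed give bit-identical output. Lesions replace
#' intensities inside the bone but never alter the mask.
#'
#' @param spec a [PhantomSpec-class].
#' @param lesions list of [LesionSpec-class] objects (optional).
#' @param center optional world (x, y) bone-axis position, mm; defaults to
#'   the grid centre.
#' @return A list with elements \code{volume} ([CTVolume-class]) and
#'   \code{mask} ([BoneMask-class]).
#' @examples
#' sp <- phantomSpec("vertebra", spacing = c(1.5, 1.5, 1.5),
#'                   outerRadiusMm = 8, corticalThicknessMm = 1.5,
#'                   heightMm = 20)
#' ph <- generateBonePhantom(sp)
#' voxelCount(ph$mask)
#' @export
generateBonePhantom <- function(spec, lesions = list(), center = NULL) {
  validObject(spec)
  dm <- spec@gridShape
  spacing <- spec@spacing
  origin <- c(0, 0, 0)
  if (is.null(center))
    center <- ((dm[1:2] - 1) * spacing[1:2]) / 2
  zBase <- 2 * spacing[3]
  .checkGeometryFits(spec, dm, spacing, center, zBase)
  codes <- .boneTissueCodes(spec, dm, spacing, origin, center, zBase)
  vol <- array(spec@huSoftTissue, dm)
  vol[codes == 1L] <- spec@huCortical
  vol[codes == 2L] <- spec@huTrabecular
  vol[codes == 3L] <- spec@huMarrow
  vol <- .applyLesions(vol, codes, lesions, spacing, origin)
  if (spec@noiseSd > 0)
    vol <- vol + .withSeed(spec@seed,
                           array(rnorm(prod(dm), 0, spec@noiseSd), dm))
  list(volume = ctVolume(vol, spacing, origin, units = "HU"),
       mask = boneMask(array(as.integer(codes != 0L), dm), spacing, origin))
}

#' Generate a bilateral hip-like volume
#'
#' Places two femur-like phantoms side by side along x, separated by at least
#' \code{gapMm} of soft tissue, in a single grid. Mirror-identical specs give
#' mirror-symmetric masks with equal voxel counts.
#'
#' @param leftSpec,rightSpec [PhantomSpec-class] objects sharing spacing.
#' @param gapMm minimum soft-tissue gap between the two bone surfaces, mm.
#' @return List with \code{volume}, \code{leftMask}, \code{rightMask}.
#' @export
generateHipVolume <- function(leftSpec, rightSpec, gapMm = 20) {
  validObject(leftSpec); validObject(rightSpec)
  if (!isTRUE(all.equal(leftSpec@spacing, rightSpec@spacing)))
    stop("both specs must share voxel spacing", call. = FALSE)
  if (gapMm <= 0) stop("bones overlap: gapMm must be positive", call. = FALSE)
  spacing <- leftSpec@spacing
  margin <- 2 * spacing
  widthMm <- 2 * leftSpec@outerRadiusMm + 2 * rightSpec@outerRadiusMm +
    gapMm + 2 * margin[1]
  ny <- max(leftSpec@gridShape[2], rightSpec@gridShape[2])
  nz <- max(leftSpec@gridShape[3], rightSpec@gridShape[3])
  nx <- as.integer(ceiling(widthMm / spacing[1]))
  dm <- c(nx, ny, nz)
  origin <- c(0, 0, 0)
  cy <- (ny - 1) * spacing[2] / 2
  ## placement symmetric about the voxel-lattice mid-plane, so
  ## mirror-identical specs give exactly mirror-symmetric masks
  cxMid <- (nx - 1) * spacing[1] / 2
  cxL <- cxMid - gapMm / 2 - leftSpec@outerRadiusMm
  cxR <- cxMid + gapMm / 2 + rightSpec@outerRadiusMm
  zBase <- 2 * spacing[3]
  .checkGeometryFits(leftSpec, dm, spacing, c(cxL, cy), zBase)
  .checkGeometryFits(rightSpec, dm, spacing, c(cxR, cy), zBase)
  codesL <- .boneTissueCodes(leftSpec, dm, spacing, origin, c(cxL, cy), zBase)
  codesR <- .boneTissueCodes(rightSpec, dm, spacing, origin, c(cxR, cy), zBase)
  if (any(codesL != 0L & codesR != 0L))
    stop("bones overlap: increase gapMm", call. = FALSE)
  vol <- array(leftSpec@huSoftTissue, dm)
  for (side in list(list(sp = leftSpec, cd = codesL),
                    list(sp = rightSpec, cd = codesR))) {
    vol[side$cd == 1L] <- side$sp@huCortical
    vol[side$cd == 2L] <- side$sp@huTrabecular
    vol[side$cd == 3L] <- side$sp@huMarrow
  }
  if (leftSpec@noiseSd > 0)
    vol <- vol + .withSeed(leftSpec@seed,
                           array(rnorm(prod(dm), 0, leftSpec@noiseSd), dm))
  list(volume = ctVolume(vol, spacing, origin, units = "HU"),
       leftMask = boneMask(array(as.integer(codesL != 0L), dm), spacing,
                           origin),
       rightMask = boneMask(array(as.integer(codesR != 0L), dm), spacing,
                            origin))
}

## Logical region of one rod (full-length cylinder along the layout axis).
.rodRegion <- function(dm, spacing, origin, layout, i) {
  co <- .coordArrays(dm, spacing, origin)
  ax <- layout@orientation
  perp <- setdiff(1:3, ax)
  cc <- list(co$x, co$y, co$z)
  r2 <- (cc[[perp[1]]] - layout@rods$centerXMm[i])^2 +
        (cc[[perp[2]]] - layout@rods$centerYMm[i])^2
  r2 <= layout@rods$radiusMm[i]^2
}

#' Embed calibration rods into a volume
#'
#' Sets rod voxels to each rod's mean HU (plus optional Gaussian noise);
#' every other voxel is untouched. Rods must lie inside the grid and must not
#' intersect the bone mask if one is supplied.
#'
#' @param volume a [CTVolume-class] in HU.
#' @param layout a [RodLayout-class].
#' @param mask optional [BoneMask-class]; rods intersecting it are an error.
#' @param noiseSd additive Gaussian noise SD inside the rods (HU).
#' @param seed RNG seed for rod noise.
#' @return The modified [CTVolume-class].
#' @export
embedRods <- function(volume, layout, mask = NULL, noiseSd = 0, seed = 1L) {
  validObject(layout)
  if (!nrow(layout@rods)) return(volume)
  dm <- gridDim(volume)
  spacing <- voxelSpacing(volume)
  origin <- gridOrigin(volume)
  dat <- volume@data
  perp <- setdiff(1:3, layout@orientation)
  extLow <- origin[perp]
  extHigh <- origin[perp] + (dm[perp] - 1) * spacing[perp]
  for (i in seq_len(nrow(layout@rods))) {
    cXY <- c(layout@rods$centerXMm[i], layout@rods$centerYMm[i])
    r <- layout@rods$radiusMm[i]
    if (any(cXY - r < extLow) || any(cXY + r > extHigh))
      stop(sprintf("rod %d does not fit inside the grid", i), call. = FALSE)
    reg <- .rodRegion(dm, spacing, origin, layout, i)
    if (!is.null(mask) && any(reg & .maskLogical(mask)))
      stop(sprintf("rod %d intersects the bone mask", i), call. = FALSE)
    vals <- rep(layout@rods$huMean[i], sum(reg))
    if (noiseSd > 0)
      vals <- vals + .withSeed(seed + i, rnorm(length(vals), 0, noiseSd))
    dat[reg] <- vals
  }
  ctVolume(dat, spacing, origin, units = intensityUnits(volume))
}

#' Build one femur case for the segmentation-sensitivity study
#'
#' Generates a noiseless femur-like phantom with randomized geometry (outer
#' radius, cortical thickness and height drawn from the seed), embeds three
#' calibration rods beside the bone, and crops the grid flush to the bone's
#' axial extent so that the compression platens land on the same planes for
#' every segmentation variant (dilation can then only add material
#' laterally, never lengthen the load path).
#'
#' @param seed integer seed controlling the geometry draw.
#' @param spacing isotropic voxel size, mm (default 1.6 mm, coarse enough to
#'   keep the finite-element meshes at a few thousand elements).
#' @param radiusRange,thicknessRange,heightRange uniform draw bounds, mm.
#' @return List with \code{volume}, \code{mask} (ground truth),
#'   \code{rodLayout}, and the drawn \code{outerRadiusMm},
#'   \code{corticalThicknessMm}, \code{heightMm}, \code{spacing}.
#' @export
femurSensitivityCase <- function(seed = 1L, spacing = 1.6,
                                 radiusRange = c(5, 6.5),
                                 thicknessRange = c(1.8, 2.4),
                                 heightRange = c(30, 36)) {
  geo <- .withSeed(seed, c(stats::runif(1, radiusRange[1], radiusRange[2]),
                           stats::runif(1, thicknessRange[1],
                                        thicknessRange[2]),
                           stats::runif(1, heightRange[1], heightRange[2])))
  R <- geo[1]; t <- geo[2]; h <- geo[3]
  spc <- phantomSpec("femur", spacing = rep(spacing, 3), outerRadiusMm = R,
                     corticalThicknessMm = t, heightMm = h, noiseSd = 0,
                     seed = seed)
  gs <- spc@gridShape
  gs[1] <- gs[1] + as.integer(ceiling(20 / spacing))  # room for the rods
  spc@gridShape <- gs
  boneCx <- R + 2 * spacing
  cy <- (gs[2] - 1) * spacing / 2
  ph <- generateBonePhantom(spc, center = c(boneCx, cy))
  x0 <- boneCx + R + 4
  rl <- rodLayout(data.frame(centerXMm = x0 + c(0, 6, 12), centerYMm = cy,
                             radiusMm = 2.2, density = c(0, 0.075, 0.15),
                             huMean = c(0, 75, 150)))
  vol <- embedRods(ph$volume, rl, mask = ph$mask)
  ## crop flush to the bone's axial extent
  zIdx <- which(apply(ph$mask@data, 3, sum) > 0)
  zr <- range(zIdx)
  keep <- zr[1]:zr[2]
  newOrigin <- gridOrigin(vol) + c(0, 0, (zr[1] - 1) * spacing)
  volC <- ctVolume(vol@data[, , keep, drop = FALSE], voxelSpacing(vol),
                   newOrigin, units = "HU")
  maskC <- boneMask(ph$mask@data[, , keep, drop = FALSE], voxelSpacing(vol),
                    newOrigin)
  list(volume = volC, mask = maskC, rodLayout = rl, outerRadiusMm = R,
       corticalThicknessMm = t, heightMm = h, spacing = spacing)
}

#' Measure mean intensity inside each calibration rod
#'
#' @inheritParams embedRods
#' @return Numeric vector of per-rod mean HU, in layout order.
#' @export
extractRodHU <- function(volume, layout) {
  validObject(layout)
  dm <- gridDim(volume)
  vapply(seq_len(nrow(layout@rods)), function(i) {
    reg <- .rodRegion(dm, voxelSpacing(volume), gridOrigin(volume), layout, i)
    mean(volume@data[reg])
  }, numeric(1))
}
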