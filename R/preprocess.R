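## Pre-processing chain: resampling to a common voxel size, splitting
## bilateral volumes, mirroring, affine co-registration, z-score
## normalisation.

.resampleArray <- function(a, spacing, targetSpacing, interpolation, fill) {
  dmIn <- dim(a)
  dmOut <- pmax(1L, as.integer(round(dmIn * spacing / targetSpacing)))
  ## centre-of-extent alignment: output voxel i samples input voxel coordinate
  ## (i - 0.5) * target/spacing + 0.5, so world extent is preserved.
  cx <- (seq_len(dmOut[1]) - 0.5) * targetSpacing[1] / spacing[1] + 0.5
  cy <- (seq_len(dmOut[2]) - 0.5) * targetSpacing[2] / spacing[2] + 0.5
  cz <- (seq_len(dmOut[3]) - 0.5) * targetSpacing[3] / spacing[3] + 0.5
  X <- array(cx, dmOut)
  Y <- array(rep(cy, each = dmOut[1]), dmOut)
  Z <- array(rep(cz, each = dmOut[1] * dmOut[2]), dmOut)
  vals <- if (interpolation == "linear")
    .interpTrilinear(a, as.vector(X), as.vector(Y), as.vector(Z), fill)
  else
    .interpNearest(a, as.vector(X), as.vector(Y), as.vector(Z), fill)
  array(vals, dmOut)
}

#' Resample a volume or mask to a target voxel size
#'
#' Output grid shape per axis is \code{round(extent_mm / target)} (minimum 1),
#' preserving the world extent to within one voxel. Volumes use trilinear
#' interpolation by default; masks always use nearest-neighbour so values stay
#' in \{0, 1\}.
#'
#' @param x a [CTVolume-class] or [BoneMask-class].
#' @param targetSpacing numeric(3), mm (default the study median,
#'   0.78 x 0.78 x 0.67 mm).
#' @param interpolation \code{"linear"} or \code{"nearest"}; ignored for
#'   masks (always nearest).
#' @return Object of the same class on the new grid.
#' @export
resampleVolume <- function(x, targetSpacing = c(0.78, 0.78, 0.67),
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  targetSpacing <- as.numeric(targetSpacing)
  if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3)
  if (any(!is.finite(targetSpacing)) || any(targetSpacing <= 0))
    stop("target spacing must be strictly positive", call. = FALSE)
  spacing <- voxelSpacing(x)
  origin <- gridOrigin(x)
  newOrigin <- origin - spacing / 2 + targetSpacing / 2
  if (is(x, "BoneMask")) {
    out <- .resampleArray(x@data, spacing, targetSpacing, "nearest", 0L)
    storage.mode(out) <- "integer"
    boneMask(out, targetSpacing, newOrigin)
  } else {
    fill <- min(x@data)
    out <- .resampleArray(x@data, spacing, targetSpacing, interpolation, fill)
    ctVolume(out, targetSpacing, newOrigin, units = intensityUnits(x))
  }
}

#' Mirror a volume or mask about one axis
#'
#' Applying the flip twice returns the original object.
#'
#' @param x a [CTVolume-class] or [BoneMask-class].
#' @param axis axis to mirror (1 = left-right by convention).
#' @return Flipped object on the same grid.
#' @export
flipVolume <- function(x, axis = 1L) {
  d <- dim(x@data)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- rev(idx[[axis]])
  out <- x@data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  if (is(x, "BoneMask")) boneMask(out, x@spacing, x@origin)
  else ctVolume(out, x@spacing, x@origin, units = x@units)
}

#' Split a bilateral volume and mirror the left side
#'
#' Detects exactly two disjoint bone components (thresholding at the midpoint
#' of the intensity range unless masks are supplied), splits the grid at the
#' mid-gap between the two components' x bounding boxes, and mirrors the
#' left-side (smaller world x) half so both outputs share the same anatomical
#' handedness.
#'
#' @param volume a [CTVolume-class] containing two bones.
#' @param maskPairHint optional list of two [BoneMask-class] objects; when
#'   given, component detection uses their union instead of thresholding.
#' @param threshold optional HU threshold for bone detection.
#' @return List with [CTVolume-class] elements \code{left} (mirrored) and
#'   \code{right}, plus \code{splitIndex}, the last x index of the left half.
#' @export
splitAndFlip <- function(volume, maskPairHint = NULL, threshold = NULL) {
  dat <- volume@data
  if (!is.null(maskPairHint)) {
    bone <- .maskLogical(maskPairHint[[1]]) | .maskLogical(maskPairHint[[2]])
  } else {
    if (is.null(threshold)) threshold <- (min(dat) + max(dat)) / 2
    bone <- dat >= threshold
  }
  comp <- .labelComponents(bone)
  ncomp <- length(comp$sizes)
  if (ncomp != 2L)
    stop(sprintf("expected 2 bone components, found %d", ncomp),
         call. = FALSE)
  xIdx <- arrayInd(which(comp$labels != 0L), dim(dat))[, 1]
  labs <- comp$labels[comp$labels != 0L]
  r1 <- range(xIdx[labs == 1L]); r2 <- range(xIdx[labs == 2L])
  if (r1[1] > r2[1]) { tmp <- r1; r1 <- r2; r2 <- tmp }
  if (r1[2] >= r2[1])
    stop("bone components are not separable by a sagittal plane",
         call. = FALSE)
  s <- floor((r1[2] + r2[1]) / 2)
  spacing <- volume@spacing; origin <- volume@origin
  leftDat <- dat[seq_len(s), , , drop = FALSE]
  rightDat <- dat[(s + 1):dim(dat)[1], , , drop = FALSE]
  left <- ctVolume(leftDat, spacing, origin, units = volume@units)
  rightOrigin <- origin + c(s * spacing[1], 0, 0)
  right <- ctVolume(rightDat, spacing, rightOrigin, units = volume@units)
  list(left = flipVolume(left, 1L), right = right, splitIndex = s)
}

## Mean-squared intensity difference between the reference and the moving
## volume pulled back through (M, t) about world centre `cen`.
.regCost <- function(par, refDat, refGrid, movDat, movSpacing, movOrigin,
                     cen, fill, mode) {
  if (mode == "translation") {
    M <- diag(3); tt <- par
  } else {
    M <- matrix(par[1:9], 3, 3); tt <- par[10:12]
  }
  P <- refGrid %*% t(M)                     # M %*% (x - cen) rowwise
  px <- (P[, 1] + cen[1] + tt[1] - movOrigin[1]) / movSpacing[1] + 1
  py <- (P[, 2] + cen[2] + tt[2] - movOrigin[2]) / movSpacing[2] + 1
  pz <- (P[, 3] + cen[3] + tt[3] - movOrigin[3]) / movSpacing[3] + 1
  v <- .interpTrilinear(movDat, px, py, pz, fill)
  mean((v - refDat)^2)
}

#' Affine registration by mean-squared intensity difference
#'
#' Multi-resolution (block-mean pyramid), translation-first then full affine,
#' quasi-Newton (BFGS) minimisation of the mean-squared difference, linear
#' interpolation. The recovered transform maps reference-space world
#' coordinates to moving-space coordinates (pull-back convention), so a
#' moving volume whose content is the reference shifted by +s mm yields a
#' translation close to +s.
#'
#' @param moving,reference [CTVolume-class] objects with overlapping world
#'   extents; both must have nonzero intensity variance.
#' @param mode \code{"affine"} (translation stage then 12-parameter affine)
#'   or \code{"translation"}.
#' @param levels number of pyramid levels (default 3).
#' @param maxit BFGS iteration cap per level.
#' @return List with \code{transform} ([AffineTransform-class]),
#'   \code{volume} (moving resampled into the reference grid) and
#'   \code{improved} (FALSE, with a warning, when optimisation could not beat
#'   the identity, in which case the identity transform is returned).
#' @export
registerAffine <- function(moving, reference, mode = c("affine", "translation"),
                           levels = 3L, maxit = 60L) {
  mode <- match.arg(mode)
  if (sd(reference@data) == 0 || sd(moving@data) == 0)
    stop("constant-intensity volume cannot be registered", call. = FALSE)
  refDim <- gridDim(reference)
  cen <- gridOrigin(reference) + (refDim - 1) * voxelSpacing(reference) / 2
  fill <- stats::median(c(moving@data[1, , ], moving@data[dim(moving@data)[1], , ],
                          moving@data[, 1, ], moving@data[, dim(moving@data)[2], ],
                          moving@data[, , 1], moving@data[, , dim(moving@data)[3]]))
  ## build pyramids from lightly smoothed copies (sharp tissue interfaces
  ## otherwise leave an interpolation-error floor in the MSE landscape that
  ## biases the optimum); the final resampled output uses the raw data
  pyr <- vector("list", levels)
  ref <- list(dat = .smooth3(reference@data), sp = voxelSpacing(reference),
              or = gridOrigin(reference))
  mov <- list(dat = .smooth3(moving@data), sp = voxelSpacing(moving),
              or = gridOrigin(moving))
  pyr[[1]] <- list(ref = ref, mov = mov)
  for (l in seq_len(levels - 1L)) {
    prev <- pyr[[l]]
    if (any(dim(prev$ref$dat) < 8L) || any(dim(prev$mov$dat) < 8L)) {
      pyr <- pyr[seq_len(l)]
      break
    }
    ds <- function(v) list(dat = .downsample2(v$dat), sp = v$sp * 2,
                           or = v$or + v$sp / 2)
    pyr[[l + 1L]] <- list(ref = ds(prev$ref), mov = ds(prev$mov))
  }
  levelData <- lapply(pyr, function(p) {
    dmr <- dim(p$ref$dat)
    grid <- .coordArrays(dmr, p$ref$sp, p$ref$or)
    list(refGrid = cbind(as.vector(grid$x) - cen[1],
                         as.vector(grid$y) - cen[2],
                         as.vector(grid$z) - cen[3]),
         refVec = as.vector(p$ref$dat), mov = p$mov)
  })
  ## translation stage, coarse to fine; the coarsest level is initialised by
  ## an exhaustive search over integer coarse-voxel shifts so BFGS starts in
  ## the global basin
  tPar <- c(0, 0, 0)
  lc <- levelData[[length(levelData)]]
  sgrid <- expand.grid(x = -3:3, y = -3:3, z = -3:3)
  sgrid <- sweep(as.matrix(sgrid), 2, lc$mov$sp, "*")
  costs <- apply(sgrid, 1, function(s)
    .regCost(s, lc$refVec, lc$refGrid, lc$mov$dat, lc$mov$sp, lc$mov$or,
             cen, fill, "translation"))
  tPar <- as.numeric(sgrid[which.min(costs), ])
  for (l in rev(seq_along(levelData))) {
    ld <- levelData[[l]]
    opt <- stats::optim(tPar, .regCost, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12,
                                       ndeps = rep(1e-4, 3L)),
                        refDat = ld$refVec, refGrid = ld$refGrid,
                        movDat = ld$mov$dat, movSpacing = ld$mov$sp,
                        movOrigin = ld$mov$or, cen = cen, fill = fill,
                        mode = "translation")
    tPar <- opt$par
  }
  if (mode == "affine") {
    ## full affine polish at the finest level, warm-started
    ld <- levelData[[1]]
    aPar <- c(as.vector(diag(3)), tPar)
    optA <- stats::optim(aPar, .regCost, method = "BFGS",
                         control = list(maxit = 3L * maxit, reltol = 1e-12,
                                        ndeps = rep(1e-4, 12L),
                                        parscale = c(rep(0.02, 9),
                                                     rep(1, 3))),
                         refDat = ld$refVec, refGrid = ld$refGrid,
                         movDat = ld$mov$dat, movSpacing = ld$mov$sp,
                         movOrigin = ld$mov$or, cen = cen, fill = fill,
                         mode = "affine")
    costT <- .regCost(tPar, ld$refVec, ld$refGrid, ld$mov$dat, ld$mov$sp,
                      ld$mov$or, cen, fill, "translation")
    if (optA$value <= costT) {
      M <- matrix(optA$par[1:9], 3, 3); tt <- optA$par[10:12]
    } else {
      ## the full affine fit lost to the translation-only fit (e.g. the
      ## degenerate map-to-background minimum); keep the translation
      M <- diag(3); tt <- tPar
    }
  } else {
    M <- diag(3); tt <- tPar
  }
  ## compare against identity on the full-resolution grid
  grid <- .coordArrays(refDim, voxelSpacing(reference), gridOrigin(reference))
  refGrid <- cbind(as.vector(grid$x) - cen[1], as.vector(grid$y) - cen[2],
                   as.vector(grid$z) - cen[3])
  refVec <- as.vector(reference@data)
  costId <- .regCost(c(0, 0, 0), refVec, refGrid, moving@data,
                     voxelSpacing(moving), gridOrigin(moving), cen, fill,
                     "translation")
  par <- c(as.vector(M), tt)
  costFit <- .regCost(par, refVec, refGrid, moving@data, voxelSpacing(moving),
                      gridOrigin(moving), cen, fill, "affine")
  improved <- costFit <= costId + 1e-12
  if (!improved) {
    warning("registration failed to improve on the identity transform")
    M <- diag(3); tt <- c(0, 0, 0)
  }
  ## fold the centre into the translation: x -> M (x - cen) + cen + t
  tWorld <- as.numeric(tt + cen - M %*% cen)
  P <- refGrid %*% t(M)
  px <- (P[, 1] + cen[1] + tt[1] - gridOrigin(moving)[1]) /
    voxelSpacing(moving)[1] + 1
  py <- (P[, 2] + cen[2] + tt[2] - gridOrigin(moving)[2]) /
    voxelSpacing(moving)[2] + 1
  pz <- (P[, 3] + cen[3] + tt[3] - gridOrigin(moving)[3]) /
    voxelSpacing(moving)[3] + 1
  resampled <- array(.interpTrilinear(moving@data, px, py, pz, fill), refDim)
  list(transform = affineTransform(M, tWorld),
       volume = ctVolume(resampled, voxelSpacing(reference),
                         gridOrigin(reference), units = moving@units),
       improved = improved)
}

#' Z-score intensity normalisation
#'
#' Subtracts the volume mean and divides by the volume standard deviation, so
#' the output has mean 0 and unit variance; invariant to positive affine
#' rescalings of the input intensities.
#'
#' @param volume a [CTVolume-class] with nonzero intensity variance.
#' @return A [CTVolume-class] with units \code{"normalized"}.
#' @export
normalizeIntensity <- function(volume) {
  s <- sd(volume@data)
  if (s == 0) stop("zero-variance volume cannot be normalized", call. = FALSE)
  ctVolume((volume@data - mean(volume@data)) / s, voxelSpacing(volume),
           gridOrigin(volume), units = "normalized")
}

#' Write / read an affine transform as a plain-text 4x4 matrix
#'
#' @param transform an [AffineTransform-class].
#' @param path file path.
#' @return \code{readAffine} returns an [AffineTransform-class].
#' @export
writeAffine <- function(transform, path) {
  H <- rbind(cbind(transform@matrix, transform@translation), c(0, 0, 0, 1))
  utils::write.table(H, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeAffine
#' @export
readAffine <- function(path) {
  H <- unname(as.matrix(utils::read.table(path)))
  affineTransform(H[1:3, 1:3], H[1:3, 4])
}
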