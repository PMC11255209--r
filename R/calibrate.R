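## QCT density calibration from phantom rods, and the density-to-elasticity
## laws: femoral power law E = 14900 rho^1.86 (MPa) and vertebral linear law
## E = 3230 rho - 34.7 (MPa), rho in g/cm^3.

#' Fit the HU-to-density calibration line
#'
#' Ordinary least squares of rod equivalent densities on measured rod HU
#' means. Densities must increase with HU; a non-positive fitted slope means
#' the phantom is inconsistent.
#'
#' @param rodHuMeans measured mean HU per rod.
#' @param rodDensities known equivalent densities, g/cm^3.
#' @return A [DensityCalibration-class].
#' @examples
#' fitHuDensity(c(0, 100, 200), c(0, 0.1, 0.2))
#' @export
fitHuDensity <- function(rodHuMeans, rodDensities) {
  if (length(rodHuMeans) != length(rodDensities) || length(rodHuMeans) < 2L)
    stop("need at least 2 rods with matching HU and density values",
         call. = FALSE)
  if (anyDuplicated(rodHuMeans))
    stop("duplicate rod HU values", call. = FALSE)
  fit <- lm(rodDensities ~ rodHuMeans)
  slope <- unname(coef(fit)[2])
  if (slope <= 0)
    stop("phantom inconsistent: fitted slope is not positive", call. = FALSE)
  ssTot <- sum((rodDensities - mean(rodDensities))^2)
  r2 <- if (ssTot > 0) 1 - sum(residuals(fit)^2) / ssTot else 1
  densityCalibration(slope, unname(coef(fit)[1]), min(max(r2, 0), 1))
}

#' Fit the calibration directly from rods embedded in a volume
#'
#' Measures each rod's mean HU with [extractRodHU()] and fits the line
#' against the layout's known densities.
#'
#' @inheritParams extractRodHU
#' @return A [DensityCalibration-class].
#' @export
calibrateFromRods <- function(volume, layout) {
  fitHuDensity(extractRodHU(volume, layout), layout@rods$density)
}

#' Convert a HU volume to QCT density
#'
#' Applies the calibration line voxelwise; negative calibrated densities
#' (air, marrow, soft tissue below the intercept crossing) are clamped to 0
#' so downstream elements cannot acquire negative stiffness.
#'
#' @param volume a [CTVolume-class] in HU.
#' @param calibration a [DensityCalibration-class].
#' @return A [CTVolume-class] with units \code{"g/cm3"}.
#' @export
huToDensity <- function(volume, calibration) {
  if (intensityUnits(volume) != "HU")
    stop("huToDensity expects a volume in HU", call. = FALSE)
  rho <- pmax(calibration@slope * volume@data + calibration@intercept, 0)
  ctVolume(rho, voxelSpacing(volume), gridOrigin(volume), units = "g/cm3")
}

#' Young's modulus from QCT density
#'
#' Femoral power law: E = coefficient * rho^exponent (14900 rho^1.86 MPa by
#' default). Vertebral linear law: E = coefficient * rho + offset
#' (3230 rho - 34.7 MPa). The result is floored at the law's \code{eFloor}
#' so zero-density voxels (clamped soft tissue) yield a tiny positive
#' stiffness rather than a singular element. Monotone non-decreasing in rho
#' for both families.
#'
#' @param rho density in g/cm^3 (vector allowed, all values >= 0).
#' @param law a [MaterialLaw-class].
#' @param floorModulus apply the eFloor clamp (default TRUE).
#' @return Young's modulus in MPa, same length as \code{rho}.
#' @examples
#' densityToModulus(1, femurLaw())      # 14900
#' densityToModulus(1, vertebraLaw())   # 3195.3
#' @export
densityToModulus <- function(rho, law, floorModulus = TRUE) {
  if (any(rho < 0)) stop("negative density", call. = FALSE)
  e <- if (law@kind == "femur_power") law@coefficient * rho^law@exponent
       else law@coefficient * rho + law@offset
  if (floorModulus) pmax(e, law@eFloor) else e
}

#' Serialise / restore a calibration as a small JSON sidecar
#'
#' @param calibration a [DensityCalibration-class].
#' @param path JSON file path.
#' @return \code{readCalibration} returns a [DensityCalibration-class].
#' @export
writeCalibration <- function(calibration, path) {
  jsonlite::write_json(list(slope = calibration@slope,
                            intercept = calibration@intercept,
                            r2 = calibration@fitR2),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  densityCalibration(x$slope, x$intercept, x$r2)
}
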