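## NIfTI-1 input/output via RNifti. Intensities are stored as 32-bit float,
## masks as 8-bit unsigned 0/1; spacing goes in pixdim and the origin in the
## qform translation.

.asNiftiGrid <- function(x) {
  img <- RNifti::asNifti(x@data)
  aff <- diag(c(x@spacing, 1))
  aff[1:3, 4] <- x@origin
  RNifti::`qform<-`(img, structure(aff, code = 2L))
}

#' Write a volume or mask as NIfTI-1
#'
#' @param x a [CTVolume-class] or [BoneMask-class].
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeVolume <- function(x, path) {
  img <- .asNiftiGrid(x)
  RNifti::writeNifti(img, path,
                     datatype = if (is(x, "BoneMask")) "uint8" else "float")
  invisible(path)
}

#' @rdname writeVolume
#' @export
writeMask <- writeVolume

#' Read a NIfTI-1 file as a volume or mask
#'
#' \code{readMask} validates that the file holds only 0/1 values.
#'
#' @param path NIfTI file path.
#' @param units intensity units to record on the volume.
#' @return A [CTVolume-class] (or [BoneMask-class] for \code{readMask}).
#' @export
readVolume <- function(path, units = "HU") {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  ctVolume(array(as.numeric(img), dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3],
           origin = aff[1:3, 4],
           units = units)
}

#' @rdname readVolume
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  boneMask(array(as.integer(img != 0), dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3],
           origin = aff[1:3, 4])
}
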