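## Voxel-based hexahedral meshing and the trilinear brick element.
##
## Local node order (natural coordinates): (0,0,0) (1,0,0) (1,1,0) (0,1,0)
## (0,0,1) (1,0,1) (1,1,1) (0,1,1) in voxel-corner offsets; dof order is
## (ux, uy, uz) per node. Voigt strain order: (exx, eyy, ezz, gxy, gyz, gxz)
## with engineering shear.

.hexNatural <- rbind(
  c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
  c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))

## Strain-displacement matrices at the 2x2x2 Gauss points of an
## axis-aligned box of edge lengths `dims`; weight = det(J) (Gauss w = 1).
.hexBmats <- function(dims) {
  gp <- .hexNatural / sqrt(3)
  Bs <- vector("list", 8L)
  for (g in 1:8) {
    xi <- gp[g, ]
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      ni <- .hexNatural[i, ]
      dN <- c(ni[1] * (1 + xi[2] * ni[2]) * (1 + xi[3] * ni[3]) / 8 * 2 / dims[1],
              ni[2] * (1 + xi[1] * ni[1]) * (1 + xi[3] * ni[3]) / 8 * 2 / dims[2],
              ni[3] * (1 + xi[1] * ni[1]) * (1 + xi[2] * ni[2]) / 8 * 2 / dims[3])
      c0 <- 3L * (i - 1L)
      B[1, c0 + 1] <- dN[1]
      B[2, c0 + 2] <- dN[2]
      B[3, c0 + 3] <- dN[3]
      B[4, c0 + 1] <- dN[2]; B[4, c0 + 2] <- dN[1]
      B[5, c0 + 2] <- dN[3]; B[5, c0 + 3] <- dN[2]
      B[6, c0 + 1] <- dN[3]; B[6, c0 + 3] <- dN[1]
    }
    Bs[[g]] <- B
  }
  list(B = Bs, w = prod(dims) / 8)
}

.isotropicD <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  G <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * G
  diag(D)[4:6] <- G
  D
}

#' Stiffness matrix of one voxel hexahedron
#'
#' Trilinear 8-node brick with 2x2x2 Gauss quadrature for an isotropic
#' linear-elastic material. The block is symmetric positive-semidefinite with
#' exactly six rigid-body zero-energy modes, and scales linearly with the
#' modulus.
#'
#' @param modulus Young's modulus, MPa (> 0).
#' @param poisson Poisson ratio in [0, 0.5).
#' @param voxelDims element edge lengths, mm.
#' @return 24 x 24 stiffness matrix (N/mm with MPa-mm units).
#' @export
elementStiffness <- function(modulus, poisson = 0.3, voxelDims = c(1, 1, 1)) {
  if (modulus <= 0) stop("modulus must be positive", call. = FALSE)
  if (any(voxelDims <= 0) || any(!is.finite(voxelDims)))
    stop("degenerate voxel dims", call. = FALSE)
  if (poisson < 0 || poisson >= 0.5)
    stop("poisson must lie in [0, 0.5)", call. = FALSE)
  bm <- .hexBmats(voxelDims)
  D <- .isotropicD(modulus, poisson)
  K <- matrix(0, 24, 24)
  for (g in 1:8) K <- K + bm$w * crossprod(bm$B[[g]], D %*% bm$B[[g]])
  (K + t(K)) / 2
}

#' Build a voxel hexahedral mesh from a mask and a density volume
#'
#' One brick element per in-mask voxel, nodes shared between adjacent voxels.
#' Each element carries the voxel's calibrated density and the Young's
#' modulus given by the material law. A disconnected mask triggers a warning
#' and only the largest connected component is meshed (so eroded masks that
#' fragment still solve).
#'
#' @param mask a nonempty [BoneMask-class].
#' @param density a [CTVolume-class] of QCT densities (g/cm^3) on the same
#'   grid.
#' @param law a [MaterialLaw-class] mapping density to modulus.
#' @return A [HexMesh-class].
#' @examples
#' d <- ctVolume(array(1, c(2, 2, 2)), spacing = c(1, 1, 1), units = "g/cm3")
#' m <- boneMask(array(1L, c(2, 2, 2)), spacing = c(1, 1, 1))
#' buildHexMesh(m, d, femurLaw())  # 8 elements, 27 nodes
#' @export
buildHexMesh <- function(mask, density, law = femurLaw()) {
  if (!all(gridDim(mask) == gridDim(density)) ||
      !isTRUE(all.equal(voxelSpacing(mask), voxelSpacing(density))))
    stop("mask and density volume must share grid and spacing",
         call. = FALSE)
  m <- .maskLogical(mask)
  if (!any(m)) stop("empty mask cannot be meshed", call. = FALSE)
  comp <- .labelComponents(m)
  if (length(comp$sizes) > 1L) {
    warning(sprintf(
      "mask has %d connected components; keeping the largest (%d voxels)",
      length(comp$sizes), max(comp$sizes)))
    m <- comp$labels == which.max(comp$sizes)
  }
  dm <- dim(m)
  vox <- arrayInd(which(m), dm)
  nx1 <- dm[1] + 1L; ny1 <- dm[2] + 1L
  corner <- function(a, b, c)
    (vox[, 1] - 1L + a) + (vox[, 2] - 1L + b) * nx1 +
      (vox[, 3] - 1L + c) * nx1 * ny1 + 1L
  conn <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L), corner(1L, 1L, 0L),
                corner(0L, 1L, 0L), corner(0L, 0L, 1L), corner(1L, 0L, 1L),
                corner(1L, 1L, 1L), corner(0L, 1L, 1L))
  uid <- sort(unique(as.vector(conn)))
  remap <- integer(nx1 * ny1 * (dm[3] + 1L))
  remap[uid] <- seq_along(uid)
  elements <- matrix(remap[conn], ncol = 8L)
  storage.mode(elements) <- "integer"
  lat <- uid - 1L
  iz <- lat %/% (nx1 * ny1)
  iy <- (lat %% (nx1 * ny1)) %/% nx1
  ix <- lat %% nx1
  sp <- voxelSpacing(mask); or <- gridOrigin(mask)
  nodes <- cbind(or[1] + (ix - 0.5) * sp[1],
                 or[2] + (iy - 0.5) * sp[2],
                 or[3] + (iz - 0.5) * sp[3])
  dens <- density@data[m]
  new("HexMesh", nodes = nodes, elements = elements,
      elementDensity = as.numeric(dens),
      elementModulus = densityToModulus(as.numeric(dens), law),
      spacing = sp, law = law)
}

#' Export a mesh as legacy-ASCII VTK
#'
#' Writes an unstructured grid of hexahedron cells with per-cell density and
#' modulus fields, readable by ParaView and meshio.
#'
#' @param mesh a [HexMesh-class].
#' @param path output file (.vtk).
#' @return The path, invisibly.
#' @export
writeMeshVTK <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh@nodes); m <- nrow(mesh@elements)
  writeLines(c("# vtk DataFile Version 3.0", "voxel hexahedral bone mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(mesh@nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 9L * m), con)
  utils::write.table(cbind(8L, mesh@elements - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS density double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(mesh@elementDensity, digits = 10), con)
  writeLines(c("SCALARS modulus double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(mesh@elementModulus, digits = 10), con)
  invisible(path)
}
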