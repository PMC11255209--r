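# Shared fixtures, all built in code at test time.

# Solid cube of side n inside a grid with a one-voxel margin.
cubeMask <- function(n, spacing = c(1, 1, 1), pad = 1L) {
  d <- rep(n + 2L * pad, 3L)
  a <- array(0L, d)
  idx <- (pad + 1L):(pad + n)
  a[idx, idx, idx] <- 1L
  boneMask(a, spacing)
}

# Small noiseless femur-like phantom (fast default for most tests).
smallFemurSpec <- function(noiseSd = 0, seed = 1L) {
  phantomSpec("femur", spacing = c(1, 1, 1), outerRadiusMm = 6,
              corticalThicknessMm = 2, heightMm = 25, noiseSd = noiseSd,
              seed = seed)
}

# Homogeneous column phantom: constant-density volume + all-ones mask.
columnFixture <- function(nx, ny, nz, rho = 1, spacing = c(1, 1, 1)) {
  list(density = ctVolume(array(rho, c(nx, ny, nz)), spacing,
                          units = "g/cm3"),
       mask = boneMask(array(1L, c(nx, ny, nz)), spacing))
}

# Registration scene: femur plus one off-axis rod (breaks axisymmetry),
# generous soft-tissue margins so shifted content never clips structure.
registrationScene <- function(marginMm = 12, spacing = 1.5) {
  sp <- phantomSpec("femur", spacing = rep(spacing, 3), outerRadiusMm = 8,
                    corticalThicknessMm = 2.5, heightMm = 26)
  ex <- as.integer(ceiling(marginMm / spacing))
  sp@gridShape <- sp@gridShape + c(2L * ex + 8L, 2L * ex, 2L * ex)
  boneCx <- marginMm + 8
  cy <- (sp@gridShape[2] - 1) * spacing / 2
  ph <- generateBonePhantom(sp, center = c(boneCx, cy))
  vol <- ph$volume
  co <- bonefail:::.coordArrays(gridDim(vol), voxelSpacing(vol),
                                gridOrigin(vol))
  rod <- (co$x - (boneCx + 13))^2 + (co$y - (cy + 3))^2 <= 2.5^2
  dat <- volData(vol)
  dat[rod] <- 900
  ctVolume(dat, voxelSpacing(vol), gridOrigin(vol))
}

# Content-shift of a volume by s mm (new volume on the same grid).
shiftScene <- function(ref, s, fill = 40) {
  d <- gridDim(ref)
  spc <- voxelSpacing(ref)
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  vals <- bonefail:::.interpTrilinear(volData(ref), co$x - s[1] / spc[1],
                                      co$y - s[2] / spc[2],
                                      co$z - s[3] / spc[3], fill = fill)
  ctVolume(array(vals, d), spc, gridOrigin(ref))
}

# Tie-aware from-scratch Friedman statistic (midranks, tie-corrected
# denominator) used as the independent oracle.
friedmanOracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1L, rank))
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  ties <- unlist(lapply(seq_len(n), function(i) table(m[i, ])))
  den <- n * k * (k + 1) - sum(ties^3 - ties) / (k - 1)
  num / den
}

# The sensitivity-study pipeline configuration used across tests: pinned
# (frictionless) platens, BC layer covering the femoral dome, displacement
# deep enough that the failure load is collapse-dominated.
sensitivityConfig <- function(cs, stepFrac = 0.005, maxFrac = 0.02) {
  pipelineConfig("femur", rodLayout = cs$rodLayout, stepFrac = stepFrac,
                 maxFrac = maxFrac, support = "pinned",
                 bcLayerVoxels = (cs$outerRadiusMm + 3.5 * cs$spacing) /
                   cs$spacing)
}
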