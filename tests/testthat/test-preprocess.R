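test_that("resampling preserves extent, identity and constants", {
  a <- array(rnorm(20 * 18 * 16, 500, 100), c(20, 18, 16))
  v <- ctVolume(a, spacing = c(1.56, 1.56, 1.34))
  out <- resampleVolume(v, c(0.78, 0.78, 0.67))
  expect_equal(gridDim(out), c(40, 36, 32))             # dimensions double
  expect_equal(gridDim(out) * voxelSpacing(out),
               gridDim(v) * voxelSpacing(v))            # world extent kept
  # identity: same target spacing returns the input voxelwise
  same <- resampleVolume(v, c(1.56, 1.56, 1.34))
  expect_equal(volData(same), a)
  # interpolating a constant gives the same constant
  cst <- resampleVolume(ctVolume(array(7, c(9, 9, 9)), c(1, 1, 1)),
                        c(0.4, 0.4, 0.4))
  expect_true(all(abs(volData(cst) - 7) < 1e-10))
  expect_error(resampleVolume(v, c(0, 1, 1)), "positive")
})

test_that("mask resampling is nearest-neighbour, binary and idempotent", {
  m <- perturbMask(cubeMask(8, spacing = c(1, 1, 1)), op = "none")
  r1 <- resampleVolume(m, c(0.5, 0.5, 0.5))
  expect_true(all(volData(r1) %in% c(0L, 1L)))
  expect_s4_class(r1, "BoneMask")
  r2 <- resampleVolume(r1, c(0.5, 0.5, 0.5))
  expect_lt(max(abs(volData(r2) - volData(r1))), 1e-6)
})

test_that("split-and-flip separates mirror femurs into identical halves", {
  sp <- smallFemurSpec()
  hip <- generateHipVolume(sp, sp, gapMm = 16)
  # make the grid x-even and symmetric: construction already symmetric
  out <- splitAndFlip(hip$volume)
  expect_equal(dim(volData(out$left)), dim(volData(out$right)))
  expect_equal(volData(out$left), volData(out$right))   # mirror symmetry
  # each half holds exactly one bone component
  thr <- (min(volData(out$left)) + max(volData(out$left))) / 2
  compL <- bonefail:::.labelComponents(volData(out$left) >= thr)
  compR <- bonefail:::.labelComponents(volData(out$right) >= thr)
  expect_length(compL$sizes, 1L)
  expect_length(compR$sizes, 1L)
  # total bone voxel count conserved across the split
  nIn <- sum(volData(hip$volume) >= thr)
  expect_identical(sum(volData(out$left) >= thr) +
                     sum(volData(out$right) >= thr), nIn)
  # single-bone input is rejected with the component count
  single <- generateBonePhantom(sp)$volume
  expect_error(splitAndFlip(single), "found 1")
})

test_that("flipping is an involution", {
  v <- generateBonePhantom(smallFemurSpec(noiseSd = 5))$volume
  expect_equal(volData(flipVolume(flipVolume(v))), volData(v))
})

test_that("affine registration recovers known translations and scalings", {
  ref <- registrationScene()
  cen <- gridOrigin(ref) + (gridDim(ref) - 1) * voxelSpacing(ref) / 2
  for (s in list(c(5, 0, 0), c(-3, 4, 2))) {
    out <- registerAffine(shiftScene(ref, s), ref)
    tf <- out$transform
    recovered <- as.numeric(tf@matrix %*% cen + tf@translation) - cen
    expect_lt(sqrt(sum((recovered - s)^2)), 0.5)
  }
  # moving == reference: transform within tolerance of the identity
  out <- registerAffine(ref, ref)
  expect_lt(max(abs(out$transform@matrix - diag(3))), 0.01)
  expect_lt(max(abs(out$transform@translation)), 0.1)
  # content scaled about the centre: determinant of the recovered linear
  # part within 5% of the inverse scaling
  d <- gridDim(ref)
  spc <- voxelSpacing(ref)
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  w <- cbind((co$x - 1) * spc[1], (co$y - 1) * spc[2], (co$z - 1) * spc[3])
  pts <- sweep(sweep(w, 2, cen) * 1.1, 2, cen, "+")
  vals <- bonefail:::.interpTrilinear(volData(ref), pts[, 1] / spc[1] + 1,
                                      pts[, 2] / spc[2] + 1,
                                      pts[, 3] / spc[3] + 1, fill = 40)
  mov <- ctVolume(array(vals, d), spc, gridOrigin(ref))
  out <- registerAffine(mov, ref)
  expect_lt(abs(det(out$transform@matrix) - 1 / 1.1^3) / (1 / 1.1^3), 0.05)
  # constant input is rejected
  cst <- ctVolume(array(1, c(8, 8, 8)), c(1, 1, 1))
  expect_error(registerAffine(cst, ref), "constant")
})

test_that("z-score normalisation has exact moments and affine invariance", {
  v <- ctVolume(array(rnorm(8000, 500, 100), c(20, 20, 20)))
  n <- normalizeIntensity(v)
  expect_lt(abs(mean(volData(n))), 1e-6)
  expect_lt(abs(sd(volData(n)) - 1), 1e-6)
  expect_identical(intensityUnits(n), "normalized")
  # invariance under positive affine intensity maps
  v2 <- ctVolume(3.2 * volData(v) + 100, voxelSpacing(v))
  expect_equal(volData(normalizeIntensity(v2)), volData(n))
  expect_error(normalizeIntensity(ctVolume(array(5, c(4, 4, 4)))),
               "zero-variance")
})

test_that("affine transforms round-trip through the plain-text sidecar", {
  tf <- affineTransform(matrix(c(1.1, 0, 0, 0.05, 0.9, 0, 0, 0, 1), 3, 3),
                        c(-4.5, 2, 0.25))
  path <- tempfile(fileext = ".txt")
  writeAffine(tf, path)
  back <- readAffine(path)
  expect_equal(back@matrix, tf@matrix)
  expect_equal(back@translation, tf@translation)
})
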