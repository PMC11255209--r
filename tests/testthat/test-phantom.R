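test_that("noiseless phantoms take exact tissue-class means and are reproducible", {
  sp <- smallFemurSpec()
  ph <- generateBonePhantom(sp)
  vol <- volData(ph$volume)
  d <- gridDim(ph$volume)
  # voxel at the cortical mid-shell: bone axis at grid centre, radius R - t/2
  cx <- (d[1] - 1) / 2 + 1
  cy <- (d[2] - 1) / 2 + 1
  midShellX <- round(cx + (sp@outerRadiusMm - sp@corticalThicknessMm / 2))
  zMid <- round(d[3] / 2)
  expect_identical(vol[midShellX, round(cy), zMid], sp@huCortical)
  # interior trabecular voxel between the marrow canal and the shell
  trabX <- round(cx + (sp@marrowRadiusMm + sp@outerRadiusMm -
                         sp@corticalThicknessMm) / 2)
  expect_identical(vol[trabX, round(cy), zMid], sp@huTrabecular)
  # background
  expect_identical(vol[1, 1, 1], sp@huSoftTissue)
  # only the configured class means appear
  expect_setequal(unique(as.vector(vol)),
                  c(sp@huSoftTissue, sp@huCortical, sp@huTrabecular,
                    sp@huMarrow))
  # bit-identical reruns, with and without noise
  expect_identical(ph, generateBonePhantom(sp))
  spN <- smallFemurSpec(noiseSd = 12, seed = 42L)
  expect_identical(generateBonePhantom(spN), generateBonePhantom(spN))
  expect_false(identical(volData(generateBonePhantom(spN)$volume), vol))
})

test_that("thresholding a noiseless phantom recovers the ground-truth mask", {
  # raw threshold on a canal-free phantom (the marrow canal sits below any
  # bone threshold by construction and needs the hole-filling of
  # segmentBone, tested in test-segment.R)
  sp <- smallFemurSpec()
  sp@marrowRadiusMm <- 0
  ph <- generateBonePhantom(sp)
  thr <- (40 + 300) / 2
  rec <- boneMask(array(as.integer(volData(ph$volume) >= thr),
                        gridDim(ph$volume)),
                  voxelSpacing(ph$volume))
  expect_gte(diceCoefficient(rec, ph$mask), 0.99)
})

test_that("lesions reassign the expected sphere volume and never alter the mask", {
  sp <- phantomSpec("vertebra", spacing = c(1, 1, 1), outerRadiusMm = 8,
                    corticalThicknessMm = 1, heightMm = 20)
  base <- generateBonePhantom(sp)
  ctr <- round(gridDim(base$volume) / 2)
  les <- lesionSpec(center = ctr, radiusMm = 3, huLesion = 15)
  ph <- generateBonePhantom(sp, lesions = list(les))
  nReassigned <- sum(volData(ph$volume) == 15)
  expect_lt(abs(nReassigned - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.15)
  expect_identical(volData(ph$mask), volData(base$mask))
  # lesion centred outside the bone errors
  expect_error(generateBonePhantom(sp, lesions = list(
    lesionSpec(c(1, 1, 1), 3, 15))), "outside the bone")
})

test_that("geometry that cannot fit the grid errors naming the axis", {
  sp <- smallFemurSpec()
  sp@gridShape <- c(sp@gridShape[1], sp@gridShape[2], 10L)
  expect_error(generateBonePhantom(sp), "along z")
  sp2 <- smallFemurSpec()
  sp2@gridShape <- c(8L, sp2@gridShape[2], sp2@gridShape[3])
  expect_error(generateBonePhantom(sp2), "along x")
})

test_that("hip volumes hold two disjoint mirror-symmetric bones at the requested gap", {
  sp <- smallFemurSpec()
  hip <- generateHipVolume(sp, sp, gapMm = 20)
  L <- volData(hip$leftMask)
  R <- volData(hip$rightMask)
  expect_identical(sum(L), sum(R))                       # symmetry
  expect_identical(sum(L * R), 0L)                       # disjoint
  # brute-force nearest pair across the two masks, world units
  spn <- voxelSpacing(hip$volume)
  a <- sweep(arrayInd(which(L == 1L), dim(L)) - 1, 2, spn, "*")
  b <- sweep(arrayInd(which(R == 1L), dim(R)) - 1, 2, spn, "*")
  bx <- range(b[, 1])
  near <- b[b[, 1] <= bx[1] + 2, , drop = FALSE]        # facing surface only
  ax <- range(a[, 1])
  aNear <- a[a[, 1] >= ax[2] - 2, , drop = FALSE]
  d2 <- outer(rowSums(aNear^2), rowSums(near^2), "+") -
    2 * aNear %*% t(near)
  expect_gte(sqrt(min(d2)), 20)
  expect_error(generateHipVolume(sp, sp, gapMm = -1), "overlap")
})

test_that("embedded rods carry their mean HU over the expected cylinder volume", {
  sp <- phantomSpec("vertebra", spacing = c(1, 1, 1), outerRadiusMm = 6,
                    corticalThicknessMm = 1, heightMm = 16,
                    gridShape = c(40L, 20L, 22L))
  cy <- (20 - 1) / 2
  ph <- generateBonePhantom(sp, center = c(10, cy))
  rl <- rodLayout(data.frame(centerXMm = c(24, 32), centerYMm = cy,
                             radiusMm = 4, density = c(0.1, 0.2),
                             huMean = c(100, 200)))
  out <- embedRods(ph$volume, rl, mask = ph$mask)
  dat <- volData(out)
  for (i in 1:2) {
    reg <- bonefail:::.rodRegion(gridDim(out), voxelSpacing(out),
                                 gridOrigin(out), rl, i)
    expect_equal(mean(dat[reg]), rl@rods$huMean[i])
    # discretised cylinder volume within 15% of pi r^2 L
    expect_lt(abs(sum(reg) - pi * 16 * 22) / (pi * 16 * 22), 0.15)
  }
  # non-rod voxels untouched
  anyRod <- bonefail:::.rodRegion(gridDim(out), voxelSpacing(out),
                                  gridOrigin(out), rl, 1) |
    bonefail:::.rodRegion(gridDim(out), voxelSpacing(out),
                          gridOrigin(out), rl, 2)
  expect_identical(dat[!anyRod], volData(ph$volume)[!anyRod])
  # a rod through the bone errors
  rlBad <- rodLayout(data.frame(centerXMm = c(10, 32), centerYMm = cy,
                                radiusMm = 4, density = c(0.1, 0.2),
                                huMean = c(100, 200)))
  expect_error(embedRods(ph$volume, rlBad, mask = ph$mask), "intersects")
  expect_equal(extractRodHU(out, rl), c(100, 200))
})

test_that("phantom and rod specifications enforce their invariants", {
  expect_error(phantomSpec("femur", outerRadiusMm = 2,
                           corticalThicknessMm = 3),
               "corticalThicknessMm")
  expect_error(phantomSpec("femur", huTrabecular = 20, huSoftTissue = 40),
               "huCortical")
  expect_error(rodLayout(data.frame(centerXMm = 1:2, centerYMm = 1,
                                    radiusMm = 1, density = c(0.2, 0.1),
                                    huMean = c(200, 100))),
               "strictly increasing")
})
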