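test_that("threshold segmentation recovers the phantom ground truth", {
  ph <- generateBonePhantom(smallFemurSpec())
  seg <- segmentBone(ph$volume, huThreshold = 170)
  expect_gte(diceCoefficient(seg, ph$mask), 0.99)
  # the marrow canal (HU 0, below threshold) must be filled as a cavity
  expect_identical(volData(seg), volData(ph$mask))
  # all-background volume: nothing to find
  bg <- ctVolume(array(40, c(8, 8, 8)), c(1, 1, 1))
  expect_error(segmentBone(bg, 170), "no bone found")
  # threshold below the global minimum: everything is bone
  all1 <- segmentBone(ph$volume, huThreshold = min(volData(ph$volume)) - 1)
  expect_identical(sum(volData(all1)), as.integer(prod(gridDim(ph$volume))))
  # normalized volumes are refused
  expect_error(segmentBone(normalizeIntensity(ph$volume), 0.5), "HU")
})

test_that("post-processing removes small islands but keeps the main body", {
  m <- cubeMask(20, pad = 3L)
  a <- volData(m)
  a[2, 2, 2] <- 1L                       # isolated voxel far from the cube
  noisy <- boneMask(a, voxelSpacing(m))
  clean <- postprocessMask(noisy, minIslandVoxels = 5L)
  expect_identical(volData(clean)[2, 2, 2], 0L)
  # opening trims the cube's edges by less than 5%
  expect_lt(abs(voxelCount(clean) - 20^3) / 20^3, 0.05)
  expect_identical(length(bonefail:::.labelComponents(
    bonefail:::.maskLogical(clean))$sizes), 1L)
  # empty in, empty out
  empty <- boneMask(array(0L, c(6, 6, 6)), c(1, 1, 1))
  expect_identical(voxelCount(postprocessMask(empty)), 0L)
  # a mask with one component and no islands keeps one component
  solo <- postprocessMask(cubeMask(10), minIslandVoxels = 5L)
  expect_identical(length(bonefail:::.labelComponents(
    bonefail:::.maskLogical(solo))$sizes), 1L)
  # output contained in the dilation of the input
  dil <- perturbMask(noisy, op = "dilate", iterations = 1)
  expect_true(all(volData(clean) <= volData(dil)))
})

test_that("erosion and dilation act one literal voxel layer per iteration", {
  cube <- cubeMask(10)
  er <- perturbMask(cube, op = "erode", iterations = 1)
  expect_identical(voxelCount(er), 512L)               # 8^3
  er2 <- perturbMask(cube, op = "erode", iterations = 2)
  expect_identical(voxelCount(er2), 216L)              # 6^3
  # identity cases
  expect_identical(volData(perturbMask(cube, op = "none")), volData(cube))
  expect_identical(volData(perturbMask(cube, op = "erode", iterations = 0)),
                   volData(cube))
  # closing a convex voxel solid recovers it exactly
  closed <- perturbMask(perturbMask(cube, op = "dilate", iterations = 1),
                        op = "erode", iterations = 1)
  expect_identical(volData(closed), volData(cube))
  # erosion that wipes the mask out is an error
  tiny <- cubeMask(2)
  expect_error(perturbMask(tiny, op = "erode", iterations = 2), "vanished")
})

test_that("perturbation sizes are monotone and nested across the study grid", {
  ph <- generateBonePhantom(smallFemurSpec())
  m <- ph$mask
  counts <- sapply(list(c("erode", 2), c("erode", 1), c("none", 0),
                        c("dilate", 1), c("dilate", 2)), function(v)
    voxelCount(perturbMask(m, op = v[1], iterations = as.integer(v[2]))))
  expect_true(all(diff(counts) >= 0))
  # nesting: erode(m) inside m inside dilate(m)
  er <- perturbMask(m, op = "erode", iterations = 1)
  di <- perturbMask(m, op = "dilate", iterations = 1)
  expect_true(all(volData(er) <= volData(m)))
  expect_true(all(volData(m) <= volData(di)))
  # Dice against the original is non-increasing in iterations
  dsc <- function(op, it)
    diceCoefficient(perturbMask(m, op = op, iterations = it), m)
  expect_gte(dsc("erode", 1), dsc("erode", 2))
  expect_gte(dsc("dilate", 1), dsc("dilate", 2))
})

test_that("perturbation commutes with axis-aligned mirroring", {
  ph <- generateBonePhantom(smallFemurSpec(noiseSd = 0, seed = 3L))
  m <- ph$mask
  for (op in c("erode", "dilate")) {
    a <- flipVolume(perturbMask(m, op = op, iterations = 2), 1L)
    b <- perturbMask(flipVolume(m, 1L), op = op, iterations = 2)
    expect_identical(volData(a), volData(b))
  }
})

test_that("the 26-connected structuring element is offered and is stronger", {
  cube <- cubeMask(10)
  er6 <- perturbMask(cube, op = "erode", iterations = 1, connectivity = 6L)
  er26 <- perturbMask(cube, op = "erode", iterations = 1, connectivity = 26L)
  expect_identical(voxelCount(er26), 512L)   # same on a cube
  di26 <- perturbMask(cube, op = "dilate", iterations = 1,
                      connectivity = 26L)
  di6 <- perturbMask(cube, op = "dilate", iterations = 1, connectivity = 6L)
  expect_gt(voxelCount(di26), voxelCount(di6))
})
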