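test_that("Dice coefficient matches direct voxel counting", {
  cube <- cubeMask(10)
  er <- perturbMask(cube, op = "erode", iterations = 1)
  expect_identical(diceCoefficient(cube, cube), 1)
  expect_identical(diceCoefficient(cube, er), 2 * 512 / (512 + 1000))
  expect_identical(diceCoefficient(er, cube), diceCoefficient(cube, er))
  # disjoint masks
  a <- array(0L, c(6, 6, 6)); a[1:2, , ] <- 1L
  b <- array(0L, c(6, 6, 6)); b[5:6, , ] <- 1L
  expect_identical(diceCoefficient(boneMask(a, c(1, 1, 1)),
                                   boneMask(b, c(1, 1, 1))), 0)
  # both empty agree perfectly; mismatched grids error
  e <- boneMask(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_identical(diceCoefficient(e, e), 1)
  expect_error(diceCoefficient(cube, e), "shape")
})

test_that("Hausdorff distance is exact on constructed masks, in mm", {
  # two single voxels 3 voxels apart along x at 0.78 mm spacing
  a <- array(0L, c(8, 4, 4)); a[2, 2, 2] <- 1L
  b <- array(0L, c(8, 4, 4)); b[5, 2, 2] <- 1L
  sp <- c(0.78, 0.78, 0.67)
  expect_equal(hausdorffDistance(boneMask(a, sp), boneMask(b, sp)),
               3 * 0.78)
  # identical masks
  cube <- cubeMask(10)
  expect_identical(hausdorffDistance(cube, cube), 0)
  # cube vs its erosion: corner of the original to the nearest surviving
  # voxel is sqrt(3) at unit spacing
  er <- perturbMask(cube, op = "erode", iterations = 1)
  expect_equal(hausdorffDistance(cube, er), sqrt(3))
  expect_equal(hausdorffDistance(er, cube), hausdorffDistance(cube, er))
  # translation of an isolated shape by d gives exactly |d|
  c1 <- array(0L, c(12, 8, 8)); c1[2:3, 2:3, 2:3] <- 1L
  c2 <- array(0L, c(12, 8, 8)); c2[7:8, 2:3, 2:3] <- 1L
  expect_equal(hausdorffDistance(boneMask(c1, c(1, 1, 1)),
                                 boneMask(c2, c(1, 1, 1))), 5)
  # empty masks are an error; percentile variant is bounded by the max
  e <- boneMask(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_error(hausdorffDistance(cube, boneMask(array(0L, dim(volData(cube))),
                                                c(1, 1, 1))), "empty")
  expect_lte(hausdorffDistance(cube, er, percentile = 0.95),
             hausdorffDistance(cube, er))
  met <- maskMetrics(cube, er)
  expect_equal(met@dsc, 1024 / 1512)
  expect_equal(met@hdMm, sqrt(3))
})

test_that("Friedman test matches a from-scratch rank computation", {
  # all columns identical: complete ties, no evidence
  m <- matrix(rep(c(3, 1, 4, 1, 5), 3), ncol = 3)
  ft <- friedmanTest(m)
  expect_identical(unname(ft$statistic), 0)
  expect_identical(ft$p.value, 1)
  # consistent column ordering in every row, n = 10, k = 3: statistic 2n
  m2 <- matrix(rep(c(1, 2, 3), each = 10), ncol = 3) +
    matrix(rep(seq(0, 0.9, 0.1), 3), ncol = 3) * 0.01
  ft2 <- friedmanTest(m2)
  expect_equal(unname(ft2$statistic), 20)
  expect_equal(unname(ft2$parameter), 2)
  # oracle equivalence on random small integer matrices with ties
  set.seed(11)
  for (i in 1:200) {
    mm <- matrix(sample(1:3, 9, replace = TRUE), 3, 3)
    if (all(apply(mm, 1, function(x) length(unique(x))) == 1)) next
    expect_equal(unname(friedmanTest(mm)$statistic), friedmanOracle(mm))
  }
  expect_error(friedmanTest(matrix(1:5, ncol = 1)), "2 conditions")
  expect_error(friedmanTest(matrix(c(1, 2, NA, 4), 2, 2)), "missing")
})

test_that("Dunn post-hoc flags dominated conditions against the reference", {
  # identical columns: nothing to detect
  m <- matrix(rep(c(2, 7, 1, 9), 3), ncol = 3)
  d <- dunnPosthoc(m, referenceColumn = 1)
  expect_true(all(d$p.adjusted == 1))
  # one condition stochastically below the reference in every row, n = 12
  set.seed(21)
  base <- rnorm(12, 10)
  m2 <- cbind(ref = base, low = base - 2, other = base + rnorm(12, 0, 0.1))
  d2 <- dunnPosthoc(m2, referenceColumn = 1)
  expect_lt(d2$p.adjusted[d2$comparison == "low vs ref"], 0.05)
  # k = 2: the single comparison needs no multiplicity adjustment
  d3 <- dunnPosthoc(m2[, 1:2], referenceColumn = 1)
  expect_identical(d3$p, d3$p.adjusted)
  # z sign reflects the direction of the mean-rank difference
  expect_lt(d2$z[d2$comparison == "low vs ref"], 0)
})

test_that("the exact permutation p matches brute-force enumeration", {
  # brute force: enumerate all k!^n rank assignments for n = 3, k = 3
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3, byrow = TRUE)
  bruteP <- function(m) {
    obs <- friedmanOracle(m)
    tot <- 0L; ge <- 0L
    for (i in 1:6) for (j in 1:6) for (l in 1:6) {
      mm <- rbind(perms[i, ], perms[j, ], perms[l, ])
      tot <- tot + 1L
      if (friedmanOracle(mm) >= obs - 1e-9) ge <- ge + 1L
    }
    ge / tot
  }
  set.seed(17)
  for (rep in 1:5) {
    m <- t(replicate(3, sample(c(1.3, 2.7, 5.1))))
    ft <- friedmanTest(m, exact = TRUE)
    expect_equal(ft$p.value, bruteP(m))
  }
  # guards
  expect_error(friedmanTest(t(replicate(9, sample(1:3))), exact = TRUE),
               "at most 8")
  expect_error(friedmanTest(matrix(c(1, 1, 2, 1, 2, 2), 2, 3),
                            exact = TRUE), "untied")
})

test_that("Friedman p-values are well calibrated under a permutation null", {
  set.seed(31)
  B <- 2000
  p <- replicate(B, friedmanTest(t(replicate(10, sample(1:3))))$p.value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})
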