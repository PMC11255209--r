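test_that("voxel meshes have the exact lattice node and element counts", {
  fx <- columnFixture(2, 2, 2)
  mesh <- buildHexMesh(fx$mask, fx$density, femurLaw())
  expect_identical(nrow(meshElements(mesh)), 8L)
  expect_identical(nrow(meshNodes(mesh)), 27L)          # (2+1)^3 lattice
  fx1 <- columnFixture(1, 1, 1)
  mesh1 <- buildHexMesh(fx1$mask, fx1$density, femurLaw())
  expect_identical(nrow(meshElements(mesh1)), 1L)
  expect_identical(nrow(meshNodes(mesh1)), 8L)
  # per-element density is the voxel's density, exactly
  a <- array(runif(8, 0.1, 1), c(2, 2, 2))
  dens <- ctVolume(a, c(1, 1, 1), units = "g/cm3")
  m2 <- buildHexMesh(boneMask(array(1L, c(2, 2, 2)), c(1, 1, 1)), dens,
                     femurLaw())
  expect_identical(elementDensity(m2), as.numeric(a))
  expect_equal(elementModulus(m2), densityToModulus(as.numeric(a),
                                                    femurLaw()))
  # empty and disconnected masks
  expect_error(buildHexMesh(boneMask(array(0L, c(2, 2, 2)), c(1, 1, 1)),
                            dens, femurLaw()), "empty")
  disc <- array(0L, c(7, 3, 3))
  disc[1:2, , ] <- 1L; disc[6:7, 1, 1] <- 1L
  dv <- ctVolume(array(1, c(7, 3, 3)), c(1, 1, 1), units = "g/cm3")
  expect_warning(m3 <- buildHexMesh(boneMask(disc, c(1, 1, 1)), dv,
                                    femurLaw()), "largest")
  expect_identical(nrow(meshElements(m3)), 18L)
})

test_that("the brick element block is symmetric, PSD with 6 rigid modes, linear in E", {
  K <- elementStiffness(12000, 0.3, c(0.78, 0.78, 0.67))
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < 1e-8 * max(ev)), 6L)   # rigid-body modes
  expect_true(all(ev > -1e-8 * max(ev)))                # PSD
  expect_equal(elementStiffness(24000, 0.3, c(0.78, 0.78, 0.67)), 2 * K)
  expect_error(elementStiffness(0, 0.3, c(1, 1, 1)), "modulus")
  expect_error(elementStiffness(1, 0.3, c(1, 0, 1)), "degenerate")
})

test_that("compression BCs select the expected node layers", {
  fx <- columnFixture(1, 1, 10)
  mesh <- buildHexMesh(fx$mask, fx$density, femurLaw())
  bc <- applyAxialCompressionBC(mesh, axis = 3, layerMm = 1, stepMm = 0.01,
                                maxMm = 0.05)
  expect_identical(length(bc@drivenNodes), 4L)
  expect_identical(length(bc@fixedNodes), 4L)
  expect_length(intersect(bc@drivenNodes, bc@fixedNodes), 0)
  # a layer spanning the whole mesh cannot give disjoint sets
  expect_error(applyAxialCompressionBC(mesh, axis = 3, layerMm = 6,
                                       stepMm = 0.01, maxMm = 0.05),
               "span")
})

test_that("homogeneous columns match the uniaxial closed forms", {
  # elastic: reaction = E A delta / L, exact for nu = 0
  law0 <- femurLaw(poissonRatio = 0)
  for (dims in list(c(1, 1, 1), c(2, 2, 2), c(3, 3, 5))) {
    fx <- columnFixture(dims[1], dims[2], dims[3])
    mesh <- buildHexMesh(fx$mask, fx$density, law0)
    E <- elementModulus(mesh)[1]
    A <- dims[1] * dims[2]
    L <- dims[3]
    delta <- 0.0005 * L
    bc <- applyAxialCompressionBC(mesh, axis = 3, layerMm = 0.25,
                                  stepMm = delta, maxMm = delta,
                                  support = "pinned")
    r <- solveNonlinear(mesh, bc)
    expect_lt(abs(reactions(r)[1] - E * A * delta / L) / (E * A * delta / L),
              0.01)
  }
  # perfectly-plastic plateau: sigma_y * A = E * eps_y * A
  fx <- columnFixture(2, 2, 4)
  mesh <- buildHexMesh(fx$mask, fx$density, law0)
  bc <- applyAxialCompressionBC(mesh, axis = 3, layerMm = 0.25,
                                stepMm = 0.004, maxMm = 0.12,
                                support = "pinned")
  r <- solveNonlinear(mesh, bc)
  sigyA <- elementModulus(mesh)[1] * 0.015 * 4
  expect_lt(abs(tail(reactions(r), 1) - sigyA) / sigyA, 0.02)
  # near-zero prescribed displacement gives near-zero reactions
  bc0 <- applyAxialCompressionBC(mesh, axis = 3, layerMm = 0.25,
                                 stepMm = 1e-12, maxMm = 1e-12,
                                 support = "pinned")
  expect_lt(abs(reactions(solveNonlinear(mesh, bc0))[1]), 1e-6)
})

test_that("mesh refinement leaves the elastic column reaction unchanged", {
  law0 <- femurLaw(poissonRatio = 0)
  coarse <- columnFixture(1, 1, 4, spacing = c(1, 1, 1))
  fine <- columnFixture(2, 2, 8, spacing = c(0.5, 0.5, 0.5))
  rs <- sapply(list(coarse, fine), function(fx) {
    mesh <- buildHexMesh(fx$mask, fx$density, law0)
    bc <- applyAxialCompressionBC(mesh, axis = 3, layerMm = 0.2,
                                  stepMm = 0.004, maxMm = 0.004,
                                  support = "pinned")
    reactions(solveNonlinear(mesh, bc))[1]
  })
  expect_lt(abs(rs[2] - rs[1]) / rs[1], 0.01)
})

test_that("external work is non-negative and non-decreasing through yielding", {
  fx <- columnFixture(2, 2, 6)
  mesh <- buildHexMesh(fx$mask, fx$density, femurLaw())   # nu = 0.3, clamped
  bc <- applyAxialCompressionBC(mesh, axis = 3, layerMm = 0.25,
                                stepMm = 0.006, maxMm = 0.15)
  r <- solveNonlinear(mesh, bc)
  work <- cumsum(reactions(r) * bc@stepMm)
  expect_true(all(work >= 0))
  expect_true(all(diff(work) >= 0))
  expect_true(all(reactions(r) > 0))                     # compression positive
})

test_that("failure criteria read the load curve as specified", {
  mk <- function(d, r) new("SolveResult", displacements = d, reactions = r,
                           failureLoad = NA_real_, failureStep = NA_real_,
                           criterion = NA_character_,
                           iterations = integer(length(d)))
  expect_identical(as.numeric(failureLoad(mk(1:3 / 10, c(1, 2, 3)),
                                          "femur_max_load")), 3)
  fl <- failureLoad(mk(1:3 / 10, c(1, 5, 4)), "femur_max_load")
  expect_identical(as.numeric(fl), 5)
  expect_identical(attr(fl, "step"), 2L)
  # vertebral criterion: load at 1.9% of the bone height, interpolated
  d <- seq(0.1, 1, 0.1)
  flv <- failureLoad(mk(d, 100 * d), "vertebra_height_reduction",
                     boneHeightMm = 30)
  expect_equal(as.numeric(flv), 100 * 0.019 * 30)        # 0.57 mm -> 57 N
  expect_error(failureLoad(mk(d, 100 * d), "vertebra_height_reduction"),
               "boneHeightMm")
  expect_error(failureLoad(mk(d / 100, d), "vertebra_height_reduction",
                           boneHeightMm = 30), "increase max displacement")
})

test_that("the uniaxial constitutive curve shows the advertised transition", {
  cur <- uniaxialStressStrain(vertebraLaw(poissonRatio = 0), rho = 1,
                              maxStrain = 0.025, strainStep = 2.5e-4)
  onset <- plateauOnset(cur$strain, cur$stressMPa)
  expect_lt(abs(onset - 0.015), 5e-4 + 2.5e-4)
  expect_equal(max(cur$stressMPa), 3195.3 * 0.015, tolerance = 1e-6)
  # the elastic branch has slope E
  expect_equal(cur$stressMPa[4] / cur$strain[4], 3195.3, tolerance = 1e-6)
})
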