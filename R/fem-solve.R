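## Displacement-controlled quasi-static compression with a small-strain J2
## (von Mises) elastic-perfectly-plastic material, yield stress per element
## sigma_y = E * yield strain. Equilibrium at each increment is found by the
## initial-stiffness (modified Newton) iteration: the elastic sparse Cholesky
## factor is computed once per mesh and reused, with the radial-return
## mapping supplying the exact internal force at every iterate, so converged
## states satisfy the true elastoplastic equilibrium.

#' Boundary conditions for axial compression of a voxel mesh
#'
#' Driven nodes are those strictly within \code{layerMm} of the mesh's
#' maximum coordinate along the loading axis (they receive the prescribed
#' compressive displacement); fixed nodes are strictly within \code{layerMm}
#' of the minimum. \code{support = "clamped"} holds the fixed set on all
#' axes; \code{"pinned"} holds it axially with minimal lateral pins
#' (frictionless platens), which leaves homogeneous columns in a pure
#' uniaxial stress state.
#'
#' @param mesh a [HexMesh-class].
#' @param axis loading axis (default 3, cranio-caudal).
#' @param layerMm node-layer thickness, mm; one voxel by default.
#' @param stepMm displacement increment, mm.
#' @param maxMm total prescribed displacement, mm.
#' @param support \code{"clamped"} or \code{"pinned"}.
#' @return A [BoundaryConditions-class].
#' @export
applyAxialCompressionBC <- function(mesh, axis = 3L, layerMm = NULL,
                                    stepMm, maxMm, support = "clamped") {
  co <- mesh@nodes[, axis]
  if (is.null(layerMm)) layerMm <- mesh@spacing[axis]
  span <- max(co) - min(co)
  if (span <= 2 * layerMm)
    stop("mesh must span more than twice the BC layer along the axis",
         call. = FALSE)
  tol <- 1e-8 * max(1, abs(max(co)))
  driven <- which(co > max(co) - layerMm + tol)
  fixed <- which(co < min(co) + layerMm - tol)
  if (!length(driven) || !length(fixed))
    stop("empty driven or fixed node set", call. = FALSE)
  new("BoundaryConditions", fixedNodes = as.integer(fixed),
      drivenNodes = as.integer(driven), axis = as.integer(axis),
      stepMm = stepMm, maxMm = maxMm, support = support)
}

## Constrained dof indices implied by the support mode. For "pinned", the
## fixed set is held axially and rigid lateral motion is removed by the
## 3-2-1 rule: both transverse dofs of one node, plus one transverse dof of
## a second node chosen off-axis from the first.
.constrainedDofs <- function(mesh, bc) {
  ax <- bc@axis
  fixedAxial <- 3L * (bc@fixedNodes - 1L) + ax
  if (bc@support == "clamped") {
    fixed <- sort(c(3L * rep(bc@fixedNodes - 1L, each = 3L) + 1:3))
  } else {
    tr <- setdiff(1:3, ax)
    pinNode <- bc@fixedNodes[1L]
    pins <- 3L * (pinNode - 1L) + tr
    d1 <- abs(mesh@nodes[bc@fixedNodes, tr[1]] - mesh@nodes[pinNode, tr[1]])
    d2 <- abs(mesh@nodes[bc@fixedNodes, tr[2]] - mesh@nodes[pinNode, tr[2]])
    if (max(d1) >= max(d2)) {
      second <- bc@fixedNodes[which.max(d1)]
      pins <- c(pins, 3L * (second - 1L) + tr[2])
    } else {
      second <- bc@fixedNodes[which.max(d2)]
      pins <- c(pins, 3L * (second - 1L) + tr[1])
    }
    fixed <- sort(unique(c(fixedAxial, pins)))
  }
  list(fixed = fixed, drivenAxial = 3L * (bc@drivenNodes - 1L) + ax)
}

## Internal force and updated plastic state for displacement vector u.
## epl: 6 x (8 m) engineering plastic strains, Gauss point g of element e in
## column (g - 1) m + e.
.internalForce <- function(u, ED, Bs, w, G, Kb, sigy, epl) {
  m <- nrow(ED)
  U <- matrix(u[t(ED)], 24L, m)
  f24 <- matrix(0, 24L, m)
  anyPl <- FALSE
  for (g in 1:8) {
    cols <- ((g - 1L) * m + 1L):(g * m)
    eps <- Bs[[g]] %*% U
    ee <- eps - epl[, cols, drop = FALSE]
    evol <- ee[1, ] + ee[2, ] + ee[3, ]
    ev <- evol / 3
    sx <- 2 * G * (ee[1, ] - ev)
    sy <- 2 * G * (ee[2, ] - ev)
    sz <- 2 * G * (ee[3, ] - ev)
    txy <- G * ee[4, ]; tyz <- G * ee[5, ]; txz <- G * ee[6, ]
    q <- sqrt(1.5 * (sx^2 + sy^2 + sz^2 + 2 * (txy^2 + tyz^2 + txz^2)))
    over <- q - sigy
    pl <- which(over > 0)
    if (length(pl)) {
      anyPl <- TRUE
      scl <- sigy[pl] / q[pl]
      dg <- over[pl] / (3 * G[pl])
      fac <- dg * 1.5 / q[pl]
      epl[1, cols[pl]] <- epl[1, cols[pl]] + fac * sx[pl]
      epl[2, cols[pl]] <- epl[2, cols[pl]] + fac * sy[pl]
      epl[3, cols[pl]] <- epl[3, cols[pl]] + fac * sz[pl]
      epl[4, cols[pl]] <- epl[4, cols[pl]] + 2 * fac * txy[pl]
      epl[5, cols[pl]] <- epl[5, cols[pl]] + 2 * fac * tyz[pl]
      epl[6, cols[pl]] <- epl[6, cols[pl]] + 2 * fac * txz[pl]
      sx[pl] <- sx[pl] * scl; sy[pl] <- sy[pl] * scl; sz[pl] <- sz[pl] * scl
      txy[pl] <- txy[pl] * scl; tyz[pl] <- tyz[pl] * scl
      txz[pl] <- txz[pl] * scl
    }
    p <- Kb * evol
    sig <- rbind(sx + p, sy + p, sz + p, txy, tyz, txz)
    f24 <- f24 + crossprod(Bs[[g]], sig) * w
  }
  f <- numeric(length(u))
  grp <- as.vector(t(ED))
  tmp <- rowsum(as.vector(f24), grp)
  f[as.integer(rownames(tmp))] <- tmp
  list(f = f, epl = epl, anyPlastic = anyPl)
}

## Algorithmically consistent tangent of the radial-return map, assembled as
## a sparse matrix. For a plastic Gauss point the deviatoric operator is
## 2G (sigy/q_tr) [P - 3/(2 q_tr^2) s_tr s_tr'], the volumetric part stays
## elastic; elastic points use the full isotropic operator.
.tangentMatrix <- function(u, ED, Bs, w, G, Kb, sigy, epl, ii, jj, ndof) {
  m <- nrow(ED)
  U <- matrix(u[t(ED)], 24L, m)
  J6 <- matrix(0, 6, 6); J6[1:3, 1:3] <- 1
  P <- matrix(0, 6, 6); P[1:3, 1:3] <- diag(3) - 1 / 3
  diag(P)[4:6] <- 0.5
  rIdx <- rep(1:24, times = 24L)
  cIdx <- rep(1:24, each = 24L)
  xt <- matrix(0, m, 576L)
  for (g in 1:8) {
    cols <- ((g - 1L) * m + 1L):(g * m)
    B <- Bs[[g]]
    ee <- B %*% U - epl[, cols, drop = FALSE]
    evol <- ee[1, ] + ee[2, ] + ee[3, ]
    ev <- evol / 3
    S <- rbind(2 * G * (ee[1, ] - ev), 2 * G * (ee[2, ] - ev),
               2 * G * (ee[3, ] - ev), G * ee[4, ], G * ee[5, ], G * ee[6, ])
    q <- sqrt(1.5 * (S[1, ]^2 + S[2, ]^2 + S[3, ]^2 +
                       2 * (S[4, ]^2 + S[5, ]^2 + S[6, ]^2)))
    plastic <- q > sigy
    theta <- ifelse(plastic, sigy / pmax(q, 1e-300), 1)
    a <- 2 * G * theta
    vecBJB <- as.vector(crossprod(B, J6 %*% B))
    vecBPB <- as.vector(crossprod(B, P %*% B))
    xt <- xt + w * (Kb %o% vecBJB + a %o% vecBPB)
    ip <- which(plastic)
    if (length(ip)) {
      GG <- crossprod(B, S[, ip, drop = FALSE])       # 24 x np
      cc <- w * a[ip] * 1.5 / q[ip]^2
      A <- GG[rIdx, , drop = FALSE] * GG[cIdx, , drop = FALSE]
      xt[ip, ] <- xt[ip, ] - t(A) * cc
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = as.vector(xt),
                       dims = c(ndof, ndof))
}

#' Solve displacement-controlled compression to obtain the load curve
#'
#' Applies the prescribed axial displacement in increments of
#' \code{bc@stepMm}; at each increment the equilibrium of the J2
#' perfectly-plastic voxel mesh is found by modified Newton iteration with
#' the elastic stiffness (residual norm below \code{tol} times the reaction
#' force norm at convergence). The reaction is the axial force summed over
#' driven nodes, reported positive in compression.
#'
#' @param mesh a [HexMesh-class].
#' @param bc a [BoundaryConditions-class].
#' @param tol relative residual tolerance (default 1e-6).
#' @param maxIter iteration cap per increment (default 200).
#' @return A [SolveResult-class].
#' @examples
#' d <- ctVolume(array(1, c(1, 1, 1)), spacing = c(1, 1, 1), units = "g/cm3")
#' msk <- boneMask(array(1L, c(1, 1, 1)), spacing = c(1, 1, 1))
#' mesh <- buildHexMesh(msk, d, femurLaw(poissonRatio = 0))
#' bc <- applyAxialCompressionBC(mesh, stepMm = 1e-3, maxMm = 1e-3,
#'                               support = "pinned", layerMm = 0.4)
#' reactions(solveNonlinear(mesh, bc))  # E * A * delta / L = 10 N
#' @export
solveNonlinear <- function(mesh, bc, tol = 1e-6, maxIter = 200L) {
  validObject(bc)
  law <- mesh@law
  m <- nrow(mesh@elements)
  nnode <- nrow(mesh@nodes)
  ndof <- 3L * nnode
  bm <- .hexBmats(mesh@spacing)
  Emod <- mesh@elementModulus
  nu <- law@poissonRatio
  G <- Emod / (2 * (1 + nu))
  Kb <- Emod / (3 * (1 - 2 * nu))
  sigy <- Emod * law@yieldStrain
  ## dof map: columns node1(ux,uy,uz), node2(...), ...
  ED <- matrix(0L, m, 24L)
  for (i in 1:8)
    ED[, (3L * (i - 1L) + 1L):(3L * i)] <-
      cbind(3L * (mesh@elements[, i] - 1L) + 1L,
            3L * (mesh@elements[, i] - 1L) + 2L,
            3L * (mesh@elements[, i] - 1L) + 3L)
  ## elastic stiffness: E_e * unit stiffness (all elements share geometry)
  Kunit <- elementStiffness(1, nu, mesh@spacing)
  rIdx <- rep(1:24, times = 24L)
  cIdx <- rep(1:24, each = 24L)
  ii <- as.vector(ED[, rIdx, drop = FALSE])
  jj <- as.vector(ED[, cIdx, drop = FALSE])
  xx <- as.vector(Emod %o% as.vector(Kunit))
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  cd <- .constrainedDofs(mesh, bc)
  drivenAxial <- cd$drivenAxial
  prescribed <- sort(unique(c(cd$fixed, drivenAxial)))
  free <- setdiff(seq_len(ndof), prescribed)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  ch <- Matrix::Cholesky(Kff, LDL = FALSE)
  Kfc <- K[free, drivenAxial, drop = FALSE]
  nsteps <- max(1L, as.integer(round(bc@maxMm / bc@stepMm)))
  u <- numeric(ndof)
  epl <- matrix(0, 6L, 8L * m)
  ## elastic predictor for one increment (identical every step)
  dC <- rep(-bc@stepMm, length(drivenAxial))
  elasticInc <- as.numeric(Matrix::solve(ch, -(Kfc %*% dC)))
  duF <- elasticInc
  disp <- reac <- numeric(nsteps)
  iters <- integer(nsteps)
  uFreePrev <- u[free]
  for (s in seq_len(nsteps)) {
    u[drivenAxial] <- u[drivenAxial] + dC
    u[free] <- u[free] + duF
    converged <- FALSE
    switchIter <- 12L         # initial-stiffness sweeps before full Newton
    for (it in seq_len(maxIter)) {
      res <- .internalForce(u, ED, bm$B, bm$w, G, Kb, sigy, epl)
      rFree <- -res$f[free]
      refNorm <- sqrt(sum(res$f[drivenAxial]^2))
      rn <- sqrt(sum(rFree^2))
      if (rn <= tol * max(refNorm, 1e-12) || rn <= 1e-12) {
        converged <- TRUE
        break
      }
      if (it <= switchIter || !res$anyPlastic) {
        u[free] <- u[free] + as.numeric(Matrix::solve(ch, rFree))
      } else {
        ## stalled linear convergence: take consistent-tangent Newton steps
        Kt <- .tangentMatrix(u, ED, bm$B, bm$w, G, Kb, sigy, epl, ii, jj,
                             ndof)
        Ktf <- Matrix::forceSymmetric(Kt[free, free, drop = FALSE])
        du <- tryCatch(
          as.numeric(Matrix::solve(Ktf, rFree)),
          error = function(e) {
            shift <- 1e-8 * mean(Matrix::diag(Ktf))
            as.numeric(Matrix::solve(
              Ktf + shift * Matrix::Diagonal(length(free)), rFree))
          })
        u[free] <- u[free] + du
      }
    }
    if (!converged)
      stop(sprintf(
        "no convergence at step %d: residual %.3e (relative to %.3e)",
        s, rn, refNorm), call. = FALSE)
    epl <- res$epl
    duF <- u[free] - uFreePrev
    uFreePrev <- u[free]
    disp[s] <- s * bc@stepMm
    reac[s] <- -sum(res$f[drivenAxial])
    iters[s] <- it
  }
  new("SolveResult", displacements = disp, reactions = reac,
      failureLoad = NA_real_, failureStep = NA_real_,
      criterion = NA_character_, iterations = iters)
}

#' @rdname failureLoad
#' @export
setMethod("failureLoad", "SolveResult",
  function(result, criterion = c("femur_max_load",
                                 "vertebra_height_reduction"),
           boneHeightMm = NULL, heightReduction = 0.019) {
    criterion <- match.arg(criterion)
    r <- result@reactions
    d <- result@displacements
    if (!length(r)) stop("empty load-displacement curve", call. = FALSE)
    if (criterion == "femur_max_load") {
      i <- which.max(r)
      return(structure(r[i], step = i))
    }
    if (is.null(boneHeightMm))
      stop("boneHeightMm is required for the vertebral criterion",
           call. = FALSE)
    dStar <- heightReduction * boneHeightMm
    i <- which(d >= dStar - 1e-12)[1]
    if (is.na(i))
      stop("vertebral failure criterion not reached: increase max displacement",
           call. = FALSE)
    if (i == 1L || abs(d[i] - dStar) < 1e-12) {
      fl <- if (i == 1L) r[1] * dStar / d[1] else r[i]
    } else {
      fl <- r[i - 1] + (r[i] - r[i - 1]) * (dStar - d[i - 1]) /
        (d[i] - d[i - 1])
    }
    structure(fl, step = i)
  })

#' Uniaxial stress-strain curve of the constitutive model
#'
#' Drives a single 1 mm^3 voxel element (frictionless supports, Poisson
#' ratio as configured in the law) through displacement-controlled uniaxial
#' compression and returns the strain-stress curve of the
#' elastic-perfectly-plastic model: linear at modulus E up to the yield
#' strain, then a flat plateau at sigma_y = E * yield strain.
#'
#' @param law a [MaterialLaw-class].
#' @param rho density (g/cm^3) at which to evaluate the law's modulus.
#' @param maxStrain final strain (default 0.03).
#' @param strainStep strain increment (default 1e-4, i.e. 0.01\%).
#' @return data.frame with columns \code{strain} and \code{stressMPa}.
#' @export
uniaxialStressStrain <- function(law, rho = 1, maxStrain = 0.03,
                                 strainStep = 1e-4) {
  dens <- ctVolume(array(rho, c(1, 1, 1)), spacing = c(1, 1, 1),
                   units = "g/cm3")
  msk <- boneMask(array(1L, c(1, 1, 1)), spacing = c(1, 1, 1))
  mesh <- buildHexMesh(msk, dens, law)
  bc <- applyAxialCompressionBC(mesh, axis = 3L, layerMm = 0.25,
                                stepMm = strainStep, maxMm = maxStrain,
                                support = "pinned")
  res <- solveNonlinear(mesh, bc)
  data.frame(strain = res@displacements, stressMPa = res@reactions)
}

#' Locate the elastic-plastic transition of a stress-strain curve
#'
#' Returns the strain at the last point of the linear loading branch: the
#' point after which the stress increment falls below \code{relTol} times
#' the initial (elastic) increment.
#'
#' @param strain,stress curve samples (strain ascending from the first
#'   loaded state).
#' @param relTol plateau detection threshold relative to the elastic
#'   increment (default 1e-3).
#' @return The transition strain.
#' @export
plateauOnset <- function(strain, stress, relTol = 1e-3) {
  if (length(strain) != length(stress) || length(strain) < 3L)
    stop("need a curve with at least 3 samples", call. = FALSE)
  inc <- diff(stress)
  flat <- which(inc <= relTol * inc[1])
  if (!length(flat))
    stop("no plateau detected within the curve", call. = FALSE)
  strain[flat[1]]
}
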