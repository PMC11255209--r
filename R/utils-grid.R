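## Low-level regular-grid helpers shared across modules. All voxel indices are
## 1-based; world position of voxel i along an axis is
## origin + (i - 1) * spacing.

.axisCenters <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

## World-coordinate arrays for a full grid (recycling tricks keep memory flat).
.coordArrays <- function(dm, spacing, origin) {
  xc <- .axisCenters(dm[1], spacing[1], origin[1])
  yc <- .axisCenters(dm[2], spacing[2], origin[2])
  zc <- .axisCenters(dm[3], spacing[3], origin[3])
  list(x = array(xc, dm),
       y = array(rep(yc, each = dm[1]), dm),
       z = array(rep(zc, each = dm[1] * dm[2]), dm))
}

## Shift a 3-D array by integer offsets, padding with `fill`.
.shift3 <- function(a, s, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]; k <- s[ax]
    if (abs(k) >= n) return(out)
    if (k >= 0) { dst[[ax]] <- (1 + k):n; src[[ax]] <- 1:(n - k) }
    else        { dst[[ax]] <- 1:(n + k); src[[ax]] <- (1 - k):n }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## Structuring-element offsets (excluding the centre).
.seOffsets <- function(connectivity = 6L) {
  if (connectivity == 6L) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
         c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
    g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
}

## One-layer binary erosion/dilation; `m` logical. Voxels outside the grid
## count as background, so erosion peels the array border as well.
.erodeOnce <- function(m, connectivity = 6L) {
  out <- m
  for (o in .seOffsets(connectivity)) out <- out & .shift3(m, o, FALSE)
  out
}

.dilateOnce <- function(m, connectivity = 6L) {
  out <- m
  for (o in .seOffsets(connectivity)) out <- out | .shift3(m, o, FALSE)
  out
}

## Connected-component labelling (6-connectivity) via igraph.
## Returns integer label array (0 = background) and component sizes.
.labelComponents <- function(m) {
  d <- dim(m)
  idx <- which(m)
  n <- length(idx)
  if (n == 0L)
    return(list(labels = array(0L, d), sizes = integer(0)))
  pos <- arrayInd(idx, d)
  map <- integer(prod(d))
  map[idx] <- seq_len(n)
  strides <- c(1L, d[1], d[1] * d[2])
  elist <- vector("list", 3L)
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    has <- m[nb]
    elist[[ax]] <- rbind(map[idx[ok][has]], map[nb[has]])
  }
  e <- do.call(cbind, elist)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(e)) g <- igraph::add_edges(g, as.vector(e))
  comp <- igraph::components(g)
  labels <- array(0L, d)
  labels[idx] <- as.integer(comp$membership)
  list(labels = labels, sizes = as.integer(comp$csize))
}

## Fill interior cavities: background components not reaching any grid face.
.fillHoles <- function(m) {
  bg <- .labelComponents(!m)
  if (!length(bg$sizes)) return(m)
  lab <- bg$labels
  d <- dim(m)
  faceLabels <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ],
                         lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  faceLabels <- faceLabels[faceLabels != 0L]
  m | (lab != 0L & !(lab %in% faceLabels))
}

## Trilinear interpolation of array `a` at continuous 1-based voxel
## coordinates; points outside the grid get `fill`.
.interpTrilinear <- function(a, x, y, z, fill = 0) {
  d <- dim(a)
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(pmax(floor(x), 1), d[1] - 1)
  y0 <- pmin(pmax(floor(y), 1), d[2] - 1)
  z0 <- pmin(pmax(floor(z), 1), d[3] - 1)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  s1 <- d[1]; s2 <- d[1] * d[2]
  i000 <- x0 + (y0 - 1) * s1 + (z0 - 1) * s2
  dx <- if (d[1] > 1L) 1L else 0L
  dy <- if (d[2] > 1L) s1 else 0L
  dz <- if (d[3] > 1L) s2 else 0L
  v <- (1 - fx) * (1 - fy) * (1 - fz) * a[i000] +
       fx * (1 - fy) * (1 - fz) * a[i000 + dx] +
       (1 - fx) * fy * (1 - fz) * a[i000 + dy] +
       fx * fy * (1 - fz) * a[i000 + dx + dy] +
       (1 - fx) * (1 - fy) * fz * a[i000 + dz] +
       fx * (1 - fy) * fz * a[i000 + dx + dz] +
       (1 - fx) * fy * fz * a[i000 + dy + dz] +
       fx * fy * fz * a[i000 + dx + dy + dz]
  out[inside] <- v
  out
}

## Nearest-neighbour lookup at continuous 1-based voxel coordinates.
.interpNearest <- function(a, x, y, z, fill = 0) {
  d <- dim(a)
  xi <- round(x); yi <- round(y); zi <- round(z)
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(fill, length(x))
  idx <- xi[inside] + (yi[inside] - 1) * d[1] + (zi[inside] - 1) * d[1] * d[2]
  out[inside] <- a[idx]
  out
}

## 2x block-mean downsampling (used by the multi-resolution registration).
.downsample2 <- function(a) {
  d2 <- pmax(floor(dim(a) / 2) * 2, 2)
  a <- a[seq_len(min(d2[1], dim(a)[1])), seq_len(min(d2[2], dim(a)[2])),
         seq_len(min(d2[3], dim(a)[3])), drop = FALSE]
  d <- dim(a)
  if (d[1] >= 2) a <- (a[seq(1, d[1] - 1, 2), , , drop = FALSE] +
                       a[seq(2, d[1], 2), , , drop = FALSE]) / 2
  d <- dim(a)
  if (d[2] >= 2) a <- (a[, seq(1, d[2] - 1, 2), , drop = FALSE] +
                       a[, seq(2, d[2], 2), , drop = FALSE]) / 2
  d <- dim(a)
  if (d[3] >= 2) a <- (a[, , seq(1, d[3] - 1, 2), drop = FALSE] +
                       a[, , seq(2, d[3], 2), drop = FALSE]) / 2
  a
}

## Separable triangular [1 2 1]/4 smoothing along each axis, with
## renormalisation at the borders. Used to soften sharp tissue interfaces
## before intensity-based registration.
.smooth3 <- function(a) {
  ones <- array(1, dim(a))
  for (ax in 1:3) {
    o <- c(0, 0, 0)
    o[ax] <- 1L
    num <- 2 * a + .shift3(a, o, 0) + .shift3(a, -o, 0)
    den <- 2 * ones + .shift3(ones, o, 0) + .shift3(ones, -o, 0)
    a <- num / den
  }
  a
}

## Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.maskLogical <- function(mask) {
  if (is(mask, "BoneMask")) mask@data != 0L else mask != 0
}
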