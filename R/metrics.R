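## Segmentation-agreement metrics (Dice, Hausdorff in mm) and the paired
## nonparametric comparison machinery (Friedman test, Dunn post-hoc).

.checkSameGrid <- function(a, b) {
  if (!all(dim(a@data) == dim(b@data)))
    stop("masks must share the same grid shape", call. = FALSE)
  if (!isTRUE(all.equal(a@spacing, b@spacing)))
    stop("masks must share the same voxel spacing", call. = FALSE)
}

#' Sorensen-Dice coefficient
#'
#' 2|A n B| / (|A| + |B|); two empty masks are defined to agree perfectly
#' (Dice 1). Symmetric, and equal to 1 iff the masks are identical.
#'
#' @param a,b [BoneMask-class] objects on the same grid.
#' @return Dice coefficient in [0, 1].
#' @examples
#' m <- boneMask(array(1L, c(4, 4, 4)), spacing = c(1, 1, 1))
#' diceCoefficient(m, m)
#' @export
diceCoefficient <- function(a, b) {
  .checkSameGrid(a, b)
  A <- .maskLogical(a); B <- .maskLogical(b)
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0L) return(1)
  2 * sum(A & B) / (na + nb)
}

## Boundary voxels: in-mask voxels with a 6-neighbour outside the mask
## (voxels on the grid edge count as boundary).
.boundaryVoxels <- function(m) {
  interior <- m
  for (o in .seOffsets(6L)) interior <- interior & .shift3(m, o, FALSE)
  arrayInd(which(m & !interior), dim(m))
}

## For each row of A (n x 3 world mm), distance to the nearest row of B.
.minDistances <- function(A, B, chunk = 1024L) {
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ai <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), nb2, "+") - 2 * Ai %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  ## coincident points must give exactly zero despite fp cancellation
  out[out < 1e-7 * max(1, sqrt(max(nb2)))] <- 0
  out
}

#' Hausdorff distance between two masks, in mm
#'
#' Symmetric maximum of the directed surface-to-surface distances, computed
#' between boundary-voxel centres in world units (spacing-aware). The
#' boundary formulation is equivalent to the filled-volume Hausdorff distance
#' for the maximum. \code{percentile < 1} gives the robust percentile variant
#' (e.g. 0.95 for HD95).
#'
#' @param a,b nonempty [BoneMask-class] objects on the same grid.
#' @param percentile quantile of the directed distance distributions taken
#'   before the symmetric maximum; 1 (default) is the classical maximum.
#' @return Distance in mm.
#' @export
hausdorffDistance <- function(a, b, percentile = 1) {
  .checkSameGrid(a, b)
  A <- .maskLogical(a); B <- .maskLogical(b)
  if (!any(A) || !any(B))
    stop("Hausdorff distance is undefined for an empty mask", call. = FALSE)
  sp <- a@spacing
  bA <- sweep(.boundaryVoxels(A) - 1, 2, sp, "*")
  bB <- sweep(.boundaryVoxels(B) - 1, 2, sp, "*")
  dAB <- .minDistances(bA, bB)
  dBA <- .minDistances(bB, bA)
  if (percentile >= 1) max(max(dAB), max(dBA))
  else max(quantile(dAB, percentile, names = FALSE),
           quantile(dBA, percentile, names = FALSE))
}

#' Combined segmentation-agreement report
#'
#' @inheritParams hausdorffDistance
#' @return A [MetricReport-class] with the Dice coefficient and Hausdorff
#'   distance.
#' @export
maskMetrics <- function(a, b, percentile = 1) {
  new("MetricReport", dsc = diceCoefficient(a, b),
      hdMm = hausdorffDistance(a, b, percentile))
}

.checkPairedSamples <- function(samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 2L)
    stop("need at least 2 conditions (columns)", call. = FALSE)
  if (nrow(samples) < 2L)
    stop("need at least 2 subjects (rows)", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("paired samples must have no missing cells", call. = FALSE)
  samples
}

#' Friedman test across paired conditions
#'
#' Nonparametric paired comparison of k conditions over n subjects: per-row
#' midranks, tie-corrected chi-square statistic on k - 1 degrees of freedom.
#' A completely tied matrix (no rank variation at all) yields statistic 0 and
#' p = 1.
#'
#' @param samples numeric matrix, rows = subjects (bones), columns =
#'   conditions (segmentation variants).
#' @param exact use the exact permutation distribution instead of the
#'   chi-square approximation; available for untied data with at most 8
#'   subjects.
#' @return An object of class \code{"htest"} with \code{statistic},
#'   \code{parameter} (df) and \code{p.value}.
#' @export
friedmanTest <- function(samples, exact = FALSE) {
  samples <- .checkPairedSamples(samples)
  r <- t(apply(samples, 1L, rank))
  if (all(abs(r - (ncol(samples) + 1) / 2) < 1e-12)) {
    out <- list(statistic = c("Friedman chi-squared" = 0),
                parameter = c(df = ncol(samples) - 1L), p.value = 1,
                method = "Friedman rank sum test",
                data.name = deparse(substitute(samples)))
    class(out) <- "htest"
    return(out)
  }
  ht <- stats::friedman.test(samples)
  if (exact) {
    if (nrow(samples) > 8L)
      stop("exact permutation p is offered for at most 8 subjects",
           call. = FALSE)
    if (any(apply(samples, 1L, anyDuplicated) > 0))
      stop("exact permutation p requires untied rows", call. = FALSE)
    ht$p.value <- .friedmanExactP(r, unname(ht$statistic))
    ht$method <- paste(ht$method, "(exact permutation p)")
  }
  ht
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

## Exact permutation null of the Friedman statistic for untied ranks:
## dynamic programming over the joint distribution of the first k - 1
## column rank sums (rows permute independently and uniformly).
.friedmanExactP <- function(ranks, observed) {
  n <- nrow(ranks); k <- ncol(ranks)
  perms <- .permutations(k)
  keyOf <- function(v) paste(v, collapse = ",")
  dist <- new.env(parent = emptyenv())
  assign(keyOf(rep(0L, k - 1L)), 1, envir = dist)
  for (i in seq_len(n)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(dist)) {
      p0 <- get(key, envir = dist)
      sums <- as.integer(strsplit(key, ",")[[1]])
      for (j in seq_len(nrow(perms))) {
        s2 <- sums + perms[j, seq_len(k - 1L)]
        k2 <- keyOf(s2)
        prev <- if (exists(k2, envir = nxt)) get(k2, envir = nxt) else 0
        assign(k2, prev + p0, envir = nxt)
      }
    }
    dist <- nxt
  }
  total <- factorial(k)^n
  tot <- n * k * (k + 1) / 2
  pGE <- 0
  for (key in ls(dist)) {
    sums <- as.integer(strsplit(key, ",")[[1]])
    allSums <- c(sums, tot - sum(sums))
    stat <- 12 / (n * k * (k + 1)) * sum((allSums - n * (k + 1) / 2)^2)
    if (stat >= observed - 1e-9)
      pGE <- pGE + get(key, envir = dist)
  }
  pGE / total
}

#' Dunn's post-hoc comparisons against a reference condition
#'
#' Pairwise z statistics from Friedman mean ranks versus the reference
#' column, z = (Rbar_j - Rbar_ref) / sqrt(k (k + 1) / (6 n)), two-sided
#' normal p-values, Bonferroni-adjusted over the k - 1 reference comparisons
#' (only comparisons with the reference are formed).
#'
#' @inheritParams friedmanTest
#' @param referenceColumn index of the reference condition.
#' @return data.frame with one row per non-reference condition: mean-rank
#'   difference, z, raw and adjusted p-values.
#' @export
dunnPosthoc <- function(samples, referenceColumn = 1L) {
  samples <- .checkPairedSamples(samples)
  k <- ncol(samples); n <- nrow(samples)
  if (referenceColumn < 1L || referenceColumn > k)
    stop("invalid reference column", call. = FALSE)
  r <- t(apply(samples, 1L, rank))
  rbar <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * n))
  others <- setdiff(seq_len(k), referenceColumn)
  z <- (rbar[others] - rbar[referenceColumn]) / se
  p <- 2 * pnorm(-abs(z))
  nComp <- k - 1L
  data.frame(
    comparison = paste0(colnames(samples)[others] %||%
                          paste0("col", others), " vs ",
                        colnames(samples)[referenceColumn] %||%
                          paste0("col", referenceColumn)),
    meanRankDiff = unname(rbar[others] - rbar[referenceColumn]),
    z = unname(z),
    p = unname(p),
    p.adjusted = unname(pmin(1, p * nComp)),
    row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
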