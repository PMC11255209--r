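## End-to-end orchestration: calibrate -> density -> mesh -> boundary
## conditions -> nonlinear solve -> failure criterion, and the Table-3-style
## sensitivity study across eroded/dilated segmentation variants.

.variantGrid <- function() {
  data.frame(variant = c("erode2", "erode1", "none", "dilate1", "dilate2"),
             op = c("erode", "erode", "none", "dilate", "dilate"),
             iterations = c(2L, 1L, 0L, 1L, 2L),
             stringsAsFactors = FALSE)
}

.criterionFor <- function(boneKind)
  if (boneKind == "femur") "femur_max_load" else "vertebra_height_reduction"

#' Run the full CT-to-failure-load pipeline on one bone
#'
#' Executes calibration (fitting from embedded rods unless a calibration is
#' supplied), HU-to-density conversion, voxel hexahedral meshing, axial
#' compression boundary conditions, the nonlinear solve and the bone-kind
#' failure criterion. Deterministic for a fixed config. When
#' \code{config@outputDir} is set, the density volume (NIfTI), mesh (VTK),
#' load-displacement curve (CSV), calibration (JSON) and a small run manifest
#' are written there.
#'
#' @param ct a [CTVolume-class] in HU.
#' @param mask a [BoneMask-class] aligned to \code{ct}.
#' @param config a [PipelineConfig-class].
#' @return List with \code{result} ([SolveResult-class] with the failure
#'   fields filled), \code{failureLoad} (N), \code{calibration},
#'   \code{mesh}, \code{boneHeightMm}.
#' @export
runFailurePipeline <- function(ct, mask, config) {
  validObject(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cal <- stage("calibrate", {
    if (!is.null(config@calibration)) config@calibration
    else calibrateFromRods(ct, config@rodLayout)
  })
  dens <- stage("density", huToDensity(ct, cal))
  mesh <- stage("mesh", buildHexMesh(mask, dens, config@law))
  ax <- config@bcAxis
  height <- max(mesh@nodes[, ax]) - min(mesh@nodes[, ax])
  bc <- stage("bc", applyAxialCompressionBC(
    mesh, axis = ax, layerMm = config@bcLayerVoxels * mesh@spacing[ax],
    stepMm = config@stepFrac * height, maxMm = config@maxFrac * height,
    support = config@support))
  res <- stage("solve", solveNonlinear(mesh, bc))
  crit <- .criterionFor(config@boneKind)
  fl <- stage("failure", failureLoad(res, crit, boneHeightMm = height))
  res@failureLoad <- as.numeric(fl)
  res@failureStep <- as.numeric(attr(fl, "step"))
  res@criterion <- crit
  if (!is.na(config@outputDir)) {
    dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
    writeVolume(dens, file.path(config@outputDir, "density.nii.gz"))
    writeMeshVTK(mesh, file.path(config@outputDir, "mesh.vtk"))
    utils::write.csv(
      data.frame(step = seq_along(res@reactions),
                 displacement_mm = res@displacements,
                 reaction_N = res@reactions),
      file.path(config@outputDir, "load_displacement.csv"),
      row.names = FALSE)
    writeCalibration(cal, file.path(config@outputDir, "calibration.json"))
    jsonlite::write_json(
      list(boneKind = config@boneKind, seed = config@seed,
           stepFrac = config@stepFrac, maxFrac = config@maxFrac,
           support = config@support, elements = nrow(mesh@elements),
           failureLoadN = as.numeric(fl)),
      file.path(config@outputDir, "manifest.json"), auto_unbox = TRUE)
  }
  list(result = res, failureLoad = as.numeric(fl), calibration = cal,
       mesh = mesh, boneHeightMm = height)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [pipelineConfig()] arguments; an
#' optional \code{calibration} block with \code{slope}, \code{intercept}
#' and optionally \code{r2} becomes a [DensityCalibration-class].
#'
#' @param path YAML file path.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files",
         call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[names(y) %in% names(formals(pipelineConfig))]
  if (!is.null(y$calibration))
    args$calibration <- densityCalibration(
      y$calibration$slope, y$calibration$intercept,
      y$calibration$r2 %||% 1)
  do.call(pipelineConfig, args)
}

#' Segmentation-sensitivity study on one bone
#'
#' Runs the failure pipeline for the reference mask and for the five
#' perturbation variants of the automatic mask (erosion x2, erosion x1,
#' none, dilation x1, dilation x2), recording Dice and Hausdorff agreement
#' with the reference mask and the absolute and percent failure-load
#' difference against the reference-mask failure load. A variant whose mask
#' vanishes or fragments to nothing is marked failed (NA row) and the run
#' continues.
#'
#' @param ct a [CTVolume-class] in HU.
#' @param autoMask the automatic segmentation to perturb.
#' @param referenceMask the reference (manual-quality) segmentation.
#' @param config a [PipelineConfig-class].
#' @return A [SensitivityReport-class].
#' @export
runSensitivity <- function(ct, autoMask, referenceMask, config) {
  refRun <- runFailurePipeline(ct, referenceMask, config)
  flRef <- refRun$failureLoad
  grid <- .variantGrid()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    out <- data.frame(variant = grid$variant[i], dsc = NA_real_,
                      hd_mm = NA_real_, failure_load_N = NA_real_,
                      abs_diff_N = NA_real_, pct_diff = NA_real_,
                      failed = FALSE, stringsAsFactors = FALSE)
    tryCatch({
      pm <- perturbMask(autoMask, op = grid$op[i],
                        iterations = grid$iterations[i])
      met <- maskMetrics(pm, referenceMask, config@hdPercentile)
      run <- runFailurePipeline(ct, pm, config)
      out$dsc <- met@dsc
      out$hd_mm <- met@hdMm
      out$failure_load_N <- run$failureLoad
      out$abs_diff_N <- abs(run$failureLoad - flRef)
      out$pct_diff <- 100 * abs(run$failureLoad - flRef) / flRef
      out
    }, error = function(e) {
      out$failed <- TRUE
      out
    })
  })
  new("SensitivityReport", table = do.call(rbind, rows),
      referenceFL = flRef, boneKind = config@boneKind)
}

#' Aggregate sensitivity reports across bones
#'
#' Per-variant mean and SD of Dice and failure-load differences, a Friedman
#' test of the failure loads across the reference and all variants, and Dunn
#' post-hoc comparisons of each variant against the reference.
#'
#' @param reports list of at least two [SensitivityReport-class] objects with
#'   identical variant sets.
#' @param csvPath optional path; when given, the summary table is written as
#'   CSV.
#' @return List with \code{summary} (data.frame), \code{flMatrix} (bones x
#'   conditions), \code{friedman} (htest) and \code{dunn} (data.frame).
#' @export
batchReport <- function(reports, csvPath = NULL) {
  if (length(reports) < 2L)
    stop("need at least 2 reports", call. = FALSE)
  vsets <- lapply(reports, function(r) r@table$variant)
  if (!all(vapply(vsets, identical, logical(1), vsets[[1]])))
    stop("heterogeneous variant sets across reports", call. = FALSE)
  variants <- vsets[[1]]
  getCol <- function(col)
    do.call(rbind, lapply(reports, function(r) r@table[[col]]))
  dsc <- getCol("dsc"); hd <- getCol("hd_mm")
  fl <- getCol("failure_load_N")
  absd <- getCol("abs_diff_N"); pctd <- getCol("pct_diff")
  summary <- data.frame(
    variant = variants,
    dsc_mean = colMeans(dsc), dsc_sd = apply(dsc, 2, sd),
    hd_mean = colMeans(hd), hd_sd = apply(hd, 2, sd),
    fl_mean = colMeans(fl), fl_sd = apply(fl, 2, sd),
    abs_diff_mean = colMeans(absd), abs_diff_sd = apply(absd, 2, sd),
    pct_diff_mean = colMeans(pctd), pct_diff_sd = apply(pctd, 2, sd),
    row.names = NULL)
  flRef <- vapply(reports, function(r) r@referenceFL, numeric(1))
  flMat <- cbind(reference = flRef, fl)
  colnames(flMat) <- c("reference", variants)
  fr <- NULL; dunn <- NULL
  if (!any(is.na(flMat))) {
    fr <- friedmanTest(flMat)
    dunn <- dunnPosthoc(flMat, referenceColumn = 1L)
  }
  if (!is.null(csvPath))
    utils::write.csv(summary, csvPath, row.names = FALSE)
  list(summary = summary, flMatrix = flMat, friedman = fr, dunn = dunn)
}
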