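#' Full-pipeline configuration
#'
#' @param seed single seed from which all randomness in the run derives.
#' @param generator a \code{\link{generatorConfig}} used when
#'   \code{simulate = TRUE} (its seed is overridden by \code{seed}).
#' @param simulate generate a synthetic cohort (\code{TRUE}) or read clouds
#'   from \code{inputDir} (\code{FALSE}).
#' @param inputDir directory of per-subject point clouds plus a
#'   \code{covariates.csv}, used when \code{simulate = FALSE}.
#' @param fit a \code{\link{fitConfig}}.
#' @param alignmentModes any of \code{"size-inclusive"},
#'   \code{"size-exclusive"}.
#' @param cutoffPercent cumulative-variance cutoff handed to
#'   \code{\link{selectModes}}.
#' @param nModesTested number of leading modes passed to the association
#'   analysis.
#' @param writeFittedMeshes write per-subject fitted meshes as JSON.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1L, generator = generatorConfig(seed = seed),
                           simulate = TRUE, inputDir = NULL,
                           fit = fitConfig(),
                           alignmentModes = c("size-inclusive",
                                              "size-exclusive"),
                           cutoffPercent = 90, nModesTested = 4L,
                           writeFittedMeshes = FALSE) {
  alignmentModes <- match.arg(alignmentModes,
                              c("size-inclusive", "size-exclusive"),
                              several.ok = TRUE)
  generator$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), generator = generator,
                 simulate = simulate, inputDir = inputDir, fit = fit,
                 alignmentModes = alignmentModes,
                 cutoffPercent = cutoffPercent,
                 nModesTested = as.integer(nModesTested),
                 writeFittedMeshes = writeFittedMeshes),
            class = "PipelineConfig")
}

.logTo <- function(logFile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  cat(msg, "\n", file = logFile, append = TRUE)
  message(msg)
}

#' Run the full shape-modelling pipeline
#'
#' Executes fit -> GPA (size-inclusive and/or size-exclusive) -> PCA shape
#' model -> SD-unit score projection -> covariate associations, writing every
#' artifact (model archives, scores, associations, covariates, log and a
#' manifest with file hashes) into \code{outDir}. Any stage failure leaves
#' partial outputs plus a \code{FAILED} marker and rethrows the error.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir run directory (created; must not require cleanup).
#' @return Invisibly, a list with the cohort, per-subject fits, and per
#'   alignment mode: the GPA result, model, scores and association table.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  cat("", file = logFile)
  result <- list()
  tryCatch({
    set.seed(config$seed)
    if (isTRUE(config$simulate)) {
      .logTo(logFile, "simulating cohort: n=", config$generator$nSubjects,
             " seed=", config$seed)
      cohort <- generateCohort(config$generator,
                               covariatesCsv = file.path(outDir,
                                                         "covariates.csv"))
      clouds <- lapply(cohort$subjects, `[[`, "cloud")
      ids <- cohort$covariates$subject_id
      covariates <- cohort$covariates
      template <- cohort$template
    } else {
      if (is.null(config$inputDir)) stop("inputDir required when simulate=FALSE")
      covariates <- utils::read.csv(file.path(config$inputDir,
                                              "covariates.csv"),
                                    stringsAsFactors = FALSE)
      ids <- covariates$subject_id
      files <- file.path(config$inputDir, paste0(ids, ".ply"))
      missing <- ids[!file.exists(files)]
      if (length(missing))
        stop("missing point cloud for subject(s): ",
             paste(missing, collapse = ", "))
      clouds <- lapply(files, readPointCloud)
      template <- templateLungMesh(config$generator$lungGrid,
                                   config$generator$fissureGrid)
      cohort <- list(covariates = covariates, template = template)
    }
    result$cohort <- cohort

    G <- smoothnessMatrix(template, config$fit$smoothing)
    fits <- vector("list", length(clouds))
    for (i in seq_along(clouds)) {
      fits[[i]] <- fitMesh(template, clouds[[i]], config$fit, smoothnessG = G)
      .logTo(logFile, ids[i], " fit RMSE ",
             sprintf("%.3f", fitRMSE(fits[[i]])), " mm in ",
             fits[[i]]@iterations, " iterations")
    }
    result$fits <- fits
    rmse <- vapply(fits, fitRMSE, numeric(1L))
    .logTo(logFile, sprintf("cohort fit RMSE %.2f +/- %.2f mm",
                            mean(rmse), stats::sd(rmse)))
    shapes <- do.call(cbind, lapply(fits, function(f)
      shapeVector(fittedMesh(f))))
    colnames(shapes) <- ids

    for (mode in config$alignmentModes) {
      withScale <- mode == "size-exclusive"
      al <- gpa(shapes, withScale = withScale)
      .logTo(logFile, mode, " GPA converged in ", al$iterations,
             " iterations")
      model <- buildSSM(assembleShapes(al$aligned, ids))
      tag <- gsub("-", "_", mode)
      writeShapeModel(model, file.path(outDir, paste0("model_", tag)),
                      gpaMode = mode)
      nm <- min(config$nModesTested, model@L)
      .logTo(logFile, mode, " variance explained (first ", nm, " modes): ",
             paste(sprintf("%.1f%%",
                           100 * model@varianceFractions[seq_len(nm)]),
                   collapse = ", "),
             "; modes to reach ", config$cutoffPercent, "%: ",
             selectModes(model, config$cutoffPercent))
      scores <- projectShapes(model, al$aligned)
      utils::write.csv(
        data.frame(subject_id = rownames(scores), scores,
                   row.names = NULL),
        file.path(outDir, paste0("scores_", tag, ".csv")), row.names = FALSE)
      assoc <- associationTable(scores, covariates,
                                modes = seq_len(nm))
      utils::write.csv(assoc,
                       file.path(outDir, paste0("associations_", tag,
                                                ".csv")),
                       row.names = FALSE)
      result[[mode]] <- list(gpa = al, model = model, scores = scores,
                             associations = assoc)
    }

    outputs <- list.files(outDir, recursive = TRUE, full.names = TRUE)
    outputs <- setdiff(outputs, file.path(outDir, "manifest.json"))
    manifest <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("LungSSM")),
      r_version = as.character(getRversion()),
      alignment_modes = config$alignmentModes,
      n_subjects = length(clouds),
      files = as.list(tools::md5sum(sort(outputs))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    .logTo(logFile, "pipeline complete")
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(outDir, "FAILED"))
    stop(e)
  })
  invisible(result)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the \code{\link{pipelineConfig}},
#' \code{\link{generatorConfig}} and \code{\link{fitConfig}} arguments:
#' top-level \code{seed, simulate, input_dir, alignment_modes,
#' cutoff_percent, n_modes_tested}, plus nested \code{generator:} and
#' \code{fit:} blocks whose entries are passed straight through.
#'
#' @param path a YAML file.
#' @return A \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- do.call(generatorConfig, c(y$generator,
                                    if (!is.null(y$seed)) list(seed = y$seed)))
  fit <- do.call(fitConfig, if (is.null(y$fit)) list() else y$fit)
  pipelineConfig(
    seed = if (is.null(y$seed)) 1L else y$seed,
    generator = gen,
    simulate = if (is.null(y$simulate)) TRUE else y$simulate,
    inputDir = y$input_dir,
    fit = fit,
    alignmentModes = if (is.null(y$alignment_modes))
      c("size-inclusive", "size-exclusive") else unlist(y$alignment_modes),
    cutoffPercent = if (is.null(y$cutoff_percent)) 90 else y$cutoff_percent,
    nModesTested = if (is.null(y$n_modes_tested)) 4L else y$n_modes_tested)
}
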