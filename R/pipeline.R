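# End-to-end pipeline: register -> derive -> segment -> measure -> report,
# with per-stage persistence and a run manifest.

stageFile <- function(outDir, name) file.path(outDir, name)

#' Run one pipeline stage from persisted inputs
#'
#' Each stage reads the previous stage's persisted outputs, so a pipeline can
#' be re-run piecewise; re-running a stage from persisted intermediates
#' reproduces the single-shot run bit-for-bit (lossless RDS intermediates).
#'
#' @param inputDir directory with the five channel TIFFs
#' @param outDir pipeline output directory
#' @param config a \code{\linkS4class{PipelineConfig}}
#' @return the stage's primary object, invisibly
#' @name stages
NULL

#' @rdname stages
#' @export
registerStage <- function(inputDir, outDir, config = pipelineConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stack <- readStack(inputDir, pixelScale = config@pixelScale)
  reg <- estimateTransforms(stack, "confocal", config)
  writeRegistration(reg, stageFile(outDir, "registration.json"))
  aligned <- applyTransforms(stack, reg)
  saveRDS(aligned, stageFile(outDir, "aligned_stack.rds"))
  invisible(reg)
}

#' @rdname stages
#' @param warnUnregistered warn (but proceed) when no registration output is
#'   found; registration is advisory, not enforced
#' @export
deriveStage <- function(inputDir, outDir, config = pipelineConfig(),
                        warnUnregistered = TRUE) {
  alignedPath <- stageFile(outDir, "aligned_stack.rds")
  if (file.exists(alignedPath)) {
    stack <- readRDS(alignedPath)
  } else {
    if (warnUnregistered)
      warning("no registration output found; deriving from the raw stack")
    stack <- readStack(inputDir, pixelScale = config@pixelScale)
  }
  derived <- deriveAll(stack, config)
  writeDerived(derived, outDir)
  invisible(derived)
}

#' @rdname stages
#' @param editScript optional path to a JSON edit script applied after the
#'   automatic pass
#' @export
segmentStage <- function(inputDir, outDir, config = pipelineConfig(),
                         editScript = NULL) {
  derived <- readRDS(stageFile(outDir, "derived_set.rds"))
  seg <- segmentVesselWall(derived, config)
  if (!is.null(editScript)) {
    edits <- jsonlite::read_json(editScript, simplifyVector = FALSE)
    edits <- lapply(edits, function(ed) {
      if (!is.null(ed$geometry$x))
        ed$geometry <- lapply(ed$geometry, function(v)
          if (is.list(v)) unlist(v) else v)
      ed
    })
    seg <- applyEdits(seg, edits, config)
  }
  writeSegmentation(seg, outDir)
  invisible(seg)
}

#' @rdname stages
#' @export
measureStage <- function(inputDir, outDir, config = pipelineConfig()) {
  seg <- readRDS(stageFile(outDir, "segmentation.rds"))
  profile <- diameterProfile(seg@centerline, seg,
                             pixelScale = config@pixelScale,
                             spacing = config@profileSpacing,
                             smoothingWindow = config@smoothingWindow)
  writeReport(profile, seg, outDir)
  invisible(profile)
}

#' Run the full analysis chain
#'
#' Executes register, derive, segment and measure in order, persisting every
#' stage output under \code{outDir}, and writes a run manifest (config
#' snapshot, input hashes, stage timings, output list, seed, package
#' version). Deterministic given config and inputs. If a stage fails, the
#' run aborts naming the stage and the outputs of completed stages remain on
#' disk.
#'
#' @param inputDir directory with the five channel TIFFs
#'   (\code{offset1.tif .. confocal.tif})
#' @param config a \code{\linkS4class{PipelineConfig}} or path to a YAML
#'   config file
#' @param outDir output directory
#' @param editScript optional JSON edit script for the segment stage
#' @return list with the profile, segmentation and manifest, invisibly
#' @export
runPipeline <- function(inputDir, config = pipelineConfig(), outDir,
                        editScript = NULL) {
  if (is.character(config)) config <- readConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(
    register = function() registerStage(inputDir, outDir, config),
    derive = function() deriveStage(inputDir, outDir, config,
                                    warnUnregistered = FALSE),
    segment = function() segmentStage(inputDir, outDir, config, editScript),
    measure = function() measureStage(inputDir, outDir, config))
  timings <- numeric(0)
  results <- list()
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    results[[nm]] <- tryCatch(stages[[nm]](), error = function(e)
      abort("stage-failed", sprintf("stage '%s': %s", nm, conditionMessage(e))))
    timings[nm] <- proc.time()[["elapsed"]] - t0
  }
  chanFiles <- file.path(inputDir, paste0(.CHANNELS, ".tif"))
  outputs <- list.files(outDir, recursive = TRUE)
  manifest <- list(
    config = configAsList(config),
    inputs = as.list(stats::setNames(unname(tools::md5sum(chanFiles)),
                                     basename(chanFiles))),
    stageTimingsSec = as.list(timings),
    version = as.character(utils::packageVersion("aoslomorph")),
    seed = config@seed,
    outputs = outputs)
  jsonlite::write_json(manifest, stageFile(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  stopifnot(all(file.exists(file.path(outDir, outputs))))
  invisible(list(profile = results$measure, segmentation = results$segment,
                 registration = results$register, manifest = manifest))
}
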