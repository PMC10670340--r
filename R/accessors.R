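#' Accessors for the core data objects
#'
#' @param x an \code{\linkS4class{OffsetStack}},
#'   \code{\linkS4class{DerivedSet}} or \code{\linkS4class{MorphometryProfile}}
#' @name accessors
NULL

#' @describeIn accessors number of frames in a stack
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
setMethod("nFrames", "OffsetStack", function(x) dim(x@frames[[1]])[3])

#' @describeIn accessors channel names of a stack
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
setMethod("channelNames", "OffsetStack", function(x) names(x@frames))

#' @describeIn accessors frame array of one channel (height x width x
#'   n_frames), or a single frame matrix when \code{frame} is given
#' @param channel channel key
#' @param frame optional frame index
#' @export
setGeneric("channelFrames", function(x, channel, frame = NULL)
  standardGeneric("channelFrames"))
setMethod("channelFrames", "OffsetStack", function(x, channel, frame = NULL) {
  if (!channel %in% names(x@frames))
    abort("channel-missing", sprintf("no channel '%s'", channel))
  a <- x@frames[[channel]]
  if (is.null(frame)) a else a[, , frame]
})

#' @describeIn accessors micrometres per pixel
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))
setMethod("pixelScale", "OffsetStack", function(x) x@pixelScale)
setMethod("pixelScale", "DerivedSet", function(x) x@pixelScale)
setMethod("pixelScale", "MorphometryProfile", function(x) x@pixelScale)

#' @describeIn accessors image dimensions c(height, width)
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))
setMethod("frameDim", "OffsetStack", function(x) dim(x@frames[[1]])[1:2])
setMethod("frameDim", "DerivedSet", function(x) dim(x@mpg))

#' @describeIn accessors the morphometry table as a data.frame
#' @param ... unused
#' @export
setMethod("as.data.frame", "MorphometryProfile", function(x, ...) x@profile)

setMethod("show", "OffsetStack", function(object) {
  d <- dim(object@frames[[1]])
  cat(sprintf("OffsetStack: %d frames of %d x %d px, 5 channels, %.3g um/px\n",
              d[3], d[1], d[2], object@pixelScale))
  nbad <- sum(is.na(object@frames[[1]][, , 1]))
  if (nbad > 0)
    cat(sprintf("  %d invalid pixels in frame 1 (registered borders)\n", nbad))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: %d frames, reference %d, %d accepted, %d rejected\n",
              nrow(object@transforms), object@referenceIndex,
              length(object@accepted), length(object@rejected)))
  q <- object@transforms$quality
  cat(sprintf("  quality: median %.3f, min %.3f\n",
              stats::median(q), min(q)))
})

setMethod("show", "DerivedSet", function(object) {
  d <- dim(object@mpg)
  cat(sprintf("DerivedSet: %d x %d px (%.3g um/px)\n", d[1], d[2],
              object@pixelScale))
  cat(sprintf("  mpg range [%.3g, %.3g], stdMotion mean %.3g\n",
              min(object@mpg, na.rm = TRUE), max(object@mpg, na.rm = TRUE),
              mean(object@stdMotion, na.rm = TRUE)))
})

setMethod("show", "WallSegmentation", function(object) {
  cat(sprintf("WallSegmentation: lumen area %d px, %d ridge px\n",
              sum(object@lumenMask), sum(object@ridgeMask)))
  for (i in 1:2)
    cat(sprintf("  side %d: %d inner, %d outer points (%d in gaps)\n", i,
                nrow(object@inner[[i]]), nrow(object@outer[[i]]),
                sum(!object@outer[[i]]$valid)))
  cat("  provenance:", length(object@provenance), "entries\n")
})

setMethod("show", "MorphometryProfile", function(object) {
  p <- object@profile
  v <- p[p$valid, , drop = FALSE]
  cat(sprintf("MorphometryProfile: %d samples (%d valid) over %.1f um\n",
              nrow(p), nrow(v),
              if (nrow(p) > 0) diff(range(p$position_um)) else 0))
  if (nrow(v) > 0)
    cat(sprintf("  median LD %.1f um, VD %.1f um, WLR %.3f\n",
                stats::median(v$LD_um), stats::median(v$VD_um),
                stats::median(v$WLR)))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d x %d px, lumen radius %.1f-%.1f um, wall %.1f-%.1f um\n",
              nrow(object@lumenMask), ncol(object@lumenMask),
              min(object@lumenRadiusUm), max(object@lumenRadiusUm),
              min(object@wallThicknessUm), max(object@wallThicknessUm)))
})
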