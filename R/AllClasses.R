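#' @import methods
NULL

.CHANNELS <- c("offset1", "offset2", "offset3", "offset4", "confocal")

#' Five-channel AO-SLO frame stack
#'
#' An \code{OffsetStack} holds the time series of co-acquired frames for the
#' four offset-fiber channels and the confocal channel, with shared geometry.
#' Each channel is a \code{height x width x n_frames} numeric array. Intensity
#' values are stored as acquired (no silent normalization); \code{NA} marks
#' invalid pixels (e.g. out-of-bounds samples after registration resampling).
#'
#' @slot frames named list of 3-D arrays, one per channel
#'   (\code{offset1..offset4}, \code{confocal})
#' @slot pixelScale micrometres per pixel (> 0)
#' @slot channelGains named numeric, per-channel multiplicative normalization
#'   factors applied explicitly by the user (default 1)
#' @exportClass OffsetStack
setClass("OffsetStack",
  representation(frames = "list", pixelScale = "numeric",
                 channelGains = "numeric"))

setValidity("OffsetStack", function(object) {
  f <- object@frames
  if (!identical(sort(names(f)), sort(.CHANNELS)))
    return(sprintf("channels must be exactly {%s}",
                   paste(.CHANNELS, collapse = ", ")))
  dims <- lapply(f, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("every channel must be a height x width x n_frames array")
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), TRUE)))
    return("all channels must share identical dimensions")
  for (ch in .CHANNELS) {
    v <- f[[ch]]
    bad <- !is.na(v) & (!is.finite(v) | v < 0)
    if (any(bad))
      return(sprintf("channel %s contains non-finite or negative intensities", ch))
  }
  if (length(object@pixelScale) != 1 || !is.finite(object@pixelScale) ||
      object@pixelScale <= 0)
    return("pixelScale must be a single positive number")
  TRUE
})

#' Processing parameters for the analysis chain
#'
#' Created with \code{\link{pipelineConfig}}; see that constructor for the
#' meaning and default of every parameter.
#'
#' @slot pixelScale micrometres per pixel
#' @slot epsilon denominator guard for ratio (split) images; \code{NA} means
#'   scale-free auto (1e-6 x mean ring sum)
#' @slot derivativePair which orthogonal split pair feeds the MPG:
#'   \code{"axis"} (near-horizontal/vertical split-3/4) or \code{"diagonal"}
#'   (split-1/2)
#' @slot maxShift maximum registration shift searched, px
#' @slot stripCount number of horizontal strips for non-rigid registration
#'   (1 = global translation only)
#' @slot rejectionThreshold frames with alignment quality below this are
#'   rejected
#' @slot ridgeHighQuantile,ridgeLowQuantile hysteresis thresholds for MPG
#'   ridge detection, as quantiles of the valid MPG values
#' @slot ridgeSigma structure-tensor smoothing, px
#' @slot minRidgeLength minimum accepted ridge component size, px
#' @slot flowClosingRadius morphological closing radius for the flow mask, px
#' @slot maxWallThickness outward search range for the outer wall, px
#' @slot wallStartOffset start of the outward ridge search, px
#' @slot bridgeLength longest outer-boundary gap bridged by interpolation, px
#' @slot snapDistance inner-boundary-to-ridge snapping distance, px
#' @slot profileSpacing arclength sampling step of the diameter profile, px
#' @slot smoothingWindow optional moving-average window for profiles
#'   (0 = none)
#' @slot multiVessel allow more than one flow component
#' @slot seed RNG seed for stochastic steps (reference-frame subsampling)
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(pixelScale = "numeric", epsilon = "numeric",
                 derivativePair = "character", maxShift = "numeric",
                 stripCount = "integer", rejectionThreshold = "numeric",
                 ridgeHighQuantile = "numeric", ridgeLowQuantile = "numeric",
                 ridgeSigma = "numeric", minRidgeLength = "integer",
                 flowClosingRadius = "numeric", maxWallThickness = "numeric",
                 wallStartOffset = "numeric", bridgeLength = "numeric",
                 snapDistance = "numeric", profileSpacing = "numeric",
                 smoothingWindow = "integer", multiVessel = "logical",
                 seed = "integer"))

setValidity("PipelineConfig", function(object) {
  if (!is.na(object@epsilon) && object@epsilon <= 0)
    return("epsilon must be > 0 (or NA for scale-free auto)")
  if (object@maxShift < 0) return("maxShift must be >= 0")
  if (object@profileSpacing < 1) return("profileSpacing must be >= 1 px")
  if (!object@derivativePair %in% c("axis", "diagonal"))
    return("derivativePair must be 'axis' or 'diagonal'")
  if (object@ridgeLowQuantile >= object@ridgeHighQuantile)
    return("ridgeLowQuantile must be below ridgeHighQuantile")
  TRUE
})

#' Per-frame alignment result
#'
#' @slot transforms data.frame with one row per frame: \code{frame},
#'   \code{dy}, \code{dx} (estimated content displacement relative to the
#'   reference, px), \code{quality} (normalized cross-correlation with the
#'   reference after alignment, in [-1, 1])
#' @slot stripShifts list (one element per frame) of per-strip (dy, dx)
#'   matrices, or empty when global registration was used
#' @slot referenceIndex index of the reference frame
#' @slot accepted,rejected retained / rejected frame indices
#' @exportClass RegistrationResult
setClass("RegistrationResult",
  representation(transforms = "data.frame", stripShifts = "list",
                 referenceIndex = "integer", accepted = "integer",
                 rejected = "integer"))

setValidity("RegistrationResult", function(object) {
  n <- nrow(object@transforms)
  all_idx <- sort(c(object@accepted, object@rejected))
  if (!identical(all_idx, seq_len(n)))
    return("accepted and rejected must partition all frame indices")
  if (!(object@referenceIndex %in% object@accepted))
    return("reference frame must be accepted")
  TRUE
})

#' A single split-detector image
#'
#' Normalized difference of opposed offset channels. Valid values lie in
#' [-1, 1]; pixels whose denominator falls below the epsilon guard are
#' \code{NA}.
#'
#' @slot values 2-D numeric matrix
#' @slot axis one of \code{"diag1"} (pair 1-3), \code{"diag2"} (pair 2-4),
#'   \code{"horizontal"} (split-3), \code{"vertical"} (split-4)
#' @exportClass SplitImage
setClass("SplitImage",
  representation(values = "matrix", axis = "character"))

setValidity("SplitImage", function(object) {
  if (!object@axis %in% c("diag1", "diag2", "horizontal", "vertical"))
    return("axis must be diag1, diag2, horizontal or vertical")
  v <- object@values
  if (any(!is.na(v) & abs(v) > 1 + 1e-12))
    return("valid split values must lie in [-1, 1]")
  TRUE
})

#' All derived images computed from a registered stack
#'
#' @slot splitMean list of four \code{SplitImage} temporal means
#'   (diag1, diag2, horizontal, vertical)
#' @slot splitStd list of four per-split temporal standard-deviation matrices
#' @slot mpg magnitude of the phase gradient (>= 0)
#' @slot offsetSD per-pixel std among the four simultaneous offsets,
#'   temporally averaged (>= 0)
#' @slot ringSum temporal mean of the four-offset ring sum (>= 0)
#' @slot stdMotion motion-contrast image: mean of the four split temporal
#'   standard deviations (>= 0)
#' @slot channelMeans named list of per-channel temporal mean images
#' @slot confocalMean confocal temporal mean
#' @slot pixelScale micrometres per pixel
#' @exportClass DerivedSet
setClass("DerivedSet",
  representation(splitMean = "list", splitStd = "list", mpg = "matrix",
                 offsetSD = "matrix", ringSum = "matrix",
                 stdMotion = "matrix", channelMeans = "list",
                 confocalMean = "matrix", pixelScale = "numeric"))

setValidity("DerivedSet", function(object) {
  d <- dim(object@mpg)
  comp <- c(list(object@offsetSD, object@ringSum, object@stdMotion,
                 object@confocalMean),
            lapply(object@splitMean, methods::slot, "values"),
            object@splitStd, object@channelMeans)
  if (!all(vapply(comp, function(m) identical(dim(m), d), TRUE)))
    return("all component images must share the same dimensions")
  for (m in list(object@mpg, object@offsetSD, object@stdMotion)) {
    if (any(!is.na(m) & m < -1e-12))
      return("mpg, offsetSD and stdMotion must be >= 0 where valid")
  }
  TRUE
})

#' Vessel wall segmentation
#'
#' Subpixel inner (lumen) and outer (vessel) boundary polylines, one per
#' vessel side, plus the masks they were derived from and a provenance log of
#' automatic steps and edit operations.
#'
#' @slot inner list of two data.frames (\code{x}, \code{y}, \code{s}) tracing
#'   the lumen edge, ordered by centerline arclength \code{s}
#' @slot outer list of two data.frames (\code{x}, \code{y}, \code{s},
#'   \code{valid}, \code{bridged}); \code{valid = FALSE} marks explicit gap
#'   segments where no MPG ridge was found
#' @slot lumenMask logical matrix, flow region
#' @slot ridgeMask logical matrix, accepted MPG gradient maxima
#' @slot centerline data.frame (\code{x}, \code{y}, \code{s})
#' @slot images list with the \code{mpg} and \code{stdMotion} images the
#'   segmentation was computed from (kept for edit replay)
#' @slot provenance character vector, ordered log of steps applied
#' @exportClass WallSegmentation
setClass("WallSegmentation",
  representation(inner = "list", outer = "list", lumenMask = "matrix",
                 ridgeMask = "matrix", centerline = "data.frame",
                 images = "list", provenance = "character"))

setValidity("WallSegmentation", function(object) {
  if (length(object@inner) != 2 || length(object@outer) != 2)
    return("inner and outer must each hold two side polylines")
  h <- nrow(object@lumenMask); w <- ncol(object@lumenMask)
  for (b in c(object@inner, object@outer)) {
    if (nrow(b) == 0) next
    ok <- !is.na(b$x) & !is.na(b$y)
    if (any(b$x[ok] < 0.5 | b$x[ok] > w + 0.5 |
            b$y[ok] < 0.5 | b$y[ok] > h + 0.5))
      return("boundary points must lie within the image")
    if (is.unsorted(b$s)) return("boundary points must be ordered by arclength")
  }
  # no outer point strictly inside the lumen
  for (b in object@outer) {
    ok <- if (nrow(b) > 0) !is.na(b$x) & b$valid else logical(0)
    if (any(ok)) {
      idx <- cbind(pmin(pmax(round(b$y[ok]), 1), h),
                   pmin(pmax(round(b$x[ok]), 1), w))
      core <- EBImage::erode(matrix(as.numeric(object@lumenMask), h, w),
                             EBImage::makeBrush(3, "box")) > 0.5
      if (any(core[idx]))
        return("outer boundary points must not lie strictly inside the lumen")
    }
  }
  TRUE
})

#' Arclength-resolved vessel morphometry
#'
#' @slot profile data.frame with columns \code{position_um}, \code{VD_um},
#'   \code{LD_um}, \code{wall_thickness_um}, \code{WLR}, \code{valid}
#' @slot pixelScale micrometres per pixel used for the measurement
#' @exportClass MorphometryProfile
setClass("MorphometryProfile",
  representation(profile = "data.frame", pixelScale = "numeric"))

setValidity("MorphometryProfile", function(object) {
  p <- object@profile
  need <- c("position_um", "VD_um", "LD_um", "wall_thickness_um", "WLR",
            "valid")
  if (!all(need %in% names(p)))
    return(sprintf("profile must have columns %s", paste(need, collapse = ", ")))
  if (nrow(p) > 1 && any(diff(p$position_um) <= 0))
    return("position must be strictly increasing")
  v <- p$valid & !is.na(p$VD_um) & !is.na(p$LD_um)
  if (any(v & (p$LD_um <= 0 | p$VD_um < p$LD_um - 1e-9)))
    return("VD >= LD > 0 must hold at every valid position")
  if (any(v & abs(p$wall_thickness_um - (p$VD_um - p$LD_um) / 2) > 1e-9))
    return("wall_thickness must equal (VD - LD)/2 exactly")
  TRUE
})

#' Ground truth of a simulated scene
#'
#' @slot centerline data.frame (\code{x}, \code{y}, \code{s}) in px, covering
#'   the padded render domain
#' @slot lumenRadiusUm,wallThicknessUm per-centerline-vertex truth, micrometres
#' @slot orientationDeg orientation for straight vessels (degrees,
#'   counterclockwise from +x)
#' @slot pixelScale micrometres per pixel
#' @slot phaseAmplitude wall phase elevation, radians
#' @slot lumenMask,wallMask logical truth masks (unpadded image)
#' @slot fields internal render fields (padded distance/orientation maps etc.)
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(centerline = "data.frame", lumenRadiusUm = "numeric",
                 wallThicknessUm = "numeric", orientationDeg = "numeric",
                 pixelScale = "numeric", phaseAmplitude = "numeric",
                 lumenMask = "matrix", wallMask = "matrix", fields = "list"))

setValidity("SceneTruth", function(object) {
  if (any(object@lumenRadiusUm <= 0)) return("lumen radius must be > 0")
  if (any(object@wallThicknessUm < 0)) return("wall thickness must be >= 0")
  if (any(object@lumenMask & object@wallMask))
    return("wall and lumen masks must be disjoint")
  TRUE
})

#' Simulator configuration
#'
#' Created with \code{\link{simConfig}}; see that constructor for meanings,
#' units and defaults.
#'
#' @slot imageSize c(height, width) px
#' @slot nFrames number of frames
#' @slot pixelScale micrometres per pixel
#' @slot background mean background intensity, counts
#' @slot alpha offset contrast coefficient, counts per (radian/px) of
#'   directional phase derivative
#' @slot edgeWidth wall-edge phase transition width, px
#' @slot textureAmplitude confocal background texture std, counts
#' @slot fiberAngles four offset-fiber direction angles, degrees
#' @slot flow list: \code{density} (cells per 100 um of vessel),
#'   \code{cellRadiusUm}, \code{speed} (px/frame), \code{contrast} (radians)
#' @slot jitter list: \code{sigma} (px), \code{distortedProb},
#'   \code{shearMagnitude}
#' @slot noise list: \code{gaussianSigma} (counts), \code{poissonGain}
#'   (0 = off)
#' @slot seed RNG seed
#' @exportClass SimConfig
setClass("SimConfig",
  representation(imageSize = "integer", nFrames = "integer",
                 pixelScale = "numeric", background = "numeric",
                 alpha = "numeric", edgeWidth = "numeric",
                 textureAmplitude = "numeric", fiberAngles = "numeric",
                 flow = "list", jitter = "list", noise = "list",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nFrames < 2) return("nFrames must be >= 2")
  if (object@jitter$sigma < 0 || object@noise$gaussianSigma < 0)
    return("all sigmas must be >= 0")
  a <- object@fiberAngles
  if (length(a) != 4) return("fiberAngles must have four entries")
  if (abs(((a[1] - a[3]) %% 360) - 180) > 1e-6 ||
      abs(((a[2] - a[4]) %% 360) - 180) > 1e-6)
    return("fiber pairs (1,3) and (2,4) must be antiparallel")
  TRUE
})
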