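#' Create a pipeline configuration
#'
#' One configuration object drives every stage of the analysis chain. All
#' distances are in pixels unless noted; \code{pixelScale} converts measured
#' diameters to micrometres.
#'
#' @param pixelScale micrometres per pixel (> 0)
#' @param epsilon denominator guard for split images. \code{NA} (default)
#'   selects a scale-free guard of 1e-6 times the global mean of the ring-sum
#'   image, so the guard adapts to the intensity units of the data.
#' @param derivativePair orthogonal split pair feeding the MPG:
#'   \code{"axis"} (default; near-horizontal split-3 and near-vertical
#'   split-4) or \code{"diagonal"} (split-1 and split-2)
#' @param maxShift maximum registration shift searched, px
#' @param stripCount horizontal strips for non-rigid (strip-wise translation)
#'   registration; 1 = global translation
#' @param rejectionThreshold frames with post-alignment normalized
#'   cross-correlation below this are rejected (default 0.5)
#' @param ridgeHighQuantile,ridgeLowQuantile hysteresis thresholds for MPG
#'   ridge detection, quantiles of valid MPG values (defaults 0.90 / 0.70)
#' @param ridgeSigma structure-tensor smoothing for ridge orientation, px
#' @param minRidgeLength minimum ridge component size kept, px
#' @param flowClosingRadius morphological closing radius for the flow mask, px
#' @param maxWallThickness outward search range for the outer wall, px
#' @param wallStartOffset distance from the inner boundary at which the
#'   outward ridge search starts, px (skips the inner ridge itself)
#' @param bridgeLength longest outer-boundary gap bridged by linear
#'   interpolation, px of arclength; longer gaps stay explicit gap segments
#' @param snapDistance maximum distance over which inner-boundary points snap
#'   to a nearby MPG ridge, px
#' @param profileSpacing arclength step between diameter samples, px (>= 1)
#' @param smoothingWindow optional moving-average window for the diameter
#'   profile (0 = none; raw variation is the finding of interest)
#' @param multiVessel keep all flow components above a minimum area instead of
#'   the largest only
#' @param seed RNG seed for the stochastic reference-frame subsample
#' @return a validated \code{\linkS4class{PipelineConfig}}
#' @export
pipelineConfig <- function(pixelScale = 1, epsilon = NA_real_,
                           derivativePair = "axis", maxShift = 15,
                           stripCount = 1L, rejectionThreshold = 0.5,
                           ridgeHighQuantile = 0.90, ridgeLowQuantile = 0.70,
                           ridgeSigma = 2, minRidgeLength = 10L,
                           flowClosingRadius = 2, maxWallThickness = 15,
                           wallStartOffset = 1.5, bridgeLength = 10,
                           snapDistance = 2, profileSpacing = 1,
                           smoothingWindow = 0L, multiVessel = FALSE,
                           seed = 1L) {
  methods::new("PipelineConfig", pixelScale = pixelScale,
               epsilon = as.numeric(epsilon),
               derivativePair = derivativePair, maxShift = maxShift,
               stripCount = as.integer(stripCount),
               rejectionThreshold = rejectionThreshold,
               ridgeHighQuantile = ridgeHighQuantile,
               ridgeLowQuantile = ridgeLowQuantile, ridgeSigma = ridgeSigma,
               minRidgeLength = as.integer(minRidgeLength),
               flowClosingRadius = flowClosingRadius,
               maxWallThickness = maxWallThickness,
               wallStartOffset = wallStartOffset, bridgeLength = bridgeLength,
               snapDistance = snapDistance, profileSpacing = profileSpacing,
               smoothingWindow = as.integer(smoothingWindow),
               multiVessel = multiVessel, seed = as.integer(seed))
}

#' Read / write a pipeline configuration as YAML
#'
#' Only keys present in the file override the defaults of
#' \code{\link{pipelineConfig}}.
#'
#' @param path YAML (or JSON) file
#' @return \code{readConfig}: a \code{\linkS4class{PipelineConfig}};
#'   \code{writeConfig}: \code{path}, invisibly
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals[intersect(names(vals), known)])
}

#' @rdname readConfig
#' @param config a \code{\linkS4class{PipelineConfig}}
#' @export
writeConfig <- function(config, path) {
  sl <- methods::slotNames(config)
  vals <- lapply(sl, function(s) methods::slot(config, s))
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}

configAsList <- function(config) {
  sl <- methods::slotNames(config)
  vals <- lapply(sl, function(s) methods::slot(config, s))
  names(vals) <- sl
  vals
}
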