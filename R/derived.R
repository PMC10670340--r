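# Derived images: splits, MPG, multi-offset SD, ring sum, temporal statistics
# and the motion-contrast STD image.

#' Split-detector image of two opposed offset channels
#'
#' The split image is the difference of the two offset images divided by their
#' sum, \code{(a - b)/(a + b)}. Pixels whose denominator does not exceed
#' \code{epsilon} are flagged invalid (\code{NA}) rather than propagating a
#' division blow-up; invalidity of either input also propagates.
#'
#' @param a,b same-shape nonnegative intensity matrices
#' @param epsilon denominator guard (> 0)
#' @param axis directional label of the pair (\code{"diag1"}, \code{"diag2"},
#'   \code{"horizontal"}, \code{"vertical"})
#' @return a \code{\linkS4class{SplitImage}} with valid values in [-1, 1]
#' @export
splitPair <- function(a, b, epsilon, axis = "diag1") {
  if (!identical(dim(a), dim(b)))
    abort("shape-mismatch", sprintf("a is %s, b is %s",
                                    paste(dim(a), collapse = "x"),
                                    paste(dim(b), collapse = "x")))
  s <- a + b
  v <- (a - b) / s
  v[is.na(s) | s <= epsilon] <- NA_real_
  methods::new("SplitImage", values = as.matrix(v), axis = axis)
}

# Raw split arrays for the four combinations; works on matrices or 3-D arrays.
# split1 = (I1-I3)/(I1+I3)            diagonal pair 1-3
# split2 = (I2-I4)/(I2+I4)            diagonal pair 2-4
# split3 = (I1-I2-I3+I4)/(I1+I2+I3+I4)   near-horizontal
# split4 = (I1+I2-I3-I4)/(I1+I2+I3+I4)   near-vertical
quadSplitArrays <- function(i1, i2, i3, i4, epsilon) {
  guard <- function(num, den) {
    v <- num / den
    v[is.na(den) | den <= epsilon] <- NA_real_
    v
  }
  ring <- i1 + i2 + i3 + i4
  list(diag1 = guard(i1 - i3, i1 + i3),
       diag2 = guard(i2 - i4, i2 + i4),
       horizontal = guard(i1 - i2 - i3 + i4, ring),
       vertical = guard(i1 + i2 - i3 - i4, ring))
}

#' All four split images of one frame
#'
#' Computes the two diagonal splits (opposed fiber pairs 1-3 and 2-4) and the
#' near-horizontal / near-vertical splits obtained from adjacent-fiber sums,
#' \code{(I1 - I2 - I3 + I4)} and \code{(I1 + I2 - I3 - I4)} over the ring sum.
#'
#' @param i1,i2,i3,i4 same-shape nonnegative offset intensity matrices
#' @param epsilon denominator guard
#' @return named list of four \code{\linkS4class{SplitImage}}s
#'   (\code{diag1}, \code{diag2}, \code{horizontal}, \code{vertical})
#' @export
quadSplits <- function(i1, i2, i3, i4, epsilon) {
  dims <- list(dim(i1), dim(i2), dim(i3), dim(i4))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    abort("shape-mismatch",
          paste("offset shapes:", paste(vapply(dims, paste, "", collapse = "x"),
                                        collapse = ", ")))
  arrs <- quadSplitArrays(i1, i2, i3, i4, epsilon)
  mapply(function(v, ax) methods::new("SplitImage", values = as.matrix(v),
                                      axis = ax),
         arrs, names(arrs), SIMPLIFY = FALSE)
}

#' Magnitude of the phase gradient
#'
#' Per-pixel square root of the sum of the squared orthogonal split
#' (phase-derivative) images. The two inputs must form an orthogonal pair:
#' horizontal/vertical or diag1/diag2. Invalid pixels in either input stay
#' invalid.
#'
#' @param dh,dv two \code{\linkS4class{SplitImage}}s forming an orthogonal
#'   pair
#' @return nonnegative matrix
#' @export
mpgImage <- function(dh, dv) {
  pair <- sort(c(dh@axis, dv@axis))
  if (!identical(pair, c("horizontal", "vertical")) &&
      !identical(pair, c("diag1", "diag2")))
    abort("pair-mismatch",
          sprintf("%s + %s is not an orthogonal derivative pair",
                  dh@axis, dv@axis))
  sqrt(dh@values^2 + dv@values^2)
}

#' Temporal mean and standard deviation of a channel
#'
#' Per-pixel mean and sample standard deviation over valid frames; pixels with
#' fewer than two valid frames are flagged invalid.
#'
#' @param frames \code{height x width x n_frames} array (or list of matrices)
#' @return list with \code{mean} and \code{sd} matrices
#' @export
temporalStats <- function(frames) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2)
    abort("insufficient-frames", "need at least 2 frames")
  temporalMeanSd(frames)
}

#' Compute every derived image of the analysis chain
#'
#' From a registered stack: the four per-frame split images and their temporal
#' means and standard deviations; the motion-contrast image
#' \code{stdMotion} (arithmetic mean of the four split temporal standard
#' deviations); the multi-offset \code{offsetSD} (per-frame, per-pixel
#' population standard deviation among the four simultaneous offsets,
#' temporally averaged); the ring-detection \code{ringSum} (temporal mean of
#' the four-offset sum); the \code{mpg} computed from the temporal means of
#' the configured orthogonal split pair; and per-channel temporal means.
#'
#' MPG is computed mean-first (from temporal-mean splits, which suppress
#' speckle) rather than per frame. The population formula (divide by 4) is
#' used for the four-offset SD; sample vs population changes only a constant
#' factor.
#'
#' @param stack a registered \code{\linkS4class{OffsetStack}} (>= 2 frames)
#' @param config a \code{\linkS4class{PipelineConfig}}; \code{epsilon = NA}
#'   selects the scale-free guard 1e-6 x mean ring sum
#' @return a \code{\linkS4class{DerivedSet}}
#' @export
deriveAll <- function(stack, config = pipelineConfig()) {
  if (nFrames(stack) < 2)
    abort("insufficient-frames", "need at least 2 frames")
  i1 <- stack@frames$offset1; i2 <- stack@frames$offset2
  i3 <- stack@frames$offset3; i4 <- stack@frames$offset4
  ring <- i1 + i2 + i3 + i4
  epsilon <- config@epsilon
  if (is.na(epsilon)) epsilon <- 1e-6 * mean(ring, na.rm = TRUE)
  if (!is.finite(epsilon) || epsilon <= 0) epsilon <- 1e-12

  sp <- quadSplitArrays(i1, i2, i3, i4, epsilon)
  st <- lapply(sp, temporalMeanSd)
  splitMean <- mapply(function(s, ax)
    methods::new("SplitImage", values = s$mean, axis = ax),
    st, names(st), SIMPLIFY = FALSE)
  splitStd <- lapply(st, `[[`, "sd")
  stdMotion <- (splitStd[[1]] + splitStd[[2]] + splitStd[[3]] +
                  splitStd[[4]]) / 4

  mu4 <- ring / 4
  sd4 <- sqrt(((i1 - mu4)^2 + (i2 - mu4)^2 + (i3 - mu4)^2 + (i4 - mu4)^2) / 4)
  offsetSD <- temporalMeanSd(sd4)$mean
  ringSum <- temporalMeanSd(ring)$mean

  pairNames <- if (config@derivativePair == "axis")
    c("horizontal", "vertical") else c("diag1", "diag2")
  mpg <- mpgImage(splitMean[[pairNames[1]]], splitMean[[pairNames[2]]])

  channelMeans <- lapply(stack@frames, function(a) temporalMeanSd(a)$mean)
  methods::new("DerivedSet", splitMean = splitMean, splitStd = splitStd,
               mpg = mpg, offsetSD = offsetSD, ringSum = ringSum,
               stdMotion = stdMotion, channelMeans = channelMeans,
               confocalMean = channelMeans$confocal,
               pixelScale = stack@pixelScale)
}

#' Persist a derived set as viewable TIFFs plus a sidecar
#'
#' Each component image is written as a 16-bit TIFF linearly scaled to the
#' full integer range, with the affine scale per image recorded in
#' \code{derived_scales.json}; a validity-mask TIFF marks invalid pixels.
#' These files are for viewing and interchange; exact stage chaining uses the
#' lossless RDS written alongside.
#'
#' @param derived a \code{\linkS4class{DerivedSet}}
#' @param dir output directory
#' @return named vector of paths, invisibly
#' @export
writeDerived <- function(derived, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- c(stats::setNames(lapply(derived@splitMean, methods::slot, "values"),
                            paste0("split", 1:4, "_mean")),
            list(mpg = derived@mpg, sd = derived@offsetSD,
                 sum = derived@ringSum, std_motion = derived@stdMotion,
                 confocal_mean = derived@confocalMean))
  scales <- list()
  paths <- character(0)
  for (nm in names(imgs)) {
    v <- imgs[[nm]]
    rng <- range(v, na.rm = TRUE)
    den <- if (diff(rng) > 0) diff(rng) else 1
    u <- (v - rng[1]) / den
    u[is.na(u)] <- 0
    p <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(u, p, bits.per.sample = 16L, compression = "none")
    scales[[nm]] <- list(min = rng[1], max = rng[2])
    paths[nm] <- p
  }
  validMask <- !is.na(imgs$std_motion) & !is.na(imgs$mpg)
  p <- file.path(dir, "validity_mask.tif")
  tiff::writeTIFF(matrix(as.numeric(validMask), nrow(validMask)), p,
                  bits.per.sample = 8L, compression = "none")
  paths["validity_mask"] <- p
  jsonlite::write_json(scales, file.path(dir, "derived_scales.json"),
                       digits = NA, auto_unbox = TRUE)
  saveRDS(derived, file.path(dir, "derived_set.rds"))
  paths["rds"] <- file.path(dir, "derived_set.rds")
  invisible(paths)
}
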