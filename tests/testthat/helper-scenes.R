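# Shared small-scene fixtures, generated in code and memoized per test run.

.fixtureCache <- new.env(parent = emptyenv())

smallSim <- function(seed = 5L, nFrames = 64L, ...) {
  simConfig(imageSize = c(160L, 160L), nFrames = as.integer(nFrames),
            seed = as.integer(seed), ...)
}

# The registered stack lives in the reference frame's coordinates, which are
# offset from scene coordinates by that frame's applied jitter shift.
refShift <- function(fx) fx$rend$shifts[fx$reg@referenceIndex, ]

# Shift a scene-coordinate truth mask into registered coordinates.
alignMask <- function(mask, fx) {
  sh <- round(refShift(fx))
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  ys <- seq_len(h) - sh[1]; xs <- seq_len(w) - sh[2]
  okY <- ys >= 1 & ys <= h; okX <- xs >= 1 & xs <= w
  out[okY, okX] <- mask[ys[okY], xs[okX]]
  out
}

# Render + register + derive a small scene; memoized on the argument key.
scenePipeline <- function(key, geometry = "straight", lumenDiameterUm = 40,
                          wallThicknessUm = 5, orientationDeg = 0,
                          sim = smallSim(), config = pipelineConfig(), ...) {
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  scene <- buildScene(geometry, lumenDiameterUm = lumenDiameterUm,
                      wallThicknessUm = wallThicknessUm,
                      orientationDeg = orientationDeg, sim = sim, ...)
  rend <- renderStack(scene, sim)
  reg <- estimateTransforms(rend$stack, "confocal", config)
  aligned <- applyTransforms(rend$stack, reg)
  derived <- deriveAll(aligned, config)
  out <- list(scene = scene, rend = rend, reg = reg, aligned = aligned,
              derived = derived, sim = sim, config = config)
  assign(key, out, envir = .fixtureCache)
  out
}

# A textured base image with known integer-shifted copies (exact oracle).
integerShiftStack <- function(nFrames = 8L, size = 96L, shiftMax = 3L,
                              seed = 3L, snr = 20) {
  set.seed(seed)
  pad <- shiftMax
  big <- matrix(stats::rnorm((size + 2 * pad)^2), size + 2 * pad)
  br <- EBImage::makeBrush(15, "Gaussian", sigma = 2.5)
  big <- EBImage::filter2(big, br, boundary = "replicate")
  big <- (big - min(big)) / diff(range(big)) * 100 + 50
  shifts <- cbind(dy = sample(-shiftMax:shiftMax, nFrames, replace = TRUE),
                  dx = sample(-shiftMax:shiftMax, nFrames, replace = TRUE))
  shifts[1, ] <- 0
  frames <- lapply(seq_len(nFrames), function(k) {
    # frame(y, x) = base(y - dy, x - dx): content displaced by (dy, dx)
    f <- big[pad + seq_len(size) - shifts[k, 1],
             pad + seq_len(size) - shifts[k, 2]]
    round(f + stats::rnorm(size^2, 0, mean(f) / (snr * 10)))
  })
  arr <- simplify2array(frames)
  st <- offsetStack(list(offset1 = arr, offset2 = arr, offset3 = arr,
                         offset4 = arr, confocal = arr), pixelScale = 1)
  list(stack = st, shifts = shifts)
}
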