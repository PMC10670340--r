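# Synthetic scene simulator: a vessel as a phase object imaged through four
# offset apertures plus a confocal channel, with flowing blood cells,
# eye-motion jitter, occasional shear-distorted frames and noise.

#' Create a simulator configuration
#'
#' Defaults describe the nominal study conditions: 64 frames of 256 x 256 px
#' at 1 um/px, background 100 counts, offset contrast such that wall-edge
#' split amplitudes reach ~0.14 (edge SNR ~ 10 against the per-frame split
#' noise), eye-motion jitter of 2 px RMS with 5% severely sheared frames, and
#' dense erythrocyte flow.
#'
#' @param imageSize c(height, width) px
#' @param nFrames frames per stack
#' @param pixelScale micrometres per pixel
#' @param background mean background intensity, counts
#' @param alpha offset contrast coefficient: counts added per (radian/px) of
#'   the directional phase derivative along a fiber direction
#' @param edgeWidth width of the raised-cosine phase transition at each wall
#'   edge, px
#' @param textureAmplitude std of the static confocal background texture
#'   (nerve-fiber-like smooth random field), counts
#' @param fiberAngles four offset-fiber directions, degrees; pairs (1,3) and
#'   (2,4) must be antiparallel. The default diagonal arrangement
#'   (45/135/225/315) makes the adjacent-fiber sums yield near-horizontal and
#'   near-vertical splits.
#' @param flow list: \code{density} cells per 100 um of vessel length,
#'   \code{cellRadiusUm} cell radius, \code{speed} advection px/frame,
#'   \code{contrast} peak cell phase, radians (cells are moving phase
#'   objects; their directional phase gradient enters the offset channels and
#'   10\% of their scalar profile enters the confocal channel)
#' @param jitter list: \code{sigma} per-frame global shift std px,
#'   \code{distortedProb} probability of a severely sheared frame,
#'   \code{shearMagnitude} px of horizontal shear per px of height
#' @param noise list: \code{gaussianSigma} additive noise std counts,
#'   \code{poissonGain} photon-noise gain (0 = off)
#' @param seed RNG seed; identical configurations and seeds render
#'   bit-identical stacks
#' @return a validated \code{\linkS4class{SimConfig}}
#' @export
simConfig <- function(imageSize = c(256L, 256L), nFrames = 64L,
                      pixelScale = 1, background = 100, alpha = 25,
                      edgeWidth = 2, textureAmplitude = 30,
                      fiberAngles = c(45, 135, 225, 315),
                      flow = list(), jitter = list(), noise = list(),
                      seed = 42L) {
  flowDef <- list(density = 50, cellRadiusUm = 3, speed = 3, contrast = 2)
  jitDef <- list(sigma = 2, distortedProb = 0.05, shearMagnitude = 0.25)
  noiDef <- list(gaussianSigma = 2, poissonGain = 0)
  flowDef[names(flow)] <- flow
  jitDef[names(jitter)] <- jitter
  noiDef[names(noise)] <- noise
  methods::new("SimConfig", imageSize = as.integer(imageSize),
               nFrames = as.integer(nFrames), pixelScale = pixelScale,
               background = background, alpha = alpha, edgeWidth = edgeWidth,
               textureAmplitude = textureAmplitude, fiberAngles = fiberAngles,
               flow = flowDef, jitter = jitDef, noise = noiDef,
               seed = as.integer(seed))
}

.PAD <- 10L

# Radial derivative of the wall phase profile: a raised-cosine step up
# centred on the inner edge (d = r) minus one centred on the outer edge
# (d = r + w), each of transition width e, amplitude A.
wallPhaseDeriv <- function(d, r, w, A, e) {
  ramp <- function(c0) {
    t <- d - c0
    out <- numeric(length(d))
    on <- abs(t) < e / 2
    out[on] <- (A * pi / (2 * e)) * cos(pi * t[on] / e)
    out
  }
  ramp(r) - ramp(r + w)
}

# Scalar wall phase (for reference/testing).
wallPhase <- function(d, r, w, A, e) {
  step <- function(c0) {
    t <- pmin(pmax((d - c0) / e + 0.5, 0), 1)
    A * 0.5 * (1 - cos(pi * t))
  }
  step(r) - step(r + w)
}

#' Build a ground-truthed vessel scene
#'
#' Constructs the scene geometry (centerline, per-arclength lumen radius and
#' wall thickness), the truth masks, and the static phase-derivative fields
#' the renderer samples. The wall is a phase object: the phase map is flat in
#' the background and lumen and elevated by \code{phaseAmplitude} across the
#' wall annulus, with raised-cosine transitions of width
#' \code{sim@edgeWidth} centred on the inner (\code{d = r}) and outer
#' (\code{d = r + w}) edges, so the phase-gradient maxima sit exactly on the
#' true boundaries.
#'
#' @param geometry \code{"straight"}, \code{"sinusoidal"} (meandering
#'   centerline), or \code{"radius-modulated"} (straight centerline,
#'   sinusoidally varying lumen diameter)
#' @param lumenDiameterUm lumen diameter, um (mean value for
#'   radius-modulated scenes)
#' @param wallThicknessUm wall thickness, um
#' @param orientationDeg straight-vessel orientation, degrees CCW from +x
#' @param amplitudeUm sinusoidal centerline amplitude, um
#' @param periodUm period of the sinusoidal centerline or of the diameter
#'   modulation, um
#' @param ldRangeUm c(min, max) lumen diameter for radius-modulated scenes
#' @param phaseAmplitude wall phase elevation, radians
#' @param sim a \code{\linkS4class{SimConfig}}
#' @return a \code{\linkS4class{SceneTruth}}
#' @export
buildScene <- function(geometry = c("straight", "sinusoidal",
                                    "radius-modulated"),
                       lumenDiameterUm = 50, wallThicknessUm = 5,
                       orientationDeg = 0, amplitudeUm = 20, periodUm = 150,
                       ldRangeUm = c(40, 80), phaseAmplitude = 1,
                       sim = simConfig()) {
  geometry <- match.arg(geometry)
  H <- sim@imageSize[1]; W <- sim@imageSize[2]
  ps <- sim@pixelScale
  P <- .PAD
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  e <- sim@edgeWidth

  # centerline across the padded domain, ~1 px vertex spacing
  if (geometry == "sinusoidal") {
    xs <- seq(1 - P, W + P, by = 1)
    Ageo <- amplitudeUm / ps
    ys <- cy + Ageo * sin(2 * pi * (xs - cx) / (periodUm / ps))
  } else {
    th <- if (geometry == "straight") orientationDeg * pi / 180 else 0
    Tmax <- sqrt(H^2 + W^2) / 2 + P + 2
    tt <- seq(-Tmax, Tmax, by = 1)
    xs <- cx + tt * cos(th)
    ys <- cy + tt * sin(th)
    Ageo <- 0
  }
  s <- arclength(xs, ys)
  nv <- length(xs)

  if (geometry == "radius-modulated") {
    mid <- mean(ldRangeUm) / 2
    amp <- diff(ldRangeUm) / 4   # radius amplitude = LD amplitude / 2 / 2
    rUm <- mid + amp * sin(2 * pi * s * ps / periodUm)
  } else {
    rUm <- rep(lumenDiameterUm / 2, nv)
  }
  wUm <- rep(wallThicknessUm, nv)
  rPx <- rUm / ps; wPx <- wUm / ps

  halfSpan <- min(H, W) / 2
  if (max(rPx + wPx) + e / 2 + max(wPx) + Ageo > halfSpan - 1)
    abort("scene-too-large",
          "vessel does not fit inside the image with a wall-thickness margin")

  # nearest-centerline-vertex fields on the padded grid
  hp <- H + 2L * P; wp <- W + 2L * P
  qx <- rep(seq(1 - P, W + P), each = hp)
  qy <- rep(seq(1 - P, H + P), times = wp)
  npx <- hp * wp
  vx <- xs; vy <- ys
  bestD2 <- rep(Inf, npx); bestK <- rep(1L, npx)
  chunk <- 200L
  q2 <- qx^2 + qy^2
  for (k0 in seq(1, nv, by = chunk)) {
    ks <- k0:min(k0 + chunk - 1L, nv)
    cross <- cbind(qx, qy) %*% rbind(vx[ks], vy[ks])     # BLAS: q . v
    d2 <- sweep(-2 * cross, 2, vx[ks]^2 + vy[ks]^2, "+") + q2
    j <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(npx), j)]
    upd <- dmin < bestD2
    bestD2[upd] <- dmin[upd]
    bestK[upd] <- ks[j[upd]]
  }
  D <- sqrt(pmax(bestD2, 0))
  Ux <- (qx - vx[bestK]) / D; Uy <- (qy - vy[bestK]) / D
  Ux[D < 1e-9] <- 0; Uy[D < 1e-9] <- 0
  Sarc <- s[bestK]
  rHere <- rPx[bestK]; wHere <- wPx[bestK]

  dphi <- wallPhaseDeriv(D, rHere, wHere, phaseAmplitude, e)
  ang <- sim@fiberAngles * pi / 180
  G <- lapply(seq_len(4), function(i) {
    matrix(sim@alpha * dphi * (Ux * cos(ang[i]) + Uy * sin(ang[i])), hp, wp)
  })
  # soft lumen mask: 1 inside, raised-cosine roll-off over the last px
  Mfield <- pmin(pmax(rHere - D, 0), 1)
  Mfield <- 0.5 * (1 - cos(pi * Mfield))
  Mpad <- matrix(Mfield, hp, wp)

  crop <- function(v) matrix(v, hp, wp)[P + seq_len(H), P + seq_len(W)]
  lumenMask <- crop(D <= rHere)
  wallMask <- crop(D > rHere & D <= rHere + wHere)

  methods::new("SceneTruth",
               centerline = data.frame(x = xs, y = ys, s = s),
               lumenRadiusUm = rUm, wallThicknessUm = wUm,
               orientationDeg = if (geometry == "straight") orientationDeg else NA_real_,
               pixelScale = ps, phaseAmplitude = phaseAmplitude,
               lumenMask = lumenMask, wallMask = wallMask,
               fields = list(G = G, M = Mpad,
                             D = matrix(D, hp, wp), S = matrix(Sarc, hp, wp),
                             pad = P, rPx = rPx, wPx = wPx,
                             geometry = geometry))
}

# Sample a padded field for a globally shifted frame:
# out(y, x) = field(y - sy + P, x - sx + P), bilinear via four crops.
sampleShifted <- function(field, P, H, W, sy, sx) {
  a <- 1 - sy + P; b <- 1 - sx + P
  r0 <- floor(a); c0 <- floor(b)
  fy <- a - r0; fx <- b - c0
  ri <- r0 + 0:(H - 1); ci <- c0 + 0:(W - 1)
  (1 - fy) * (1 - fx) * field[ri, ci] +
    (1 - fy) * fx * field[ri, ci + 1] +
    fy * (1 - fx) * field[ri + 1, ci] +
    fy * fx * field[ri + 1, ci + 1]
}

# Sheared sampling: out(y, x) = field(y - sy + P, x - sx - shear*(y - cy) + P),
# with replicate boundary (large shears reach beyond the padded field).
sampleSheared <- function(field, P, H, W, sy, sx, shear, cy) {
  yy <- rep(seq_len(H), times = W)
  xx <- rep(seq_len(W), each = H)
  qy <- pmin(pmax(yy - sy + P, 1), nrow(field))
  qx <- pmin(pmax(xx - sx - shear * (yy - cy) + P, 1), ncol(field))
  matrix(bilinearSample(field, qy, qx), H, W)
}

#' Render a five-channel stack from a scene
#'
#' Forward model per frame: each offset channel is
#' \code{background + alpha * (grad phi . d_i) + noise}, where the phase map
#' is the static wall profile plus the phase bumps of the flowing cells
#' (clipped smoothly to the lumen); the confocal channel is
#' \code{background + static texture + 0.1 x cell intensity + noise} with no
#' wall term (the confocal mode is blind to the wall). Each frame receives a
#' global jitter shift; with the configured probability an additional
#' horizontal shear emulates a severely motion-distorted frame, and its index
#' is recorded. Intensities are clipped at zero and quantized to integer
#' counts (digitizer model), which makes written stacks read back
#' bit-identically.
#'
#' @param scene a \code{\linkS4class{SceneTruth}} from \code{\link{buildScene}}
#' @param sim the \code{\linkS4class{SimConfig}} used to build the scene
#' @return list with \code{stack} (an \code{\linkS4class{OffsetStack}}),
#'   \code{shifts} (n x 2 matrix of applied (dy, dx)), and
#'   \code{distorted} (indices of sheared frames)
#' @export
renderStack <- function(scene, sim) {
  H <- sim@imageSize[1]; W <- sim@imageSize[2]
  P <- scene@fields$pad
  n <- sim@nFrames
  cy <- (H + 1) / 2
  ps <- sim@pixelScale

  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(sim@seed)

  hp <- H + 2L * P; wp <- W + 2L * P
  texture <- gaussBlur(matrix(stats::rnorm(hp * wp), hp, wp), 3)
  texture <- texture / stats::sd(texture) * sim@textureAmplitude

  maxSh <- P - 3
  shifts <- matrix(pmin(pmax(stats::rnorm(2 * n, 0, sim@jitter$sigma),
                             -maxSh), maxSh), n, 2)   # (dy, dx)
  distorted <- which(stats::runif(n) < sim@jitter$distortedProb)
  shearSign <- sample(c(-1, 1), n, replace = TRUE)

  # flow cells advected along the centerline
  cl <- scene@centerline
  Ltot <- max(cl$s)
  rc <- sim@flow$cellRadiusUm / ps
  ncell <- max(1L, as.integer(round(sim@flow$density * (Ltot * ps) / 100)))
  cellS <- stats::runif(ncell, 0, Ltot)
  cellLat <- stats::runif(ncell, -1, 1)
  rAt <- function(sq) stats::approx(cl$s, scene@fields$rPx, sq, rule = 2)$y
  ang <- sim@fiberAngles * pi / 180
  ca <- cos(ang); sa <- sin(ang)
  flowOn <- sim@flow$density > 0 && sim@flow$contrast != 0

  chans <- lapply(1:5, function(i) array(0, dim = c(H, W, n)))
  names(chans) <- .CHANNELS
  overflowWarned <- FALSE

  for (k in seq_len(n)) {
    sy <- shifts[k, 1]; sx <- shifts[k, 2]
    shear <- if (k %in% distorted) sim@jitter$shearMagnitude * shearSign[k] else 0
    samp <- if (shear == 0)
      function(f) sampleShifted(f, P, H, W, sy, sx)
    else
      function(f) sampleSheared(f, P, H, W, sy, sx, shear, cy)

    fr <- lapply(1:4, function(i) sim@background + samp(scene@fields$G[[i]]))
    conf <- sim@background + samp(texture)

    if (flowOn) {
      # advance cells; wrapping cells re-enter with a fresh lateral position
      cellS <- cellS + sim@flow$speed
      wrapped <- cellS > Ltot
      if (any(wrapped)) {
        cellS[wrapped] <- cellS[wrapped] - Ltot
        cellLat[wrapped] <- stats::runif(sum(wrapped), -1, 1)
      }
      px <- stats::approx(cl$s, cl$x, cellS, rule = 2)$y
      py <- stats::approx(cl$s, cl$y, cellS, rule = 2)$y
      tx <- stats::approx(cl$s, c(diff(cl$x), 0), cellS, rule = 2)$y
      ty <- stats::approx(cl$s, c(diff(cl$y), 0), cellS, rule = 2)$y
      tn <- sqrt(tx^2 + ty^2); tx <- tx / tn; ty <- ty / tn
      off <- cellLat * pmax(rAt(cellS) - 1, 0.3)
      px <- px - ty * off; py <- py + tx * off
      for (ci in seq_len(ncell)) {
        # frame position of the cell centre
        yc <- py[ci] + sy
        xc <- px[ci] + sx + shear * (yc - cy)
        wy <- max(1, floor(yc - rc - 1)):min(H, ceiling(yc + rc + 1))
        wx <- max(1, floor(xc - rc - 1)):min(W, ceiling(xc + rc + 1))
        if (length(wy) == 0 || length(wx) == 0) next
        gy <- rep(wy, times = length(wx))
        gx <- rep(wx, each = length(wy))
        qy <- gy - sy                     # back to scene coordinates
        qx <- gx - sx - shear * (gy - cy)
        dyc <- qy - py[ci]; dxc <- qx - px[ci]
        rho <- sqrt(dyc^2 + dxc^2)
        inb <- rho < rc
        if (!any(inb)) next
        msamp <- bilinearSample(scene@fields$M, qy[inb] + P, qx[inb] + P)
        msamp[is.na(msamp)] <- 0
        bump <- sim@flow$contrast * 0.5 * (1 + cos(pi * rho[inb] / rc))
        dbump <- -sim@flow$contrast * pi / (2 * rc) * sin(pi * rho[inb] / rc)
        ur <- ifelse(rho[inb] > 1e-9, 1 / rho[inb], 0)
        gxu <- dxc[inb] * ur; gyu <- dyc[inb] * ur
        idx <- cbind(gy[inb], gx[inb])
        for (i in 1:4) {
          add <- sim@alpha * dbump * (gxu * ca[i] + gyu * sa[i]) * msamp
          fr[[i]][idx] <- fr[[i]][idx] + add
        }
        conf[idx] <- conf[idx] + 0.1 * sim@alpha * bump * msamp
      }
    }

    all5 <- c(fr, list(conf))
    if (!overflowWarned) {
      negFrac <- mean(vapply(all5, function(m) mean(m < 0), 0))
      if (negFrac > 0.01) {
        warning("contrast-overflow: offset contrast clips below zero on >1% of pixels")
        overflowWarned <- TRUE
      }
    }
    for (i in 1:5) {
      v <- all5[[i]]
      if (sim@noise$gaussianSigma > 0)
        v <- v + stats::rnorm(length(v), 0, sim@noise$gaussianSigma)
      if (sim@noise$poissonGain > 0)
        v <- stats::rpois(length(v), pmax(v, 0) / sim@noise$poissonGain) *
          sim@noise$poissonGain
      chans[[i]][, , k] <- round(pmin(pmax(v, 0), 65535))
    }
  }

  list(stack = methods::new("OffsetStack", frames = chans,
                            pixelScale = ps,
                            channelGains = stats::setNames(rep(1, 5), .CHANNELS)),
       shifts = shifts, distorted = distorted)
}

#' Ground-truth morphometry profile of a scene
#'
#' The exact VD/LD/wall/WLR profile implied by the scene construction, for
#' comparison with the pipeline output. Positions are rebased to zero at the
#' first centerline vertex inside the image.
#'
#' @param scene a \code{\linkS4class{SceneTruth}}
#' @return a \code{\linkS4class{MorphometryProfile}}
#' @export
truthProfile <- function(scene) {
  cl <- scene@centerline
  H <- nrow(scene@lumenMask); W <- ncol(scene@lumenMask)
  inside <- cl$x >= 1 & cl$x <= W & cl$y >= 1 & cl$y <= H
  ld <- 2 * scene@lumenRadiusUm[inside]
  vd <- 2 * (scene@lumenRadiusUm[inside] + scene@wallThicknessUm[inside])
  pos <- (cl$s[inside] - min(cl$s[inside])) * scene@pixelScale
  prof <- data.frame(position_um = pos, VD_um = vd, LD_um = ld,
                     wall_thickness_um = (vd - ld) / 2,
                     WLR = 0.5 * (vd - ld) / ld, valid = TRUE)
  prof <- prof[!duplicated(prof$position_um), , drop = FALSE]
  methods::new("MorphometryProfile", profile = prof,
               pixelScale = scene@pixelScale)
}

#' Simulate a scene and write all artifacts to disk
#'
#' Writes the five channel TIFFs, the scene truth (JSON), the ground-truth
#' profile (CSV), the applied per-frame shifts (CSV) and the distorted-frame
#' index list, all under one directory.
#'
#' @param outDir output directory
#' @param sim a \code{\linkS4class{SimConfig}}
#' @param ... geometry arguments passed to \code{\link{buildScene}}
#' @return invisibly, a list with the scene, render result and file paths
#' @export
simulateScene <- function(outDir, sim = simConfig(), ...) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  scene <- buildScene(..., sim = sim)
  rend <- renderStack(scene, sim)
  paths <- writeStack(rend$stack, outDir)
  truthCsv <- file.path(outDir, "truth_profile.csv")
  writeProfileCsv(truthProfile(scene), truthCsv)
  truthJson <- file.path(outDir, "scene_truth.json")
  jsonlite::write_json(
    list(centerline = scene@centerline,
         lumenRadiusUm = scene@lumenRadiusUm,
         wallThicknessUm = scene@wallThicknessUm,
         orientationDeg = scene@orientationDeg,
         pixelScale = scene@pixelScale,
         phaseAmplitude = scene@phaseAmplitude),
    truthJson, digits = NA, auto_unbox = TRUE)
  shiftsCsv <- file.path(outDir, "applied_shifts.csv")
  utils::write.csv(data.frame(frame = seq_len(nrow(rend$shifts)),
                              dy = rend$shifts[, 1], dx = rend$shifts[, 2]),
                   shiftsCsv, row.names = FALSE)
  distortedTxt <- file.path(outDir, "distorted_frames.txt")
  writeLines(as.character(rend$distorted), distortedTxt)
  invisible(list(scene = scene, render = rend,
                 paths = c(paths, truth_profile = truthCsv,
                           scene_truth = truthJson, shifts = shiftsCsv,
                           distorted = distortedTxt)))
}
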