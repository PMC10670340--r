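# Frame registration: one alignment function per frame, estimated on a driver
# channel and applied identically to all channels.

# Cross-correlation shift estimate between two same-size matrices.
# Returns the displacement (dy, dx) of `frm` content relative to `ref`, i.e.
# frm(y, x) ~ ref(y - dy, x - dx), refined to subpixel by a parabolic fit.
xcorrShift <- function(ref, frm, maxShift) {
  a <- ref - mean(ref); b <- frm - mean(frm)
  h <- nrow(a); w <- ncol(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  uy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1))    # lag of index 1..h
  ux <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1))
  my <- abs(uy) <= maxShift; mx <- abs(ux) <= maxShift
  sub <- cc[my, mx, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  iy <- which(my)[k[1]]; ix <- which(mx)[k[2]]
  wrap <- function(i, n) ((i - 1) %% n) + 1
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0 || abs(den) < 1e-12) return(0)
    d <- 0.5 * (cm - cp) / den
    max(min(d, 0.5), -0.5)
  }
  dy <- para(cc[wrap(iy - 1, h), ix], cc[iy, ix], cc[wrap(iy + 1, h), ix])
  dx <- para(cc[iy, wrap(ix - 1, w)], cc[iy, ix], cc[iy, wrap(ix + 1, w)])
  c(dy = -(uy[iy] + dy), dx = -(ux[ix] + dx))
}

# Pearson correlation over jointly valid pixels, with a defined value for
# constant images (1 if equal, 0 otherwise).
overlapCor <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 16) return(0)
  x <- a[ok]; y <- b[ok]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    return(if (sx == 0 && sy == 0 && isTRUE(all.equal(x, y))) 1 else 0)
  stats::cor(x, y)
}

stripCenters <- function(h, stripCount) {
  edges <- seq(0, h, length.out = stripCount + 1)
  (head(edges, -1) + edges[-1]) / 2 + 0.5
}

# Per-row (dy, dx) from strip shifts, linear between strip centers.
rowShifts <- function(h, strips, stripCount) {
  ctr <- stripCenters(h, stripCount)
  y <- seq_len(h)
  if (stripCount == 1) {
    cbind(rep(strips[1, 1], h), rep(strips[1, 2], h))
  } else {
    cbind(stats::approx(ctr, strips[, 1], y, rule = 2)$y,
          stats::approx(ctr, strips[, 2], y, rule = 2)$y)
  }
}

# Resample img with a per-row shift table (h x 2 of dy, dx).
warpRows <- function(img, rs) {
  h <- nrow(img); w <- ncol(img)
  yy <- rep(seq_len(h), times = w) + rep(rs[, 1], times = w)
  xx <- rep(seq_len(w), each = h) + rep(rs[, 2], times = w)
  matrix(bilinearSample(img, yy, xx), h, w)
}

#' Estimate one alignment function per frame
#'
#' Shifts are estimated on a single driver channel (default: confocal, whose
#' static retinal texture is strongest) by cross-correlation peak with
#' parabolic subpixel refinement, and are later applied identically to all
#' channels, exploiting the simultaneity of the five-channel acquisition. The
#' reference frame is the member of a seeded random subsample (up to 10
#' frames) with the highest mean pairwise post-alignment correlation, which
#' avoids anchoring on a motion-distorted frame. With \code{stripCount > 1}
#' the frame is additionally divided into horizontal strips, each receiving
#' its own translation (the standard raster-scan distortion model),
#' interpolated linearly between strip centers. Frame quality is the
#' normalized cross-correlation with the reference after alignment; frames
#' below \code{rejectionThreshold} are rejected.
#'
#' @param stack an \code{\linkS4class{OffsetStack}} with at least 2 frames
#' @param driverChannel channel used to estimate the transforms
#' @param config a \code{\linkS4class{PipelineConfig}}
#' @return a \code{\linkS4class{RegistrationResult}}
#' @export
estimateTransforms <- function(stack, driverChannel = "confocal",
                               config = pipelineConfig()) {
  methods::validObject(stack)
  n <- nFrames(stack)
  if (n < 2) abort("insufficient-frames", "need at least 2 frames")
  drv <- channelFrames(stack, driverChannel)
  frames <- lapply(seq_len(n), function(k) {
    f <- drv[, , k]; f[is.na(f)] <- mean(f, na.rm = TRUE); f
  })

  # reference: best mean pairwise aligned correlation in a seeded subsample
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(config@seed)
  cand <- sort(sample(n, min(10L, n)))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  m <- length(cand)
  pc <- matrix(1, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    sh <- xcorrShift(frames[[cand[i]]], frames[[cand[j]]], config@maxShift)
    q <- overlapCor(shiftImage(frames[[cand[j]]], sh[1], sh[2]),
                    frames[[cand[i]]])
    pc[i, j] <- pc[j, i] <- q
  }
  refIdx <- cand[which.max(rowMeans(pc))]
  ref <- frames[[refIdx]]

  h <- nrow(ref)
  tr <- data.frame(frame = seq_len(n), dy = 0, dx = 0, quality = 1)
  stripShifts <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == refIdx) {
      if (config@stripCount > 1)
        stripShifts[[k]] <- matrix(0, config@stripCount, 2)
      next
    }
    sh <- xcorrShift(ref, frames[[k]], config@maxShift)
    tr$dy[k] <- sh[1]; tr$dx[k] <- sh[2]
    if (config@stripCount > 1) {
      edges <- round(seq(0, h, length.out = config@stripCount + 1))
      st <- matrix(0, config@stripCount, 2)
      for (s in seq_len(config@stripCount)) {
        rows <- (edges[s] + 1):edges[s + 1]
        st[s, ] <- xcorrShift(ref[rows, , drop = FALSE],
                              frames[[k]][rows, , drop = FALSE],
                              config@maxShift)
      }
      stripShifts[[k]] <- st
      aligned <- warpRows(frames[[k]], rowShifts(h, st, config@stripCount))
    } else {
      aligned <- shiftImage(frames[[k]], sh[1], sh[2])
    }
    tr$quality[k] <- overlapCor(aligned, ref)
  }
  rejected <- which(tr$quality < config@rejectionThreshold)
  accepted <- setdiff(seq_len(n), rejected)
  if (length(accepted) == 0)
    abort("no-frames-survive", "all frames fell below the rejection threshold")
  methods::new("RegistrationResult", transforms = tr,
               stripShifts = if (config@stripCount > 1) stripShifts else list(),
               referenceIndex = as.integer(refIdx),
               accepted = as.integer(accepted), rejected = as.integer(rejected))
}

#' Apply the estimated transforms to every channel
#'
#' Every channel of every accepted frame is resampled with the \emph{same}
#' alignment function (single-alignment-function contract); rejected frames
#' are dropped. Interpolation is bilinear; pixels sampled outside the frame
#' are marked invalid (\code{NA}) and are excluded from all downstream
#' temporal statistics.
#'
#' @param stack the \code{\linkS4class{OffsetStack}} that was registered
#' @param result the matching \code{\linkS4class{RegistrationResult}}
#' @return a new \code{\linkS4class{OffsetStack}} with
#'   \code{length(accepted)} frames
#' @export
applyTransforms <- function(stack, result) {
  n <- nFrames(stack)
  if (nrow(result@transforms) != n)
    abort("transform-mismatch",
          sprintf("%d transforms for %d frames", nrow(result@transforms), n))
  acc <- result@accepted
  useStrips <- length(result@stripShifts) > 0
  h <- frameDim(stack)[1]
  out <- lapply(stack@frames, function(a) {
    res <- array(NA_real_, dim = c(dim(a)[1:2], length(acc)))
    for (i in seq_along(acc)) {
      k <- acc[i]
      if (useStrips) {
        st <- result@stripShifts[[k]]
        res[, , i] <- warpRows(a[, , k], rowShifts(h, st, nrow(st)))
      } else {
        dy <- result@transforms$dy[k]; dx <- result@transforms$dx[k]
        res[, , i] <- if (dy == 0 && dx == 0) a[, , k]
                      else shiftImage(a[, , k], dy, dx)
      }
    }
    res
  })
  methods::new("OffsetStack", frames = out, pixelScale = stack@pixelScale,
               channelGains = stack@channelGains)
}

#' Persist / load a registration result as JSON
#'
#' @param result a \code{\linkS4class{RegistrationResult}}
#' @param path JSON file
#' @return \code{writeRegistration}: \code{path} invisibly;
#'   \code{readRegistration}: the restored object
#' @export
writeRegistration <- function(result, path) {
  obj <- list(transforms = result@transforms,
              referenceIndex = result@referenceIndex,
              accepted = result@accepted, rejected = result@rejected,
              stripShifts = lapply(result@stripShifts, function(m)
                if (is.null(m)) NULL
                else list(dy = m[, 1], dx = m[, 2])))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname writeRegistration
#' @export
readRegistration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) vapply(v, as.numeric, 0)
  tr <- data.frame(frame = num(lapply(obj$transforms, `[[`, "frame")),
                   dy = num(lapply(obj$transforms, `[[`, "dy")),
                   dx = num(lapply(obj$transforms, `[[`, "dx")),
                   quality = num(lapply(obj$transforms, `[[`, "quality")))
  strips <- lapply(obj$stripShifts, function(d)
    if (is.null(d) || length(d) == 0) NULL
    else cbind(num(d$dy), num(d$dx)))
  if (all(vapply(strips, is.null, TRUE))) strips <- list()
  methods::new("RegistrationResult", transforms = tr, stripShifts = strips,
               referenceIndex = as.integer(obj$referenceIndex[[1]]),
               accepted = as.integer(unlist(obj$accepted)),
               rejected = sort(as.integer(unlist(obj$rejected))))
}
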