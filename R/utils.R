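# Internal numerical helpers shared across modules.

# Classed error so callers can match on the short error code.
abort <- function(code, msg) {
  stop(structure(list(message = sprintf("%s: %s", code, msg),
                      call = sys.call(-1)),
                 class = c(paste0("aoslomorph_", gsub("-", "_", code)),
                           "aoslomorph_error", "error", "condition")))
}

# Bilinear interpolation at continuous (y, x); NA outside the image or where
# any of the four supporting pixels is NA.
bilinearSample <- function(img, y, x) {
  h <- nrow(img); w <- ncol(img)
  out <- rep(NA_real_, length(y))
  ok <- is.finite(y) & is.finite(x) & y >= 1 & y <= h & x >= 1 & x <= w
  if (!any(ok)) return(out)
  yy <- y[ok]; xx <- x[ok]
  y0 <- pmin(floor(yy), h - 1); x0 <- pmin(floor(xx), w - 1)
  fy <- yy - y0; fx <- xx - x0
  i00 <- img[cbind(y0, x0)];     i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]; i11 <- img[cbind(y0 + 1, x0 + 1)]
  out[ok] <- (1 - fy) * (1 - fx) * i00 + (1 - fy) * fx * i01 +
    fy * (1 - fx) * i10 + fy * fx * i11
  out
}

# Resample an image shifted by a constant subpixel displacement:
# out(y, x) = img(y + dy, x + dx), bilinear, NA out of bounds.
shiftImage <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  yy <- rep(seq_len(h), times = w) + dy
  xx <- rep(seq_len(w), each = h) + dx
  matrix(bilinearSample(img, yy, xx), h, w)
}

# Gaussian smoothing with replicate boundary; tolerates small images.
gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  sz <- 2L * as.integer(ceiling(2.5 * sigma)) + 1L
  sz <- min(sz, 2L * (min(dim(img)) %/% 2L) - 1L)
  if (sz < 3L) return(img)
  br <- EBImage::makeBrush(sz, shape = "Gaussian", sigma = sigma)
  EBImage::filter2(img, br, boundary = "replicate")
}

# Otsu threshold on a numeric vector of valid values.
otsuThreshold <- function(v) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  m <- matrix((v - rng[1]) / diff(rng), nrow = 1)
  t01 <- EBImage::otsu(m, range = c(0, 1), levels = 256L)
  rng[1] + t01 * diff(rng)
}

# 8-connected component labelling built on EBImage's 4-connected bwlabel by
# merging labels that touch diagonally (union-find).
label8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- findRoot(pairs[k, 1]); b <- findRoot(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), findRoot, 1L)
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Per-pixel temporal mean / sample std over the third dimension of a 3-D
# array, ignoring NA; pixels with fewer than two valid frames are NA.
temporalMeanSd <- function(arr) {
  d <- dim(arr)
  m <- matrix(arr, d[1] * d[2], d[3])
  nv <- rowSums(!is.na(m))
  s1 <- rowSums(m, na.rm = TRUE)
  s2 <- rowSums(m * m, na.rm = TRUE)
  mu <- s1 / nv
  va <- pmax(s2 - nv * mu * mu, 0) / (nv - 1)
  mu[nv < 1] <- NA_real_
  sd <- sqrt(va)
  sd[nv < 2] <- NA_real_
  list(mean = matrix(mu, d[1], d[2]), sd = matrix(sd, d[1], d[2]))
}

# Moving average that shortens the window near the ends (no phase shift).
movingAverage <- function(v, window) {
  if (window <= 1 || length(v) < 2) return(v)
  half <- window %/% 2
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Linear interpolation of a polyline (x, y given at arclength s) at query s.
interpPolyline <- function(poly, s) {
  list(x = stats::approx(poly$s, poly$x, s, rule = 2)$y,
       y = stats::approx(poly$s, poly$y, s, rule = 2)$y)
}

# Cumulative arclength of a polyline given x, y vectors.
arclength <- function(x, y) {
  if (length(x) < 2) return(rep(0, length(x)))
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}
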