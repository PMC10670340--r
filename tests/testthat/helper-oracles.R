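# Brute-force oracles: direct per-pixel loops over the defining formulas,
# independent of the package's vectorized implementations.

oracleSplit <- function(a, b, eps) {
  out <- matrix(NA_real_, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    s <- a[i, j] + b[i, j]
    if (!is.na(s) && s > eps) out[i, j] <- (a[i, j] - b[i, j]) / s
  }
  out
}

# All derived images from four offset frame lists, by definition:
# per-frame splits, temporal mean/sample-sd per split, STD = mean of the four
# split sds, per-frame population sd over the four offsets then temporal
# mean, ring sum temporal mean, MPG from the mean horizontal/vertical splits.
oracleDerived <- function(f1, f2, f3, f4, eps) {
  n <- length(f1); h <- nrow(f1[[1]]); w <- ncol(f1[[1]])
  splitDefs <- list(
    diag1 = function(a, b, c, d) oracleSplit(a, c, eps),
    diag2 = function(a, b, c, d) oracleSplit(b, d, eps),
    horizontal = function(a, b, c, d) oracleSplit(a + d, b + c, eps),
    vertical = function(a, b, c, d) oracleSplit(a + b, c + d, eps))
  perFrame <- lapply(seq_len(n), function(k)
    lapply(splitDefs, function(f) f(f1[[k]], f2[[k]], f3[[k]], f4[[k]])))
  stat <- function(vals) {
    v <- vals[!is.na(vals)]
    if (length(v) < 1) return(c(NA, NA))
    c(mean(v), if (length(v) >= 2) stats::sd(v) else NA)
  }
  splitMean <- splitStd <- lapply(1:4, function(i) matrix(NA_real_, h, w))
  names(splitMean) <- names(splitStd) <- names(splitDefs)
  for (nm in names(splitDefs)) for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- vapply(perFrame, function(pf) pf[[nm]][i, j], 0)
    ms <- stat(vals)
    splitMean[[nm]][i, j] <- ms[1]; splitStd[[nm]][i, j] <- ms[2]
  }
  stdMotion <- (splitStd$diag1 + splitStd$diag2 + splitStd$horizontal +
                  splitStd$vertical) / 4
  offsetSD <- ringSum <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    sds <- rings <- numeric(n)
    for (k in seq_len(n)) {
      v4 <- c(f1[[k]][i, j], f2[[k]][i, j], f3[[k]][i, j], f4[[k]][i, j])
      sds[k] <- sqrt(mean((v4 - mean(v4))^2))   # population, divide by 4
      rings[k] <- sum(v4)
    }
    offsetSD[i, j] <- mean(sds); ringSum[i, j] <- mean(rings)
  }
  mpg <- sqrt(splitMean$horizontal^2 + splitMean$vertical^2)
  list(splitMean = splitMean, splitStd = splitStd, stdMotion = stdMotion,
       offsetSD = offsetSD, ringSum = ringSum, mpg = mpg)
}

randomFrames <- function(n, h, w, lo = 1, hi = 100) {
  lapply(seq_len(n), function(k) matrix(stats::runif(h * w, lo, hi), h, w))
}
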