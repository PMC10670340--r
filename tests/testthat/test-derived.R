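test_that("splitPair matches its definition, guards and symmetry", {
  u <- matrix(10, 4, 4)
  expect_equal(splitPair(u, u, 1e-9)@values, matrix(0, 4, 4))
  a <- matrix(3, 2, 2); b <- matrix(1, 2, 2)
  expect_equal(splitPair(a, b, 1e-9)@values, matrix(0.5, 2, 2))
  z <- matrix(0, 2, 2)
  v <- splitPair(z, z, 1e-9)@values
  expect_true(all(is.na(v)))            # guarded, not NaN-propagating
  expect_error(splitPair(matrix(1, 2, 2), matrix(1, 3, 3), 1e-9),
               "shape-mismatch")
})

test_that("split antisymmetry, boundedness and gain invariance hold on random inputs", {
  set.seed(11)
  for (rep in 1:250) {
    a <- matrix(runif(4, 0, 100), 2, 2)
    b <- matrix(runif(4, 0, 100), 2, 2)
    eps <- 1e-9
    sab <- splitPair(a, b, eps)@values
    sba <- splitPair(b, a, eps)@values
    expect_equal(sab, -sba, tolerance = 1e-12)
    expect_true(all(abs(sab[!is.na(sab)]) <= 1))
    g <- runif(1, 0.1, 10)
    q1 <- quadSplits(a, b, a + 1, b + 2, eps)
    q2 <- quadSplits(g * a, g * b, g * (a + 1), g * (b + 2), eps * g)
    for (nm in names(q1))
      expect_equal(q1[[nm]]@values, q2[[nm]]@values, tolerance = 1e-9)
  }
})

test_that("quadSplits reproduces the four combination formulas", {
  o <- matrix(1, 1, 1)
  q <- quadSplits(2 * o, o, o, o, 1e-9)
  expect_equal(q$diag1@values[1, 1], 1 / 3)       # (2-1)/(2+1)
  expect_equal(q$horizontal@values[1, 1], 1 / 5)  # (2-1-1+1)/5
  expect_equal(q$vertical@values[1, 1], 1 / 5)    # (2+1-1-1)/5
  set.seed(12)
  i <- lapply(1:4, function(k) matrix(runif(16, 1, 50), 4, 4))
  q1 <- quadSplits(i[[1]], i[[2]], i[[3]], i[[4]], 1e-9)
  # swapping each opposed pair negates every split (recompute oracle)
  q2 <- quadSplits(i[[3]], i[[4]], i[[1]], i[[2]], 1e-9)
  for (nm in names(q1))
    expect_equal(q2[[nm]]@values, -q1[[nm]]@values, tolerance = 1e-12)
  allEq <- quadSplits(i[[1]], i[[1]], i[[1]], i[[1]], 1e-9)
  for (nm in names(allEq))
    expect_equal(allEq[[nm]]@values, matrix(0, 4, 4))
})

test_that("mpgImage combines orthogonal derivatives and rejects others", {
  h <- new("SplitImage", values = matrix(0.3, 2, 2), axis = "horizontal")
  v <- new("SplitImage", values = matrix(0.4, 2, 2), axis = "vertical")
  expect_equal(mpgImage(h, v), matrix(0.5, 2, 2))   # 3-4-5 scaled
  z <- new("SplitImage", values = matrix(0, 2, 2), axis = "vertical")
  expect_equal(mpgImage(h, z), matrix(0.3, 2, 2))
  d1 <- new("SplitImage", values = matrix(0, 2, 2), axis = "diag1")
  expect_error(mpgImage(h, d1), "pair-mismatch")
})

test_that("temporal statistics use the sample formula and respect validity", {
  const <- array(7, dim = c(3, 3, 5))
  ts <- temporalStats(const)
  expect_equal(ts$sd, matrix(0, 3, 3))
  two <- array(c(rep(1, 4), rep(3, 4)), dim = c(2, 2, 2))
  ts2 <- temporalStats(two)
  expect_equal(ts2$mean, matrix(2, 2, 2))
  expect_equal(ts2$sd, matrix(sqrt(2), 2, 2))
  expect_error(temporalStats(array(1, dim = c(2, 2, 1))),
               "insufficient-frames")
  # sampling distribution of the sample std: with n frames the relative sd of
  # the estimate is ~1/sqrt(2(n-1)), so n = 240 puts ~97% of pixels within 10%
  set.seed(13)
  noisy <- array(rnorm(40 * 40 * 240, 100, 5), dim = c(40, 40, 240))
  sdHat <- temporalStats(noisy)$sd
  expect_gte(mean(abs(sdHat - 5) / 5 <= 0.1), 0.95)
  # invalid pixels are excluded per pixel
  hole <- two
  hole[1, 1, 1] <- NA
  tsh <- temporalStats(hole)
  expect_true(is.na(tsh$sd[1, 1]))
  expect_equal(tsh$mean[1, 1], 3)
})

test_that("deriveAll equals brute-force recomputation on random frames", {
  set.seed(14)
  n <- 5
  fs <- lapply(1:4, function(i) randomFrames(n, 8, 8))
  conf <- randomFrames(n, 8, 8)
  st <- offsetStack(list(offset1 = fs[[1]], offset2 = fs[[2]],
                         offset3 = fs[[3]], offset4 = fs[[4]],
                         confocal = conf), pixelScale = 1)
  eps <- 1e-9
  dv <- deriveAll(st, pipelineConfig(epsilon = eps))
  oracle <- oracleDerived(fs[[1]], fs[[2]], fs[[3]], fs[[4]], eps)
  for (nm in names(oracle$splitMean))
    expect_equal(dv@splitMean[[nm]]@values, oracle$splitMean[[nm]],
                 tolerance = 1e-9)
  expect_equal(dv@stdMotion, oracle$stdMotion, tolerance = 1e-9)
  expect_equal(dv@offsetSD, oracle$offsetSD, tolerance = 1e-9)
  expect_equal(dv@ringSum, oracle$ringSum, tolerance = 1e-9)
  expect_equal(dv@mpg, oracle$mpg, tolerance = 1e-9)
  expect_true(all(dv@mpg >= 0, na.rm = TRUE))
  expect_true(all(dv@stdMotion >= 0, na.rm = TRUE))
})

test_that("identical offsets give zero splits, SD and MPG", {
  set.seed(15)
  f <- randomFrames(4, 8, 8)
  st <- offsetStack(list(offset1 = f, offset2 = f, offset3 = f, offset4 = f,
                         confocal = f), pixelScale = 1)
  dv <- deriveAll(st, pipelineConfig())
  expect_equal(dv@offsetSD, matrix(0, 8, 8), tolerance = 1e-12)
  expect_equal(dv@mpg, matrix(0, 8, 8), tolerance = 1e-12)
  for (nm in names(dv@splitMean))
    expect_equal(dv@splitMean[[nm]]@values, matrix(0, 8, 8),
                 tolerance = 1e-12)
})

test_that("derived set TIFF persistence writes all components plus sidecar", {
  set.seed(16)
  fs <- lapply(1:4, function(i) randomFrames(3, 8, 8))
  st <- offsetStack(list(offset1 = fs[[1]], offset2 = fs[[2]],
                         offset3 = fs[[3]], offset4 = fs[[4]],
                         confocal = fs[[1]]), pixelScale = 1)
  dv <- deriveAll(st, pipelineConfig())
  d <- withr::local_tempdir()
  paths <- writeDerived(dv, d)
  expect_true(all(file.exists(paths)))
  expect_true(file.exists(file.path(d, "derived_scales.json")))
  back <- readRDS(paths["rds"])
  expect_equal(back@mpg, dv@mpg)
})
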