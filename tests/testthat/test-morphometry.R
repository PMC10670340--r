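test_that("centerline of a horizontal bar is its midline", {
  mask <- matrix(FALSE, 64, 120)
  mask[23:42, 11:110] <- TRUE   # 20 px wide, 100 px long
  cl <- extractCenterline(mask, pipelineConfig())
  expect_lt(max(abs(cl$y - 32.5)), 1)
  # length ~ 100 minus end-cap trim (1.5 r) and thinning forks (~1.5 r more)
  expect_gt(max(cl$s), 100 - 6 * 10)
  expect_lt(max(cl$s), 100)
})

test_that("branched masks are refused in single-vessel mode", {
  mask <- matrix(FALSE, 128, 128)
  mask[60:68, 5:123] <- TRUE                      # trunk
  for (k in 0:79) mask[60 + k %/% 2 + 0:8, 44 + k] <- TRUE  # long oblique arm
  expect_error(extractCenterline(mask, pipelineConfig()),
               "branched-centerline")
})

test_that("sinusoidal centerlines are recovered within 1 px RMS", {
  fx <- scenePipeline("sinus", geometry = "sinusoidal",
                      lumenDiameterUm = 36, wallThicknessUm = 5,
                      amplitudeUm = 10, periodUm = 80)
  lumen <- detectFlowRegion(fx$derived@stdMotion, fx$config)
  cl <- extractCenterline(lumen, fx$config)
  sh <- refShift(fx)   # registered coords = scene coords + reference jitter
  truthY <- stats::approx(fx$scene@centerline$x + sh[2],
                          fx$scene@centerline$y + sh[1], cl$x)$y
  expect_lt(sqrt(mean((cl$y - truthY)^2)), 1)
})

test_that("wlr implements 0.5*(VD-LD)/LD with its guards", {
  expect_equal(wlr(50, 50), 0)
  expect_equal(wlr(3 * 20, 20), 1)
  expect_equal(wlr(100, 80), 0.125)
  expect_error(wlr(50, 0), "invalid-lumen")
  expect_error(wlr(40, 50), "inverted-wall")
})

test_that("parallel synthetic boundaries give an exact constant profile", {
  n <- 80
  mask <- matrix(FALSE, 64, n)
  mask[23:42, ] <- TRUE
  centerline <- data.frame(x = seq_len(n), y = rep(32.5, n),
                           s = seq_len(n) - 1)
  inner <- list(
    data.frame(x = seq_len(n), y = rep(22.5, n), s = seq_len(n) - 1),
    data.frame(x = seq_len(n), y = rep(42.5, n), s = seq_len(n) - 1))
  outer <- list(
    data.frame(x = seq_len(n), y = rep(18.5, n), s = seq_len(n) - 1,
               valid = TRUE, bridged = FALSE),
    data.frame(x = seq_len(n), y = rep(46.5, n), s = seq_len(n) - 1,
               valid = TRUE, bridged = FALSE))
  seg <- new("WallSegmentation", inner = inner, outer = outer,
             lumenMask = mask, ridgeMask = matrix(FALSE, 64, n),
             centerline = centerline,
             images = list(mpg = matrix(0, 64, n),
                           stdMotion = matrix(0, 64, n)),
             provenance = "constructed")
  prof <- diameterProfile(centerline, seg, pixelScale = 2, spacing = 1)
  p <- as.data.frame(prof)
  expect_equal(unique(p$LD_um), 40)          # 20 px * 2 um/px
  expect_equal(unique(p$VD_um), 56)
  expect_equal(p$wall_thickness_um, (p$VD_um - p$LD_um) / 2)
  expect_equal(p$WLR, 0.5 * (p$VD_um - p$LD_um) / p$LD_um)

  # scale equivariance: diameters scale with pixel size, WLR does not
  p1 <- as.data.frame(diameterProfile(centerline, seg, 1, 1))
  expect_equal(p$LD_um, 2 * p1$LD_um)
  expect_equal(p$VD_um, 2 * p1$VD_um)
  expect_equal(p$WLR, p1$WLR)

  # sampling arithmetic: doubling the spacing halves the sample count
  p2 <- as.data.frame(diameterProfile(centerline, seg, 1, 2))
  expect_lte(abs(nrow(p2) - nrow(p1) / 2), 1)
})

test_that("perpendicular chords keep a curved constant-radius vessel constant", {
  fx <- scenePipeline("sinus", geometry = "sinusoidal",
                      lumenDiameterUm = 36, wallThicknessUm = 5,
                      amplitudeUm = 10, periodUm = 80)
  seg <- segmentVesselWall(fx$derived, fx$config)
  p <- as.data.frame(diameterProfile(seg@centerline, seg, 1, 1))
  v <- p[p$valid, ]
  expect_lt(stats::sd(v$LD_um) / mean(v$LD_um), 0.04)
  expect_lt(abs(mean(v$LD_um) - 36) / 36, 0.02)
})

test_that("straight-vessel profiles recover truth within stated tolerances", {
  fx <- scenePipeline("seg40")
  seg <- segmentVesselWall(fx$derived, fx$config)
  prof <- diameterProfile(seg@centerline, seg,
                          pixelScale = fx$sim@pixelScale, spacing = 1)
  p <- as.data.frame(prof)
  v <- p[p$valid, ]
  expect_gt(nrow(v), 0.7 * nrow(p))
  expect_lt(mean(abs(v$LD_um - 40)), 1)
  expect_lt(mean(abs(v$VD_um - 50)), 1.5)
  trueWlr <- 0.5 * (50 - 40) / 40
  expect_lt(median(abs(v$WLR - trueWlr) / trueWlr), 0.15)
  # exact identities at every valid sample
  expect_equal(v$wall_thickness_um, (v$VD_um - v$LD_um) / 2)
  expect_equal(v$WLR, v$wall_thickness_um / v$LD_um)
})

test_that("rotated vessels yield matching profiles (rotation invariance)", {
  p0 <- local({
    fx <- scenePipeline("iso0", orientationDeg = 0,
                        lumenDiameterUm = 40, wallThicknessUm = 5)
    seg <- segmentVesselWall(fx$derived, fx$config)
    as.data.frame(diameterProfile(seg@centerline, seg, 1, 1))
  })
  p45 <- local({
    fx <- scenePipeline("iso45", orientationDeg = 45,
                        lumenDiameterUm = 40, wallThicknessUm = 5)
    seg <- segmentVesselWall(fx$derived, fx$config)
    as.data.frame(diameterProfile(seg@centerline, seg, 1, 1))
  })
  m0 <- mean(p0$LD_um[p0$valid]); m45 <- mean(p45$LD_um[p45$valid])
  expect_lt(abs(m0 - m45) / m0, 0.02)
  v0 <- mean(p0$VD_um[p0$valid]); v45 <- mean(p45$VD_um[p45$valid])
  expect_lt(abs(v0 - v45) / v0, 0.02)
})
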