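test_that("scene construction yields consistent truth masks and profiles", {
  sim <- smallSim()
  sc <- buildScene("straight", lumenDiameterUm = 50, wallThicknessUm = 5,
                   orientationDeg = 0, sim = sim)
  # a horizontal vessel: the lumen is a 50 px wide horizontal band
  colExtent <- colSums(sc@lumenMask)
  expect_true(all(abs(colExtent - 50) <= 1))
  expect_false(any(sc@lumenMask & sc@wallMask))
  tp <- as.data.frame(truthProfile(sc))
  expect_equal(unique(tp$VD_um), 60)
  expect_equal(unique(tp$WLR), 0.1)   # 0.5*(60-50)/50

  flat <- buildScene("straight", lumenDiameterUm = 50, wallThicknessUm = 0,
                     sim = sim)
  expect_equal(sum(flat@wallMask), 0)
  expect_equal(max(abs(flat@fields$G[[1]])), 0)   # zero wall -> flat phase
  expect_equal(unique(as.data.frame(truthProfile(flat))$WLR), 0)

  mod <- buildScene("radius-modulated", ldRangeUm = c(40, 60),
                    periodUm = 100, wallThicknessUm = 5, sim = sim)
  tpm <- as.data.frame(truthProfile(mod))
  expect_equal(range(tpm$LD_um), c(40, 60), tolerance = 1e-3)
  expect_equal(tpm$WLR, 0.5 * (tpm$VD_um - tpm$LD_um) / tpm$LD_um)

  expect_error(buildScene("straight", lumenDiameterUm = 200,
                          wallThicknessUm = 10, sim = sim),
               "scene-too-large")
})

test_that("null-contrast render makes all offsets identical with zero splits", {
  sim <- smallSim(nFrames = 4L, alpha = 0,
                  flow = list(density = 0),
                  noise = list(gaussianSigma = 0, poissonGain = 0))
  sc <- buildScene("straight", sim = sim)
  r <- renderStack(sc, sim)
  for (ch in c("offset2", "offset3", "offset4"))
    expect_identical(channelFrames(r$stack, ch),
                     channelFrames(r$stack, "offset1"))
  q <- quadSplits(channelFrames(r$stack, "offset1", 1),
                  channelFrames(r$stack, "offset2", 1),
                  channelFrames(r$stack, "offset3", 1),
                  channelFrames(r$stack, "offset4", 1), 1e-9)
  expect_equal(q$horizontal@values, matrix(0, 160, 160))
})

test_that("splits of a noise-free render recover the scaled phase derivatives", {
  sim <- smallSim(nFrames = 2L, flow = list(density = 0),
                  noise = list(gaussianSigma = 0),
                  jitter = list(sigma = 0, distortedProb = 0))
  sc <- buildScene("straight", lumenDiameterUm = 40, wallThicknessUm = 6,
                   orientationDeg = 30, sim = sim)
  r <- renderStack(sc, sim)
  q <- quadSplits(channelFrames(r$stack, "offset1", 1),
                  channelFrames(r$stack, "offset2", 1),
                  channelFrames(r$stack, "offset3", 1),
                  channelFrames(r$stack, "offset4", 1),
                  1e-6 * 4 * sim@background)
  # analytic expectation: split3 = alpha*sqrt(2)*phi_x/(2B), vertical likewise
  P <- sc@fields$pad
  crop <- function(m) m[P + 1:160, P + 1:160]
  gradX <- crop((sc@fields$G[[1]] - sc@fields$G[[2]] - sc@fields$G[[3]] +
                   sc@fields$G[[4]]))
  expRes <- gradX / (4 * sim@background)
  got <- q$horizontal@values
  sel <- abs(expRes) > 0.02     # on the wall edges
  relRms <- sqrt(mean((got[sel] - expRes[sel])^2)) /
    sqrt(mean(expRes[sel]^2))
  expect_lt(relRms, 0.05)
})

test_that("a vessel parallel to a fiber pair vanishes in that split only", {
  fx <- scenePipeline("par45", orientationDeg = 45,
                      lumenDiameterUm = 40, wallThicknessUm = 5)
  edge <- fx$scene@wallMask
  c1 <- mean(abs(fx$derived@splitMean$diag1@values[edge]), na.rm = TRUE)
  c2 <- mean(abs(fx$derived@splitMean$diag2@values[edge]), na.rm = TRUE)
  expect_lt(c1, 0.2 * c2)
})

test_that("renders are deterministic given the seed", {
  sim <- smallSim(nFrames = 3L, seed = 21L)
  sc <- buildScene("straight", sim = sim)
  r1 <- renderStack(sc, sim)
  r2 <- renderStack(sc, sim)
  for (ch in channelNames(r1$stack))
    expect_identical(channelFrames(r1$stack, ch),
                     channelFrames(r2$stack, ch))
  expect_identical(r1$shifts, r2$shifts)
  expect_identical(r1$distorted, r2$distorted)
})

test_that("flow drives lumen temporal variance; no flow matches the noise floor", {
  fx <- scenePipeline("flowon", lumenDiameterUm = 40, wallThicknessUm = 5)
  sc <- fx$scene
  core <- sc@lumenMask & !is.na(fx$derived@stdMotion)
  bg <- !sc@lumenMask & !sc@wallMask & !is.na(fx$derived@stdMotion)
  ratioOn <- mean(fx$derived@stdMotion[core]) / mean(fx$derived@stdMotion[bg])
  expect_gte(ratioOn, 3)

  simOff <- smallSim(flow = list(density = 0))
  scOff <- buildScene("straight", lumenDiameterUm = 40, wallThicknessUm = 5,
                      sim = simOff)
  rOff <- renderStack(scOff, simOff)
  dvOff <- deriveAll(applyTransforms(
    rOff$stack, estimateTransforms(rOff$stack, "confocal", fx$config)),
    fx$config)
  core2 <- scOff@lumenMask & !is.na(dvOff@stdMotion)
  bg2 <- !scOff@lumenMask & !scOff@wallMask & !is.na(dvOff@stdMotion)
  ratioOff <- mean(dvOff@stdMotion[core2]) / mean(dvOff@stdMotion[bg2])
  expect_lt(abs(ratioOff - 1), 0.1)
})

test_that("simulateScene writes a complete, reloadable artifact set", {
  d <- withr::local_tempdir()
  sim <- smallSim(nFrames = 3L, seed = 30L)
  out <- simulateScene(d, sim = sim, geometry = "straight",
                       lumenDiameterUm = 40, wallThicknessUm = 5)
  expect_true(all(file.exists(out$paths)))
  st <- readStack(d, pixelScale = sim@pixelScale)
  expect_identical(channelFrames(st, "offset1"),
                   channelFrames(out$render$stack, "offset1"))
  tp <- readProfileCsv(file.path(d, "truth_profile.csv"))
  expect_equal(unique(as.data.frame(tp)$LD_um), 40)
})

test_that("excessive contrast triggers the overflow warning", {
  sim <- smallSim(nFrames = 2L, alpha = 2000, flow = list(density = 0))
  sc <- buildScene("straight", sim = sim)
  expect_warning(renderStack(sc, sim), "contrast-overflow")
})
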