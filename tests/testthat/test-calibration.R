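test_that("pedestal estimation: exact small cases and Monte-Carlo recovery", {
  ## identical darks
  darks <- array(10, c(4, 4, 3))
  est <- estimatePedestal(darks)
  expect_equal(est$pedestal, matrix(10, 4, 4))
  expect_equal(est$readNoise, matrix(0, 4, 4))
  ## two-point sample sd
  est2 <- estimatePedestal(array(c(rep(9, 16), rep(11, 16)), c(4, 4, 2)))
  expect_equal(est2$pedestal, matrix(10, 4, 4))
  expect_equal(est2$readNoise, matrix(sqrt(2), 4, 4))
  expect_error(estimatePedestal(array(1, c(4, 4, 1))), "insufficient-darks")
  ## 500 simulated darks, pedestal 20, sigma 3
  set.seed(11)
  sim <- array(rnorm(32 * 32 * 500, 20, 3), c(32, 32, 500))
  est3 <- estimatePedestal(sim)
  frac <- mean(abs(est3$pedestal - 20) <= 3 * 3 / sqrt(500))
  expect_gte(frac, 0.99)
})

test_that("common-mode correction recovers per-panel offsets robustly", {
  geom <- DetectorGeometry(100, 200, 110, 2400, c(49.5, 99.5), 7)
  layout <- panelLayout(geom, 1L, 2L, gapPx = 0L)
  cal <- CalibrationSet(matrix(0, 100, 200), readNoise = 3, gain = 33)
  ## uniform +5 offset, no signal: exactly removed
  f <- new("CalibratedFrame", data = matrix(5, 100, 200),
           panel = layout$panel, mask = cal@badPixels, id = "a",
           flaggedPanels = integer())
  out <- commonModeCorrect(f, cal)
  expect_equal(out@data, matrix(0, 100, 200))
  expect_length(out@flaggedPanels, 0)
  ## one bright pixel above the cut does not bias the median
  d <- matrix(0, 100, 200); d[3, 3] <- 1000
  f2 <- new("CalibratedFrame", data = d, panel = layout$panel,
            mask = cal@badPixels, id = "b", flaggedPanels = integer())
  out2 <- commonModeCorrect(f2, cal)
  expect_equal(out2@data, d)
  expect_length(out2@flaggedPanels, 0)
  ## a panel with no sub-threshold pixels is flagged, not corrected
  f3 <- new("CalibratedFrame", data = matrix(100, 100, 200),
            panel = layout$panel, mask = cal@badPixels, id = "c",
            flaggedPanels = integer())
  out3 <- commonModeCorrect(f3, cal)
  expect_setequal(out3@flaggedPanels, c(1L, 2L))
  expect_equal(out3@data, f3@data)
  ## simulated offsets uniform(-4, 4) with sigma = 3 noise, 1e4 px/panel
  set.seed(7)
  offs <- runif(2, -4, 4)
  noise <- matrix(rnorm(100 * 200, 0, 3), 100, 200)
  noise[, 1:100] <- noise[, 1:100] + offs[1]
  noise[, 101:200] <- noise[, 101:200] + offs[2]
  f4 <- new("CalibratedFrame", data = noise, panel = layout$panel,
            mask = cal@badPixels, id = "d", flaggedPanels = integer())
  out4 <- commonModeCorrect(f4, cal)
  expect_lt(abs(median(noise[, 1:100] - out4@data[, 1:100]) - offs[1]), 0.2)
  expect_lt(abs(median(noise[, 101:200] - out4@data[, 101:200]) - offs[2]), 0.2)
})

test_that("photonize follows the ceil rule with thresholds at (n - 0.5) gamma", {
  A <- matrix(c(16.4, 17, 49.5, 50, -100, 0), 2)
  k <- frameData(photonize(A, gamma = 33))
  expect_identical(as.vector(k), c(0L, 1L, 1L, 2L, 0L, 0L))
  expect_error(photonize(A, gamma = 0), "invalid-gain")
  expect_error(photonize(A, gamma = -1), "invalid-gain")
  ## monotone non-decreasing in A and scale covariant
  set.seed(2)
  Av <- matrix(sort(runif(500, -50, 400)), 1)
  kv <- as.vector(frameData(photonize(Av, 33)))
  expect_true(all(diff(kv) >= 0))
  for (cc in c(0.1, 2, 117)) {
    expect_identical(frameData(photonize(cc * Av, cc * 33)),
                     frameData(photonize(Av, 33)))
  }
})

test_that("noise-free simulation chain returns the generator's photons bit-exactly", {
  geom <- backGeom(64L, 64L, c(31.5, 31.5))
  cfg <- noiselessConfig(seed = 5L, beamstopRadiusPx = 0)
  shot <- simulateShot(cfg, geom, rdvSphere(), frameIndex = 3L,
                       class = "hit")
  layout <- panelLayout(geom, cfg@nPanelsRow, cfg@nPanelsCol, cfg@panelGapPx)
  cal <- CalibrationSet(matrix(cfg@pedestalMean, 64, 64), readNoise = 0,
                        gain = cfg@gain, badPixels = layout$gapMask)
  pf <- calibrateFrame(shot$raw, cal)
  ok <- !pf@mask
  expect_identical(pf@counts[ok], shot$truth$photons[ok])
})

test_that("gain estimation from flat-field histograms recovers the ADU/photon scale", {
  ## noiseless two-delta histogram: separation exactly the gain
  set.seed(3)
  nf <- 400L
  vals <- 33 * (runif(4 * 4 * nf) < 0.25)
  arr <- array(vals, c(4, 4, nf))
  cal <- CalibrationSet(matrix(0, 4, 4), readNoise = 0.5, gain = 33)
  g <- estimateGain(arr, cal, minFrames = 100L)
  expect_true(all(abs(g - 33) < 0.1))
  ## realistic: gamma 33, read noise 4, occupancy 0.2, 2000 frames
  set.seed(4)
  npx <- 12L * 12L
  k <- rpois(npx * 2000, 0.2)
  arr2 <- array(33 * k + rnorm(npx * 2000, 0, 4), c(12, 12, 2000))
  cal2 <- CalibrationSet(matrix(0, 12, 12), readNoise = 4, gain = 33)
  g2 <- estimateGain(arr2, cal2)
  okFrac <- mean(abs(g2 - 33) / 33 < 0.05, na.rm = TRUE)
  expect_gte(okFrac, 0.95)
  expect_lt(mean(is.na(g2)), 0.05)
  ## all-zero frames: nothing to fit
  zero <- array(0, c(4, 4, 200))
  gz <- estimateGain(zero, cal, minFrames = 100L)
  expect_true(all(is.na(gz)))
  expect_error(estimateGain(zero, cal, minFrames = 100L, strict = TRUE),
               "insufficient-statistics")
  expect_error(estimateGain(arr2[, , 1:10], cal2), "insufficient-statistics")
})

test_that("background averaging uses only non-hit, non-dark frames", {
  one <- matrix(1, 4, 4)
  stack <- array(c(one * 0, one * 2, one * 100, one * 50), c(4, 4, 4))
  labels <- c("blank", "blank", "hit", "dark")
  expect_equal(averageBackground(stack, labels), one)
  expect_equal(averageBackground(stack[, , 1, drop = FALSE], "blank"),
               one * 0)
  expect_error(averageBackground(stack, c("hit", "hit", "dark", "dark")),
               "no-background-frames")
  ## 1000 Poisson(0.05) blanks: detector-average background within 5%
  set.seed(9)
  blanks <- array(rpois(32 * 32 * 1000, 0.05), c(32, 32, 1000))
  bg <- averageBackground(blanks, rep("blank", 1000))
  expect_lt(abs(mean(bg) - 0.05) / 0.05, 0.05)
})
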