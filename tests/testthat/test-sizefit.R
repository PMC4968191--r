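test_that("sphere fit is self-consistent on the exact model pattern", {
  geom <- backGeom()
  pm <- buildPixelMap(geom)
  n71 <- sphereExpectedPhotons(rdvSphere(71), 1e11, pm)
  res <- fitSphere(n71, pm)
  expect_true(res@converged)
  expect_lt(abs(res@diameter - 71), 0.05)
  expect_lt(abs(res@fluence - 1e11) / 1e11, 0.01)
  expect_error(fitSphere(matrix(0, 185, 194), pm), "unfittable")
})

test_that("profiled fluence equals the brute-force 1-D maximizer", {
  geom <- backGeom(64L, 64L, c(31.5, 31.5))
  pm <- buildPixelMap(geom)
  set.seed(14)
  k <- matrix(rpois(64 * 64, sphereExpectedPhotons(rdvSphere(71), 1e11, pm)),
              64, 64)
  res <- fitSphere(k, pm, diamRange = c(60, 80))
  ## brute-force scan of the fluence at the fitted diameter
  bm <- sphereBinModel(pm, NULL, res@diameter)
  kb <- spidiff:::.binCounts(k, bm$binIdx, bm$ok, bm$nBins)
  mb <- bm$M[, 1]
  grid <- res@fluence * seq(0.97, 1.03, length.out = 4001)
  ll <- vapply(grid, function(phi) {
    mu <- phi * mb
    pos <- mu > 0
    sum(kb[pos] * log(mu[pos]) - mu[pos])
  }, numeric(1))
  expect_lt(abs(grid[which.max(ll)] - res@fluence) / res@fluence, 0.001)
})

test_that("Poisson shots at 71 nm are recovered with small bias", {
  geom <- backGeom()
  pm <- buildPixelMap(geom)
  cfg <- studyConfig(seed = 41L)
  layout <- panelLayout(geom, cfg@nPanelsRow, cfg@nPanelsCol, cfg@panelGapPx)
  mask <- layout$gapMask | (pm@radiusPx < cfg@beamstopRadiusPx)
  set.seed(41)
  n71 <- sphereExpectedPhotons(rdvSphere(71), 1e11, pm)
  shots <- array(rpois(length(n71) * 40, n71), c(dim(n71), 40))
  fits <- fitSphereStack(shots, pm, mask = mask)
  expect_true(all(fits$converged))
  expect_lt(abs(median(fits$diameter) - 71) / 71, 0.02)
})

test_that("fitted diameter is invariant to a constant rescaling of the rates", {
  geom <- backGeom(96L, 96L, c(47.5, 47.5))
  pm <- buildPixelMap(geom)
  set.seed(15)
  k <- matrix(rpois(96 * 96, sphereExpectedPhotons(rdvSphere(71), 1e11, pm)),
              96, 96)
  r1 <- fitSphere(k, pm, diamRange = c(55, 90))
  ## doubling every model rate (via the composition ratio) only moves fluence
  r2 <- fitSphere(k, pm, diamRange = c(55, 90),
                  electronsPerDalton = 0.53 * sqrt(2))
  expect_lt(abs(r1@diameter - r2@diameter), 0.01)
  expect_lt(abs(r2@fluence - r1@fluence / 2) / (r1@fluence / 2), 0.01)
})

test_that("featureless frames are rejected, clusters fail single-particle checks", {
  geom <- backGeom(96L, 96L, c(47.5, 47.5))
  pm <- buildPixelMap(geom)
  set.seed(16)
  flat <- matrix(rpois(96 * 96, 2), 96, 96)
  rf <- fitSphere(flat, pm)
  expect_true(!rf@converged || rf@deviance > 2.5 * rf@nBins)
  ## simulated multi-particle clusters: > 90% rejected
  cfg <- studyConfig(seed = 42L, centerDriftPx = 0)
  layout <- panelLayout(geom, cfg@nPanelsRow, cfg@nPanelsCol, cfg@panelGapPx)
  mask <- layout$gapMask | (pm@radiusPx < cfg@beamstopRadiusPx)
  shots <- lapply(1:20, function(i)
    simulateShot(cfg, geom, rdvSphere(), layout = layout, frameIndex = i,
                 class = "cluster")$truth$photons)
  fits <- fitSphereStack(shots, pm, mask = mask)
  rejected <- !fits$converged | !fits$singleParticle
  expect_gte(mean(rejected), 0.9)
})

test_that("a known uniform background is absorbed by the background-aware fit", {
  geom <- backGeom()
  pm <- buildPixelMap(geom)
  cfg <- studyConfig(seed = 44L)
  layout <- panelLayout(geom, cfg@nPanelsRow, cfg@nPanelsCol, cfg@panelGapPx)
  mask <- layout$gapMask | (pm@radiusPx < cfg@beamstopRadiusPx)
  ds <- vapply(1:6, function(i) {
    sh <- simulateShot(cfg, geom, rdvSphere(), layout = layout,
                       frameIndex = i, class = "hit")
    fitSphere(sh$truth$photons, pm, mask = mask,
              background = cfg@backgroundRate)@diameter
  }, numeric(1))
  expect_lt(abs(median(ds) - 71) / 71, 0.01)
  ## ignoring the background leaves large unmodelled residuals
  sh <- simulateShot(cfg, geom, rdvSphere(), layout = layout,
                     frameIndex = 1L, class = "hit")
  f0 <- fitSphere(sh$truth$photons, pm, mask = mask)
  fb <- fitSphere(sh$truth$photons, pm, mask = mask,
                  background = cfg@backgroundRate)
  expect_gt(f0@deviance, 5 * fb@deviance)
})

test_that("single-particle window is a closed interval and needs convergence", {
  mk <- function(d, dev = 10, conv = TRUE)
    new("SizeFitResult", diameter = d, fluence = 1, deviance = dev,
        logLik = 0, nBins = 100L, converged = conv, singleParticle = NA)
  expect_true(classifySingleParticle(mk(71))@singleParticle)
  expect_false(classifySingleParticle(mk(140))@singleParticle)
  expect_true(classifySingleParticle(mk(60))@singleParticle)   # d == lower edge
  expect_true(classifySingleParticle(mk(85))@singleParticle)   # d == upper edge
  expect_false(classifySingleParticle(mk(71, dev = 1e6))@singleParticle)
  expect_error(classifySingleParticle(mk(71, conv = FALSE)), "not-classifiable")
})
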