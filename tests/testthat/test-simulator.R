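test_that("sphere model: forward limit, fluence linearity, electron bookkeeping", {
  geom <- backGeom(65L, 65L, c(32, 32))
  pm <- buildPixelMap(geom)
  m <- rdvSphere(71)
  n <- sphereExpectedPhotons(m, 1e11, pm)
  ## q = 0 pixel: form factor exactly 1
  Ne <- sphereElectronCount(m)
  expect_equal(n[33, 33],
               1e11 * (2.8179403262e-9)^2 * pm@solidAngle[33, 33] * Ne^2)
  ## linear in fluence
  expect_equal(sphereExpectedPhotons(m, 2e11, pm), 2 * n)
  expect_equal(max(abs(sphereExpectedPhotons(m, 0, pm))), 0)
  ## total expected photons monotone increasing in diameter
  tot <- vapply(seq(50, 100, by = 10), function(d)
    sum(sphereExpectedPhotons(rdvSphere(d), 1e11, pm)), numeric(1))
  expect_true(all(diff(tot) > 0))
})

test_that("first intensity zero of a 71 nm sphere sits near 77.8 px on the back detector", {
  ## independent oracle: first root of 3(sin u - u cos u)/u^3
  uStar <- uniroot(function(u) 3 * (sin(u) - u * cos(u)) / u^3,
                   c(4, 5), tol = 1e-10)$root
  expect_equal(uStar, 4.4934, tolerance = 1e-4)
  geom <- backGeom()
  lam <- wavelength(geom)
  qStar <- uStar / (35.5 * 10)               # u = qR, R in Angstrom
  alpha <- 2 * asin(qStar * lam / (4 * pi))
  rOracle <- 2400 * tan(alpha) / 0.110       # 77.84 px
  expect_equal(rOracle, 77.8, tolerance = 0.01)
  ## the package's 2-D pattern has its first radial minimum there
  pm <- buildPixelMap(geom)
  rp <- radialAverage(sphereExpectedPhotons(rdvSphere(71), 1e11, pm), pm,
                      binWidth = 0.5)
  mid <- (rp@rLo + rp@rHi) / 2
  win <- which(mid > 60 & mid < 92 & !is.na(rp@mean))
  rMin <- mid[win][which.min(rp@mean[win])]
  expect_lt(abs(rMin - rOracle), 0.5)
})

test_that("sphere pattern is radially symmetric about the true beam centre", {
  geom <- backGeom(65L, 65L, c(32, 32))
  pm <- buildPixelMap(geom)
  n <- sphereExpectedPhotons(rdvSphere(71), 1e11, pm)
  ## pixels at exactly equal radius (reflections of the integer centre)
  for (off in list(c(5, 12), c(20, 9), c(1, 30))) {
    vals <- c(n[33 + off[1], 33 + off[2]], n[33 - off[1], 33 - off[2]],
              n[33 + off[2], 33 + off[1]], n[33 - off[2], 33 + off[1]])
    expect_lt(max(abs(vals - vals[1])) / vals[1], 1e-9)
  }
})

test_that("icosahedral blob shell: symmetry, degenerate blob, orientation contrast", {
  geom <- backGeom(65L, 65L, c(32, 32))
  pm <- buildPixelMap(geom)
  model <- IcosaBlobModel(circumRadiusNm = 35.4, blobRadiusNm = 11,
                          nElectrons = 8.2e7)
  n0 <- icosaExpectedPhotons(model, 1e11, NULL, pm)
  ## a 72-degree rotation about a vertex axis permutes the vertex set
  axis <- icosahedronVertices()[1, ]
  g <- axisAngleQuat(axis, 2 * pi / 5)
  n1 <- icosaExpectedPhotons(model, 1e11, g, pm)
  expect_lt(max(abs(n1 - n0)) / max(n0), 1e-9)
  ## unnormalized quaternion rejected
  expect_error(icosaExpectedPhotons(model, 1e11, c(2, 0, 0, 0), pm),
               "invalid-orientation")
  ## blobs collapsed onto the origin: a spherical, orientation-free profile
  tiny <- IcosaBlobModel(circumRadiusNm = 1e-9, blobRadiusNm = 11,
                         nElectrons = 8.2e7)
  set.seed(21)
  q1 <- as.vector(randomQuaternion(1)); q2 <- as.vector(randomQuaternion(1))
  a <- icosaExpectedPhotons(tiny, 1e11, q1, pm)
  b <- icosaExpectedPhotons(tiny, 1e11, q2, pm)
  expect_equal(a, b, tolerance = 1e-9)
  fb <- 8.2e7 * sphereFormFactor(pm@q * 110)
  expect_equal(a, 1e11 * (2.8179403262e-9)^2 * pm@solidAngle * fb^2,
               tolerance = 1e-9)
  ## distinct orientations give distinct patterns beyond the first fringe
  set.seed(22)
  qa <- as.vector(randomQuaternion(1)); qb <- as.vector(randomQuaternion(1))
  pa <- icosaExpectedPhotons(model, 1e11, qa, pm)
  pb <- icosaExpectedPhotons(model, 1e11, qb, pm)
  outer <- pm@radiusPx > 30
  expect_gt(max(abs(pa[outer] - pb[outer]) /
                pmax(pa[outer], pb[outer], 1e-300)), 0.01)
})

test_that("shot simulation: exact noise-free rendering and dark frames", {
  geom <- backGeom(48L, 48L, c(23.5, 23.5))
  cfg <- noiselessConfig(seed = 2L, backgroundRate = 0)
  shot <- simulateShot(cfg, geom, rdvSphere(), frameIndex = 1L, class = "hit")
  expect_equal(shot$raw@data,
               shot$truth$photons * cfg@gain + cfg@pedestalMean)
  dk <- simulateShot(cfg, geom, rdvSphere(), frameIndex = 2L, class = "dark")
  expect_true(all(dk$truth$photons == 0L))
  expect_equal(dk$raw@data, matrix(cfg@pedestalMean, 48, 48))
})

test_that("fluence jitter follows the configured log-normal", {
  geom <- backGeom(16L, 16L, c(7.5, 7.5))
  cfg <- ShotConfig(seed = 31L, beamstopRadiusPx = 0)
  flu <- vapply(seq_len(1000L), function(i)
    simulateShot(cfg, geom, rdvSphere(), frameIndex = i,
                 class = "hit")$truth$fluence, numeric(1))
  ks <- suppressWarnings(
    ks.test(flu, plnorm, meanlog = log(cfg@fluence0), sdlog = cfg@fluenceSdLog))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1000))  # 1% critical value
})

test_that("class mix respects the configured hit fraction (binomial bound)", {
  geom <- backGeom(8L, 8L, c(3.5, 3.5))
  cfg <- ShotConfig(seed = 13L, beamstopRadiusPx = 0, clusterFraction = 0,
                    darkFraction = 0)
  cls <- vapply(seq_len(2000L), function(i)
    simulateShot(cfg, geom, rdvSphere(), frameIndex = i)$truth$class,
    character(1))
  nHits <- sum(cls == "hit")
  expect_lt(abs(nHits - 200), 3 * sqrt(2000 * 0.1 * 0.9))
})

test_that("centre of intensity tracks injected beam-centre drift one-for-one", {
  geom <- backGeom(301L, 301L, c(150, 150))
  drifts <- c(0, 0.5, 1, 1.5, 2)
  coi <- vapply(drifts, function(dr) {
    pm <- buildPixelMap(geom, center = c(150, 150 + dr))
    n <- sphereExpectedPhotons(rdvSphere(71), 1e11, pm)
    centerOfIntensity(n)[2]
  }, numeric(1))
  slope <- coef(lm(coi ~ drifts))[2]
  expect_lt(abs(slope - 1), 0.02)
})

test_that("simulated runs are reproducible and empty runs are valid", {
  geom <- backGeom(32L, 32L, c(15.5, 15.5))
  cfg <- ShotConfig(seed = 8L)
  p1 <- tempfile(fileext = ".cxi"); p2 <- tempfile(fileext = ".cxi")
  r1 <- simulateRun(cfg, geom, rdvSphere(), 25L, p1)
  r2 <- simulateRun(cfg, geom, rdvSphere(), 25L, p2)
  expect_identical(getFrames(readCxi(p1)), getFrames(readCxi(p2)))
  expect_identical(readTruth(r1$truthPath)$table, readTruth(r2$truthPath)$table)
  ## zero frames: still a valid, readable file
  p0 <- tempfile(fileext = ".cxi")
  simulateRun(cfg, geom, rdvSphere(), 0L, p0)
  ds0 <- readCxi(p0)
  expect_identical(nFrames(ds0), 0L)
  unlink(c(p1, p2, p0, paste0(c(p1, p2, p0), ".truth.h5")))
})
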