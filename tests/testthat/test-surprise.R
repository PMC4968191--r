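test_that("Poisson log-pmf: e^-1 cases, zero-rate conventions, validation", {
  expect_equal(poissonLogPmf(1, 0), -1)
  expect_equal(poissonLogPmf(1, 1), -1)
  expect_equal(poissonLogPmf(2, 2), log(2) - 2)
  expect_identical(poissonLogPmf(0, 0), 0)
  expect_identical(poissonLogPmf(0, 3), -Inf)
  expect_error(poissonLogPmf(1, -1), "invalid-count")
  expect_error(poissonLogPmf(1, 1.5), "invalid-count")
})

test_that("surprise score: additivity and the infinite flag", {
  expect_equal(as.numeric(surpriseScore(matrix(1L), matrix(1))), 1)
  expect_equal(as.numeric(surpriseScore(matrix(c(1L, 0L), 1), matrix(c(1, 1), 1))), 2)
  s <- surpriseScore(matrix(c(2L, 0L), 1), matrix(c(0, 1), 1))
  expect_identical(as.numeric(s), Inf)
  expect_true(attr(s, "infinite"))
  ## masked zero-rate pixel does not trigger infinity
  pf <- PhotonFrame(matrix(c(2L, 1L), 1), mask = matrix(c(TRUE, FALSE), 1))
  s2 <- surpriseScore(pf, matrix(c(0, 1), 1))
  expect_equal(as.numeric(s2), 1)
  expect_error(surpriseScore(matrix(1L), matrix(1, 2, 2)),
               "incompatible-inputs")
})

test_that("expected surprise and sigma match the high-precision oracle", {
  for (n in c(0.01, 0.1, 1, 10, 100)) {
    oracle <- bruteNllMoments(n)
    sdOracle <- sqrt(oracle$second - oracle$mean^2)
    expect_lt(abs(expectedSurprise(matrix(n)) - oracle$mean) / oracle$mean,
              1e-9)
    expect_lt(abs(surpriseStd(matrix(n)) - sdOracle) / sdOracle, 1e-9)
  }
  ## frozen single-pixel values at n = 1
  expect_equal(expectedSurprise(matrix(1)), 1.3048, tolerance = 1e-4)
  expect_equal(surpriseStd(matrix(1)), 0.6678, tolerance = 1e-4)
  ## additivity of the mean, additivity of the variance, zero-rate pixels
  expect_identical(expectedSurprise(matrix(0, 3, 3)), 0)
  expect_identical(surpriseStd(matrix(0, 3, 3)), 0)
  n2 <- matrix(c(0.4, 7), 1)
  expect_equal(expectedSurprise(n2),
               expectedSurprise(matrix(0.4)) + expectedSurprise(matrix(7)))
  expect_equal(surpriseStd(n2)^2,
               surpriseStd(matrix(0.4))^2 + surpriseStd(matrix(7))^2)
})

test_that("z-score is calibrated under the true model and permutation invariant", {
  geom <- backGeom(64L, 64L, c(31.5, 31.5))
  pm <- buildPixelMap(geom)
  n <- sphereExpectedPhotons(rdvSphere(71), 1e11, pm)
  n <- n * 0.1 / mean(n)              # mean 0.1 photons per pixel
  ES <- expectedSurprise(n)
  sig <- surpriseStd(n)
  set.seed(51)
  nrep <- 300L
  k <- matrix(rpois(length(n) * nrep, n), length(n), nrep)
  S <- -colSums(dpois(k, as.vector(n), log = TRUE))
  z <- (S - ES) / sig
  expect_lt(abs(mean(z)), 0.2)
  expect_gt(sd(z), 0.85)
  expect_lt(sd(z), 1.15)
  ## permutation invariance
  kk <- matrix(k[, 1], nrow(n), ncol(n))
  z0 <- zScore(kk, n)@z
  set.seed(52)
  perm <- sample(length(n))
  zp <- zScore(matrix(kk[perm], nrow(n)), matrix(n[perm], nrow(n)))@z
  expect_equal(zp, z0)
  ## degenerate model
  expect_error(zScore(matrix(0L), matrix(0)), "degenerate-model")
})

test_that("model mismatch inflates z monotonically with diameter error", {
  geom <- backGeom(96L, 96L, c(47.5, 47.5))
  pm <- buildPixelMap(geom)
  truth <- sphereExpectedPhotons(rdvSphere(71), 1e11, pm)
  errs <- c(0, 0.05, 0.10)
  set.seed(53)
  medz <- vapply(errs, function(e) {
    n <- sphereExpectedPhotons(rdvSphere(71 * (1 + e)), 1e11, pm)
    ES <- expectedSurprise(n); sig <- surpriseStd(n)
    z <- vapply(1:25, function(i) {
      k <- matrix(rpois(length(truth), truth), nrow(truth))
      (as.numeric(surpriseScore(k, n)) - ES) / sig
    }, numeric(1))
    median(z)
  }, numeric(1))
  expect_true(all(diff(medz) >= 0))
  expect_lt(abs(medz[1]), 3)
  expect_gt(medz[3], 10)
})

test_that("surprise minimization scans fluence and orientation grids correctly", {
  geom <- backGeom(48L, 48L, c(23.5, 23.5))
  pm <- buildPixelMap(geom)
  n0 <- sphereExpectedPhotons(rdvSphere(71), 1, pm)   # unit fluence
  phiTrue <- 1e11
  k <- round(phiTrue * n0)
  storage.mode(k) <- "integer"
  ## single grid point: equals the direct z-score
  one <- minimizeSurprise(k, n0, phiTrue)
  direct <- zScore(k, phiTrue * n0)
  expect_equal(one@S, direct@S)
  expect_equal(one@z, direct@z)
  expect_equal(one@fluence, phiTrue)
  ## true fluence on a grid: recovered exactly
  grid <- phiTrue * c(0.25, 0.5, 1, 2, 4)
  best <- minimizeSurprise(k, n0, grid)
  expect_equal(best@fluence, phiTrue)
  expect_error(minimizeSurprise(k, list(), grid), "invalid-search")
  expect_error(minimizeSurprise(k, n0, numeric()), "invalid-search")
})

test_that("orientation recovery on an icosahedral grid finds the true pattern", {
  geom <- backGeom(64L, 64L, c(31.5, 31.5))
  pm <- buildPixelMap(geom)
  model <- IcosaBlobModel()
  set.seed(54)
  nOrient <- 150L
  quats <- randomQuaternion(nOrient)
  ## unit-fluence patterns for each candidate orientation, plus a floor
  pats <- lapply(seq_len(nOrient), function(i)
    icosaExpectedPhotons(model, 1, quats[i, ], pm))
  ## pick a target fluence giving roughly 1e4 photons per shot
  phi <- 1e4 / sum(pats[[1]])
  fluGrid <- phi * c(0.5, 0.75, 1, 1.5, 2)
  nShots <- 40L
  hits <- vapply(seq_len(nShots), function(s) {
    iTrue <- sample.int(nOrient, 1L)
    nTrue <- phi * pats[[iTrue]]
    k <- matrix(rpois(length(nTrue), nTrue), nrow(nTrue))
    res <- minimizeSurprise(k, pats, fluGrid, floor = 1e-8,
                            orientations = quats)
    iRec <- attr(res, "modelIndex")
    ## success: recovered pattern is the true one (up to symmetry)
    max(abs(pats[[iRec]] - pats[[iTrue]])) / max(pats[[iTrue]]) < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
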