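## Shared fixtures: the two detector geometries of a tandem SPI setup, scaled
## generator configs, and small convenience builders used across test files.

## Small-angle ("back") detector: 2.4 m downstream, 110 um pixels, 7 keV.
## Test-sized pixel grid; centre chosen so the first sphere fringe (~78 px)
## is on the detector.
backGeom <- function(nRows = 185L, nCols = 194L,
                     center = c(92, 96.5), energy = 7)
  DetectorGeometry(nRows, nCols, 110, 2400, center, energy)

## Wide-angle ("front") detector: 217.4 mm downstream.
frontGeom <- function(nRows = 600L, nCols = 600L,
                      center = c(300, 300), energy = 7)
  DetectorGeometry(nRows, nCols, 110, 217.4, center, energy)

## A noiseless rendering chain: exact gain, no pedestal spread, no read
## noise, no drift or fluence jitter.
noiselessConfig <- function(...) {
  ShotConfig(fluenceSdLog = 0, centerDriftPx = 0, pedestalSd = 0,
             readNoise = 0, gainSpread = 0, ...)
}

## Default study-condition config with a test seed.
studyConfig <- function(...) ShotConfig(...)

rdvSphere <- function(d = 71) SphereModel(d)

## Brute-force radial binning oracle: explicit double loop over pixels.
bruteRadialAverage <- function(x, map, ok, binWidth = 1) {
  nb <- 0L
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    if (ok[i, j]) nb <- max(nb, floor(map@radiusPx[i, j] / binWidth) + 1L)
  sums <- numeric(nb); npx <- integer(nb)
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    if (!ok[i, j]) next
    b <- floor(map@radiusPx[i, j] / binWidth) + 1L
    sums[b] <- sums[b] + x[i, j]
    npx[b] <- npx[b] + 1L
  }
  list(mean = ifelse(npx > 0, sums / npx, NA_real_), npix = npx)
}

## High-precision Poisson log-pmf moment oracle: direct summation with the
## upper tail below 1e-15.
bruteNllMoments <- function(n) {
  if (n == 0) return(list(mean = 0, second = 0))
  kmax <- 10
  while (ppois(kmax, n, lower.tail = FALSE) >= 1e-15) kmax <- kmax * 2
  k <- 0:kmax
  lp <- dpois(k, n, log = TRUE)
  p <- exp(lp)
  keep <- p > 0
  list(mean = -sum(p[keep] * lp[keep]),
       second = sum(p[keep] * lp[keep]^2))
}
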