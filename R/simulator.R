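## Synthetic-data generator.
##
## A simulated run mixes frame classes (single-particle hits, multi-particle
## clusters, blanks, darks, optionally flat-fields) and emulates the
## statistical structure the analysis has to cope with: shot-to-shot
## log-normal fluence jitter, ~1-pixel Gaussian beam-centre drift, a uniform
## instrument background, a semi-transparent circular beamstop, panel gaps,
## and ADU rendering through per-pixel pedestal / read noise / gain.

#' Shot-simulation configuration
#'
#' All tunable conditions of a simulated run.  Defaults describe a hard
#' X-ray SPI run on a small-angle back detector: median fluence 1e11
#' photons/um^2 with log-normal jitter (sdlog 0.3), 0.5 px beam-centre
#' drift per axis, 10% single-particle hits, 2% two-to-three-particle
#' clusters, 5% darks, a 0.05 photon/px background, a 20 px beamstop of 1%
#' transmission, and 33 ADU/photon conversion over a 20 ADU pedestal with
#' 3 ADU read noise.
#'
#' @slot fluence0 median incident fluence (photons/um^2).
#' @slot fluenceSdLog log-normal jitter (sdlog) of the fluence.
#' @slot centerDriftPx beam-centre drift standard deviation per axis (px).
#' @slot hitFraction,clusterFraction,darkFraction,flatfieldFraction class
#'   probabilities; the remainder are blanks.
#' @slot clusterSizeRange integer(2), min/max particles in a cluster.
#' @slot flatfieldRate flat-field occupancy (photons/pixel/frame).
#' @slot backgroundRate uniform background (photons/pixel/frame).
#' @slot beamstopRadiusPx,beamstopTransmission semi-transparent beamstop.
#' @slot pedestalMean,pedestalSd,readNoise,gain,gainSpread ADU rendering:
#'   per-pixel pedestals ~ N(pedestalMean, pedestalSd), per-pixel gains ~
#'   gain * N(1, gainSpread), Gaussian read noise (ADU).
#' @slot nPanelsRow,nPanelsCol,panelGapPx readout panel layout; gap pixels
#'   are masked.
#' @slot maskBeamstop mask the beamstop region in the per-frame mask?
#' @slot seed run seed (integer).
#' @export
setClass("ShotConfig",
  slots = c(
    fluence0 = "numeric", fluenceSdLog = "numeric", centerDriftPx = "numeric",
    hitFraction = "numeric", clusterFraction = "numeric",
    darkFraction = "numeric", flatfieldFraction = "numeric",
    clusterSizeRange = "integer", flatfieldRate = "numeric",
    backgroundRate = "numeric",
    beamstopRadiusPx = "numeric", beamstopTransmission = "numeric",
    pedestalMean = "numeric", pedestalSd = "numeric", readNoise = "numeric",
    gain = "numeric", gainSpread = "numeric",
    nPanelsRow = "integer", nPanelsCol = "integer", panelGapPx = "integer",
    maskBeamstop = "logical", seed = "integer"
  )
)

setValidity("ShotConfig", function(object) {
  fr <- c(object@hitFraction, object@clusterFraction, object@darkFraction,
          object@flatfieldFraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    return("class fractions must lie in [0,1] and sum to at most 1")
  if (object@fluence0 < 0 || object@fluenceSdLog < 0 ||
      object@backgroundRate < 0 || object@flatfieldRate < 0 ||
      object@centerDriftPx < 0)
    return("rates and spreads must be non-negative")
  if (object@beamstopTransmission < 0 || object@beamstopTransmission > 1)
    return("beamstop transmission must lie in [0,1]")
  if (object@gain <= 0) return("gain must be positive")
  TRUE
})

#' @param ... named slot overrides, see the class slots.
#' @rdname ShotConfig-class
#' @export
ShotConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    fluence0 = 1e11, fluenceSdLog = 0.3, centerDriftPx = 0.5,
    hitFraction = 0.10, clusterFraction = 0.02, darkFraction = 0.05,
    flatfieldFraction = 0, clusterSizeRange = c(2L, 3L),
    flatfieldRate = 0.2, backgroundRate = 0.05,
    beamstopRadiusPx = 20, beamstopTransmission = 0.01,
    pedestalMean = 20, pedestalSd = 2, readNoise = 3,
    gain = 33, gainSpread = 0.05,
    nPanelsRow = 2L, nPanelsCol = 2L, panelGapPx = 2L,
    maskBeamstop = TRUE, seed = 1L)
  defaults[names(args)] <- args
  ints <- c("clusterSizeRange", "nPanelsRow", "nPanelsCol", "panelGapPx",
            "seed")
  for (s in ints) defaults[[s]] <- as.integer(defaults[[s]])
  do.call(new, c(list("ShotConfig"), defaults))
}

setMethod("show", "ShotConfig", function(object) {
  cat(sprintf(
    "ShotConfig: fluence %.3g ph/um^2 (sdlog %.2f), drift %.2f px, seed %d\n",
    object@fluence0, object@fluenceSdLog, object@centerDriftPx, object@seed))
  cat(sprintf(
    "  classes: hit %.2f cluster %.2f dark %.2f flatfield %.2f blank %.2f\n",
    object@hitFraction, object@clusterFraction, object@darkFraction,
    object@flatfieldFraction,
    1 - object@hitFraction - object@clusterFraction - object@darkFraction -
      object@flatfieldFraction))
})

#' Panel layout: labels and gap mask
#'
#' Splits the pixel grid into a regular grid of readout panels and masks a
#' gap of \code{gapPx} rows/columns at each internal boundary.
#'
#' @param geom a [DetectorGeometry-class].
#' @param nPanelsRow,nPanelsCol panel grid.
#' @param gapPx gap width at each internal panel boundary (masked pixels).
#' @return list(panel = integer matrix of labels, gapMask = logical matrix).
#' @export
panelLayout <- function(geom, nPanelsRow = 2L, nPanelsCol = 2L, gapPx = 2L) {
  rIdx <- pmin(((seq_len(geom@nRows) - 1L) * nPanelsRow) %/% geom@nRows,
               nPanelsRow - 1L)
  cIdx <- pmin(((seq_len(geom@nCols) - 1L) * nPanelsCol) %/% geom@nCols,
               nPanelsCol - 1L)
  panel <- outer(rIdx, cIdx, function(r, c) r * nPanelsCol + c + 1L)
  storage.mode(panel) <- "integer"
  gapMask <- matrix(FALSE, geom@nRows, geom@nCols)
  if (gapPx > 0L) {
    rb <- which(diff(rIdx) != 0L)
    for (b in rb) {
      rows <- (b - gapPx %/% 2L + 1L):(b + (gapPx + 1L) %/% 2L)
      rows <- rows[rows >= 1L & rows <= geom@nRows]
      gapMask[rows, ] <- TRUE
    }
    cb <- which(diff(cIdx) != 0L)
    for (b in cb) {
      cols <- (b - gapPx %/% 2L + 1L):(b + (gapPx + 1L) %/% 2L)
      cols <- cols[cols >= 1L & cols <= geom@nCols]
      gapMask[, cols] <- TRUE
    }
  }
  list(panel = panel, gapMask = gapMask)
}

## Calibration truth of a simulated run (per-pixel pedestal / gain maps),
## derived deterministically from the run seed.
.simCalibration <- function(config, geom, layout) {
  set.seed(.frameSeed(config@seed, 0L))
  n <- geom@nRows * geom@nCols
  pedestal <- matrix(rnorm(n, config@pedestalMean, config@pedestalSd),
                     geom@nRows, geom@nCols)
  gain <- matrix(config@gain * (1 + config@gainSpread * rnorm(n)),
                 geom@nRows, geom@nCols)
  gain[gain < config@gain * 0.2] <- config@gain * 0.2
  readNoise <- matrix(config@readNoise, geom@nRows, geom@nCols)
  CalibrationSet(pedestal, readNoise, gain, badPixels = layout$gapMask)
}

## Expected photons of one m-particle cluster: coherent sum of m identical
## spheres in touching-contact chain positions with random link directions.
.clusterExpected <- function(model, m, fluence, map) {
  geom <- map@geometry
  twoPiLam <- 2 * pi / geom@wavelength
  qx <- twoPiLam * map@xMm / geom@distance
  qy <- twoPiLam * map@yMm / geom@distance
  dAng <- model@diameter * 10
  pos <- matrix(0, m, 3L)
  for (j in seq_len(m)[-1L]) {
    u <- rnorm(3L); u <- u / sqrt(sum(u^2))
    pos[j, ] <- pos[j - 1L, ] + dAng * u
  }
  re <- 0 * qx; im <- re
  for (j in seq_len(m)) {
    phase <- qx * pos[j, 1L] + qy * pos[j, 2L]
    re <- re + cos(phase)
    im <- im + sin(phase)
  }
  Ne <- sphereElectronCount(model)
  f <- sphereFormFactor(map@q * model@diameter * 10 / 2)
  fluence * .re_um^2 * map@solidAngle * (Ne * f)^2 * (re^2 + im^2) / 1
}

#' Simulate a single detector exposure
#'
#' Samples the frame class, fluence (log-normal), beam-centre drift
#' (Gaussian) and particle orientation (uniform over rotations), computes
#' the expected photon grid, adds the uniform background, attenuates the
#' beamstop region, Poisson-samples photon counts and renders ADU through
#' the per-pixel calibration.  Deterministic given \code{config@seed} and
#' \code{frameIndex}, independent of simulation order.
#'
#' @param config a [ShotConfig-class].
#' @param geom a [DetectorGeometry-class].
#' @param model a [SphereModel-class] or [IcosaBlobModel-class].
#' @param cal per-pixel calibration truth; built from the config when NULL.
#' @param layout panel layout from [panelLayout()]; built when NULL.
#' @param frameIndex 1-based frame counter selecting the RNG substream.
#' @param class force a frame class instead of sampling one.
#' @return list(raw = [RawFrame-class], truth = list(class, fluence,
#'   diameter, nParticles, orientation, center, photons, mask)).
#' @export
simulateShot <- function(config, geom, model, cal = NULL, layout = NULL,
                         frameIndex = 1L, class = NULL) {
  validObject(config)
  if (is.null(layout))
    layout <- panelLayout(geom, config@nPanelsRow, config@nPanelsCol,
                          config@panelGapPx)
  if (is.null(cal)) cal <- .simCalibration(config, geom, layout)
  set.seed(.frameSeed(config@seed, frameIndex))
  if (is.null(class)) {
    u <- runif(1)
    cuts <- cumsum(c(config@darkFraction, config@flatfieldFraction,
                     config@clusterFraction, config@hitFraction))
    class <- c("dark", "flatfield", "cluster", "hit", "blank")[
      findInterval(u, cuts) + 1L]
  }
  nr <- geom@nRows; nc <- geom@nCols
  fluence <- NA_real_
  orientation <- rep(NA_real_, 4L)
  center <- geom@beamCenter
  nParticles <- 0L
  expected <- matrix(0, nr, nc)
  if (class %in% c("hit", "cluster")) {
    fluence <- rlnorm(1L, log(config@fluence0), config@fluenceSdLog)
    center <- geom@beamCenter + rnorm(2L, 0, config@centerDriftPx)
    orientation <- as.vector(randomQuaternion(1L))
    map <- buildPixelMap(geom, center = center)
    if (class == "hit") {
      nParticles <- 1L
      expected <- if (is(model, "SphereModel"))
        sphereExpectedPhotons(model, fluence, map)
      else icosaExpectedPhotons(model, fluence, orientation, map)
    } else {
      nParticles <- as.integer(
        sample(seq(config@clusterSizeRange[1L], config@clusterSizeRange[2L]),
               1L))
      sphere <- if (is(model, "SphereModel")) model
                else SphereModel(2 * model@circumRadius)
      expected <- .clusterExpected(sphere, nParticles, fluence, map)
    }
  }
  bsMask <- matrix(FALSE, nr, nc)
  if (class == "flatfield") {
    expected <- matrix(config@flatfieldRate, nr, nc)
  } else if (class != "dark") {
    expected <- expected + config@backgroundRate
    if (config@beamstopRadiusPx > 0) {
      map0 <- buildPixelMap(geom, center = center)
      bsMask <- map0@radiusPx < config@beamstopRadiusPx
      expected[bsMask] <- expected[bsMask] * config@beamstopTransmission
    }
  }
  k <- matrix(rpois(nr * nc, expected), nr, nc)
  adu <- k * cal@gain + cal@pedestal +
    matrix(rnorm(nr * nc, 0, 1), nr, nc) * cal@readNoise
  mask <- layout$gapMask | cal@badPixels
  if (config@maskBeamstop && config@beamstopRadiusPx > 0) {
    mapG <- buildPixelMap(geom)   # nominal beamstop position
    mask <- mask | (mapG@radiusPx < config@beamstopRadiusPx)
  }
  id <- sprintf("evt-%010d", frameIndex)
  list(
    raw = RawFrame(adu, panel = layout$panel, id = id),
    truth = list(class = class, fluence = fluence,
                 diameter = if (is(model, "SphereModel")) model@diameter
                            else 2 * model@circumRadius,
                 nParticles = nParticles, orientation = orientation,
                 center = center, photons = k, mask = mask))
}

#' Simulate a run and write it to a CXI file plus truth table
#'
#' Simulates \code{nFrames} exposures with [simulateShot()], writes the ADU
#' stack in the CXI HDF5 layout (see [writeCxi()]) together with the shared
#' bad-pixel mask, and writes a parallel truth HDF5 file holding per-frame
#' class, fluence, orientation, beam centre and the true photon stack.
#' Bit-reproducible for a fixed seed.
#'
#' @param config a [ShotConfig-class].
#' @param geom a [DetectorGeometry-class].
#' @param model scattering model for hits.
#' @param nFrames number of frames.
#' @param path output CXI file path.
#' @param truthPath output truth HDF5 path; default \code{<path>.truth.h5}.
#' @return Invisibly, a list with \code{path}, \code{truthPath}, the truth
#'   \code{data.frame} (one row per frame) and the calibration truth.
#' @export
simulateRun <- function(config, geom, model, nFrames, path,
                        truthPath = paste0(path, ".truth.h5")) {
  layout <- panelLayout(geom, config@nPanelsRow, config@nPanelsCol,
                        config@panelGapPx)
  cal <- .simCalibration(config, geom, layout)
  nr <- geom@nRows; nc <- geom@nCols
  adu <- array(0, c(nr, nc, nFrames))
  photons <- array(0L, c(nr, nc, nFrames))
  cls <- character(nFrames); flu <- numeric(nFrames)
  quat <- matrix(NA_real_, nFrames, 4L)
  ctr <- matrix(NA_real_, nFrames, 2L)
  npart <- integer(nFrames)
  ids <- character(nFrames)
  mask <- layout$gapMask
  for (i in seq_len(nFrames)) {
    shot <- simulateShot(config, geom, model, cal, layout, frameIndex = i)
    adu[, , i] <- shot$raw@data
    photons[, , i] <- shot$truth$photons
    cls[i] <- shot$truth$class
    flu[i] <- shot$truth$fluence
    quat[i, ] <- shot$truth$orientation
    ctr[i, ] <- shot$truth$center
    npart[i] <- shot$truth$nParticles
    ids[i] <- shot$raw@id
    mask <- shot$truth$mask
  }
  writeCxi(adu, path, geom = geom, ids = ids, mask = mask)
  .writeTruth(truthPath, cls, flu, quat, ctr, npart, photons, ids)
  truth <- data.frame(id = ids, class = cls, fluence = flu,
                      nParticles = npart,
                      centerRow = ctr[, 1L], centerCol = ctr[, 2L])
  invisible(list(path = path, truthPath = truthPath, truth = truth,
                 photons = photons, mask = mask, calibration = cal,
                 panel = layout$panel))
}

.writeTruth <- function(path, cls, flu, quat, ctr, npart, photons, ids) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "truth")
  rhdf5::h5write(cls, path, "truth/class")
  rhdf5::h5write(flu, path, "truth/fluence")
  rhdf5::h5write(quat, path, "truth/orientation")
  rhdf5::h5write(ctr, path, "truth/beam_center")
  rhdf5::h5write(npart, path, "truth/n_particles")
  rhdf5::h5write(photons, path, "truth/photons")
  rhdf5::h5write(ids, path, "truth/ids")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a simulated run's truth table
#'
#' @param path truth HDF5 file written by [simulateRun()].
#' @return list(table = data.frame, orientation = matrix, photons = array).
#' @export
readTruth <- function(path) {
  cls <- as.vector(rhdf5::h5read(path, "truth/class"))
  flu <- as.vector(rhdf5::h5read(path, "truth/fluence"))
  quat <- rhdf5::h5read(path, "truth/orientation")
  ctr <- rhdf5::h5read(path, "truth/beam_center")
  npart <- as.vector(rhdf5::h5read(path, "truth/n_particles"))
  photons <- rhdf5::h5read(path, "truth/photons")
  ids <- as.vector(rhdf5::h5read(path, "truth/ids"))
  rhdf5::h5closeAll()
  list(table = data.frame(id = ids, class = cls, fluence = flu,
                          nParticles = npart,
                          centerRow = ctr[, 1L], centerCol = ctr[, 2L]),
       orientation = quat, photons = photons)
}
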