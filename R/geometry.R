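## Detector geometry and reciprocal-space mapping.
##
## Conventions used throughout the package:
##   * pixel indices are 0-based (row, col); a pixel's centre sits at integer
##     coordinates; the beam centre is real-valued and may lie off the grid
##     (an offset detector);
##   * the detector is a single flat monolithic pixel grid; panel gaps are
##     represented purely through masks;
##   * resolution uses the half-period (speckle) convention
##     d = lambda / (2 sin alpha) with alpha the FULL scattering angle, the
##     convention native to coherent imaging.

#' Detector geometry of a flat pixel-array detector
#'
#' Physical description of a monolithic flat detector: pixel grid size, pixel
#' pitch, sample-to-detector distance, forward-beam intersection point and
#' photon energy.  The X-ray wavelength is derived from the photon energy on
#' construction.
#'
#' @slot nRows,nCols integer pixel counts.
#' @slot pixelSize pixel pitch in micrometres.
#' @slot distance sample-to-detector distance in millimetres.
#' @slot beamCenter length-2 numeric, fractional pixel coordinates
#'   (row, col) of the forward-beam intersection; may lie outside the grid.
#' @slot photonEnergy photon energy in keV.
#' @slot wavelength wavelength in Angstrom, derived as 12.3984 / energy.
#'
#' @seealso [buildPixelMap()], [resolutionToRadius()]
#' @export
setClass("DetectorGeometry",
  slots = c(
    nRows = "integer", nCols = "integer",
    pixelSize = "numeric", distance = "numeric",
    beamCenter = "numeric", photonEnergy = "numeric",
    wavelength = "numeric"
  )
)

setValidity("DetectorGeometry", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "pixel counts must be positive")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive length (um)")
  if (!is.finite(object@distance) || object@distance <= 0)
    msg <- c(msg, "distance must be a positive length (mm)")
  if (length(object@beamCenter) != 2L || any(!is.finite(object@beamCenter)))
    msg <- c(msg, "beamCenter must be two finite (row, col) coordinates")
  if (!is.finite(object@photonEnergy) || object@photonEnergy <= 0)
    msg <- c(msg, "photonEnergy must be positive (keV)")
  if (abs(object@wavelength - .kev_angstrom / object@photonEnergy) > 1e-12)
    msg <- c(msg, "wavelength inconsistent with photon energy")
  if (length(msg)) msg else TRUE
})

#' @param nRows,nCols pixel counts.
#' @param pixelSizeUm pixel pitch (micrometres).
#' @param distanceMm sample-to-detector distance (millimetres).
#' @param beamCenter numeric(2), (row, col) of the beam centre in fractional
#'   0-based pixel coordinates.
#' @param photonEnergyKeV photon energy (keV).
#' @return A \code{DetectorGeometry} object.
#' @examples
#' ## front detector of a hard X-ray SPI experiment
#' geomFront <- DetectorGeometry(1736, 1742, 110, 217.4, c(870, 875), 7)
#' wavelength(geomFront)
#' @rdname DetectorGeometry-class
#' @export
DetectorGeometry <- function(nRows, nCols, pixelSizeUm, distanceMm,
                             beamCenter, photonEnergyKeV) {
  new("DetectorGeometry",
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    pixelSize = as.numeric(pixelSizeUm), distance = as.numeric(distanceMm),
    beamCenter = as.numeric(beamCenter),
    photonEnergy = as.numeric(photonEnergyKeV),
    wavelength = wavelengthFromEnergy(photonEnergyKeV))
}

#' @export
setGeneric("wavelength", function(x) standardGeneric("wavelength"))
#' @describeIn DetectorGeometry-class X-ray wavelength in Angstrom.
#' @export
setMethod("wavelength", "DetectorGeometry", function(x) x@wavelength)

#' @export
setGeneric("beamCenter", function(x) standardGeneric("beamCenter"))
#' @describeIn DetectorGeometry-class beam centre, fractional (row, col).
#' @export
setMethod("beamCenter", "DetectorGeometry", function(x) x@beamCenter)

#' @export
setGeneric("detectorDistance", function(x) standardGeneric("detectorDistance"))
#' @describeIn DetectorGeometry-class sample-to-detector distance (mm).
#' @export
setMethod("detectorDistance", "DetectorGeometry", function(x) x@distance)

#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))
#' @describeIn DetectorGeometry-class pixel pitch (micrometres).
#' @export
setMethod("pixelPitch", "DetectorGeometry", function(x) x@pixelSize)

setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf(
    "DetectorGeometry: %d x %d px, %.1f um pitch, %.1f mm downstream\n",
    object@nRows, object@nCols, object@pixelSize, object@distance))
  cat(sprintf("  beam centre (row, col): (%.2f, %.2f)\n",
              object@beamCenter[1L], object@beamCenter[2L]))
  cat(sprintf("  photon energy %.4g keV  (lambda = %.4f A)\n",
              object@photonEnergy, object@wavelength))
})

#' X-ray wavelength from photon energy
#'
#' Standard keV–Angstrom conversion, \code{lambda = 12.3984 / E}.
#'
#' @param energyKeV photon energy in keV, strictly positive.
#' @return Wavelength in Angstrom.
#' @examples
#' wavelengthFromEnergy(7)  # 1.7712 A
#' @export
wavelengthFromEnergy <- function(energyKeV) {
  if (!is.numeric(energyKeV) || any(!is.finite(energyKeV)) ||
      any(energyKeV <= 0))
    stop("invalid-geometry: photon energy must be positive (keV)")
  .kev_angstrom / energyKeV
}

#' Per-pixel reciprocal-space map
#'
#' Derived per-pixel quantities for a detector geometry: radius from the beam
#' centre (pixels and mm), signed in-plane offsets, full scattering angle
#' alpha, momentum-transfer magnitude \code{q = (4 pi / lambda) sin(alpha/2)},
#' half-period resolution \code{d = lambda / (2 sin alpha)} and pixel solid
#' angle.  A pixel exactly at the beam centre has \code{r = 0}, \code{q = 0}
#' and an undefined (infinite) resolution.
#'
#' @slot radiusPx,radiusMm per-pixel radius from the beam centre.
#' @slot xMm,yMm signed in-plane offsets (col resp. row direction), mm.
#' @slot alpha full scattering angle (rad).
#' @slot q momentum-transfer magnitude (1/Angstrom).
#' @slot resolution half-period resolution (Angstrom); Inf at the centre.
#' @slot solidAngle per-pixel solid angle (sr), \code{(p/L)^2 cos^3 alpha}.
#' @slot valid logical matrix, TRUE where the map is usable.
#' @slot geometry the generating [DetectorGeometry-class].
#' @export
setClass("PixelMap",
  slots = c(
    radiusPx = "matrix", radiusMm = "matrix",
    xMm = "matrix", yMm = "matrix",
    alpha = "matrix", q = "matrix", resolution = "matrix",
    solidAngle = "matrix", valid = "matrix",
    geometry = "DetectorGeometry"
  )
)

setMethod("show", "PixelMap", function(object) {
  g <- object@geometry
  cat(sprintf("PixelMap: %d x %d px, q in [%.4g, %.4g] 1/A\n",
              g@nRows, g@nCols, min(object@q), max(object@q)))
  dmin <- min(object@resolution[object@radiusPx > 0])
  cat(sprintf("  best (edge) resolution %.3g A, half-period convention\n",
              dmin))
})

#' Build the reciprocal-space map of a detector
#'
#' @param geom a [DetectorGeometry-class].
#' @param center optional alternative beam centre (row, col) in fractional
#'   pixels, e.g. a per-shot refined centre; defaults to the geometry's.
#' @return A [PixelMap-class].
#' @examples
#' geom <- DetectorGeometry(64, 64, 110, 2400, c(31.5, 31.5), 7)
#' pm <- buildPixelMap(geom)
#' range(pm@q)
#' @export
buildPixelMap <- function(geom, center = NULL) {
  validObject(geom)
  if (is.null(center)) center <- geom@beamCenter
  stopifnot(length(center) == 2L, all(is.finite(center)))
  pMm <- geom@pixelSize / 1000
  L <- geom@distance
  lam <- geom@wavelength
  rowOff <- (seq_len(geom@nRows) - 1) - center[1L]
  colOff <- (seq_len(geom@nCols) - 1) - center[2L]
  yMm <- matrix(rowOff * pMm, geom@nRows, geom@nCols)
  xMm <- matrix(colOff * pMm, geom@nRows, geom@nCols, byrow = TRUE)
  radiusMm <- sqrt(xMm^2 + yMm^2)
  radiusPx <- radiusMm / pMm
  alpha <- atan(radiusMm / L)
  q <- (4 * pi / lam) * sin(alpha / 2)
  resolution <- ifelse(alpha > 0, lam / (2 * sin(alpha)), Inf)
  solidAngle <- (pMm / L)^2 * cos(alpha)^3
  new("PixelMap",
    radiusPx = radiusPx, radiusMm = radiusMm, xMm = xMm, yMm = yMm,
    alpha = alpha, q = q, resolution = resolution, solidAngle = solidAngle,
    valid = matrix(TRUE, geom@nRows, geom@nCols), geometry = geom)
}

#' Convert resolution to detector radius and back
#'
#' Under the half-period convention \code{d = lambda / (2 sin alpha)}, a
#' resolution shell \code{d} intersects the detector at radius
#' \code{r = L tan(asin(lambda / 2d)) / p}.  The two functions are exact
#' inverses.
#'
#' @param d resolution in Angstrom.
#' @param radiusPx radius from the beam centre in (real-valued) pixels.
#' @param geom a [DetectorGeometry-class].
#' @return \code{resolutionToRadius}: radius in pixels;
#'   \code{radiusToResolution}: resolution in Angstrom.
#' @examples
#' geom <- DetectorGeometry(1736, 1742, 110, 217.4, c(870, 875), 7)
#' resolutionToRadius(6.67, geom)   # ~264.7 px
#' @export
resolutionToRadius <- function(d, geom) {
  validObject(geom)
  s <- geom@wavelength / (2 * d)
  if (any(!is.finite(s)) || any(s <= 0) || any(s > 1))
    stop("resolution-unreachable: require 0 < lambda/(2 d) <= 1")
  geom@distance * tan(asin(s)) / (geom@pixelSize / 1000)
}

#' @rdname resolutionToRadius
#' @export
radiusToResolution <- function(radiusPx, geom) {
  validObject(geom)
  if (any(radiusPx <= 0)) stop("radius must be positive")
  alpha <- atan(radiusPx * geom@pixelSize / 1000 / geom@distance)
  geom@wavelength / (2 * sin(alpha))
}

#' Read detector geometry from a YAML config
#'
#' Keys: \code{n_rows}, \code{n_cols}, \code{pixel_size_um},
#' \code{distance_mm}, \code{beam_center} (two numbers, row then col),
#' \code{photon_energy_kev}.
#'
#' @param path path to a YAML file.
#' @return A [DetectorGeometry-class].
#' @export
readGeometry <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("n_rows", "n_cols", "pixel_size_um", "distance_mm",
            "beam_center", "photon_energy_kev")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("invalid-geometry: missing config keys: ", paste(miss, collapse = ", "))
  DetectorGeometry(cfg$n_rows, cfg$n_cols, cfg$pixel_size_um,
                   cfg$distance_mm, unlist(cfg$beam_center),
                   cfg$photon_energy_kev)
}

#' Select pixels by radius or resolution
#'
#' Logical selection mask (TRUE = use) restricting analysis to pixels within
#' a maximum radius and/or at resolutions no finer than \code{dMin}, the way
#' a surprise or radial analysis is limited to a trusted angular range.
#'
#' @param map a [PixelMap-class].
#' @param rMaxPx maximum radius in pixels, or NULL.
#' @param dMin finest resolution to admit (Angstrom), or NULL.
#' @return Logical matrix, TRUE where the pixel is selected.
#' @export
pixelSelection <- function(map, rMaxPx = NULL, dMin = NULL) {
  sel <- map@valid
  if (!is.null(rMaxPx)) sel <- sel & (map@radiusPx <= rMaxPx)
  if (!is.null(dMin)) sel <- sel & (map@resolution >= dMin)
  sel
}
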