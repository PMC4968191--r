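## Frame family: one detector exposure at successive processing stages.
## Mask convention everywhere in the package: logical matrix, TRUE = bad /
## excluded (matching the on-disk "nonzero = bad" convention of mask files).

#' Raw detector frame (ADU)
#'
#' One uncalibrated exposure: real-valued ADU grid plus a per-pixel panel
#' label (readout panels share a common-mode offset) and a frame identifier.
#'
#' @slot data numeric matrix of ADU values.
#' @slot panel integer matrix of panel labels (contiguous rectangular blocks).
#' @slot id frame identifier / timestamp string.
#' @export
setClass("RawFrame",
  slots = c(data = "matrix", panel = "matrix", id = "character"))

setValidity("RawFrame", function(object) {
  if (!identical(dim(object@data), dim(object@panel)))
    return("panel labels must match the data shape")
  TRUE
})

#' @param data numeric ADU matrix.
#' @param panel integer matrix of panel labels; default one panel.
#' @param id frame identifier.
#' @rdname RawFrame-class
#' @export
RawFrame <- function(data, panel = NULL, id = "frame-0") {
  if (is.null(panel)) panel <- matrix(1L, nrow(data), ncol(data))
  new("RawFrame", data = data, panel = matrix(as.integer(panel), nrow(data)),
      id = as.character(id))
}

#' Calibrated detector frame (corrected ADU)
#'
#' A frame after pedestal subtraction and, optionally, common-mode and gain
#' corrections: still real-valued ADU, with the bad-pixel mask attached and
#' a record of panels whose common-mode could not be estimated.
#'
#' @slot data numeric matrix of corrected ADU.
#' @slot panel integer matrix of panel labels.
#' @slot mask logical matrix, TRUE = bad pixel.
#' @slot id frame identifier.
#' @slot flaggedPanels integer vector of panels left uncorrected.
#' @export
setClass("CalibratedFrame",
  slots = c(data = "matrix", panel = "matrix", mask = "matrix",
            id = "character", flaggedPanels = "integer"))

#' Photon-count frame
#'
#' Non-negative integer photon counts with the bad-pixel mask.
#'
#' @slot counts integer-valued matrix, >= 0 on unmasked pixels.
#' @slot mask logical matrix, TRUE = bad pixel.
#' @slot id frame identifier.
#' @export
setClass("PhotonFrame",
  slots = c(counts = "matrix", mask = "matrix", id = "character"))

setValidity("PhotonFrame", function(object) {
  if (!identical(dim(object@counts), dim(object@mask)))
    return("mask must match the counts shape")
  ok <- !object@mask
  k <- object@counts[ok]
  if (any(k < 0) || any(k != round(k)))
    return("unmasked photon counts must be non-negative integers")
  TRUE
})

#' @param counts non-negative integer matrix.
#' @param mask logical matrix, TRUE = bad; default none.
#' @param id frame identifier.
#' @rdname PhotonFrame-class
#' @export
PhotonFrame <- function(counts, mask = NULL, id = "frame-0") {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  new("PhotonFrame", counts = counts, mask = mask, id = as.character(id))
}

#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))
#' @describeIn RawFrame-class the ADU grid.
#' @export
setMethod("frameData", "RawFrame", function(x) x@data)
#' @describeIn CalibratedFrame-class the corrected ADU grid.
#' @export
setMethod("frameData", "CalibratedFrame", function(x) x@data)
#' @describeIn PhotonFrame-class the photon-count grid.
#' @export
setMethod("frameData", "PhotonFrame", function(x) x@counts)

#' @export
setGeneric("frameMask", function(x) standardGeneric("frameMask"))
#' @describeIn CalibratedFrame-class the bad-pixel mask.
#' @export
setMethod("frameMask", "CalibratedFrame", function(x) x@mask)
#' @describeIn PhotonFrame-class the bad-pixel mask.
#' @export
setMethod("frameMask", "PhotonFrame", function(x) x@mask)

setMethod("show", "RawFrame", function(object) {
  cat(sprintf("RawFrame %s: %d x %d px, ADU range [%.1f, %.1f]\n",
              object@id, nrow(object@data), ncol(object@data),
              min(object@data), max(object@data)))
})
setMethod("show", "PhotonFrame", function(object) {
  ok <- !object@mask
  cat(sprintf(
    "PhotonFrame %s: %d x %d px, %d photons on %d unmasked px\n",
    object@id, nrow(object@counts), ncol(object@counts),
    sum(object@counts[ok]), sum(ok)))
})

#' Per-pixel calibration constants
#'
#' Pedestal (dark offset), read noise, gain (ADU per photon) and bad-pixel
#' mask for one detector.
#'
#' @slot pedestal numeric matrix, ADU.
#' @slot readNoise numeric matrix, ADU standard deviation, >= 0.
#' @slot gain numeric matrix, ADU/photon, > 0 on unmasked pixels.
#' @slot badPixels logical matrix, TRUE = bad.
#' @export
setClass("CalibrationSet",
  slots = c(pedestal = "matrix", readNoise = "matrix",
            gain = "matrix", badPixels = "matrix"))

setValidity("CalibrationSet", function(object) {
  d <- dim(object@pedestal)
  if (!identical(dim(object@readNoise), d) ||
      !identical(dim(object@gain), d) ||
      !identical(dim(object@badPixels), d))
    return("all calibration grids must share one shape")
  ok <- !object@badPixels
  if (any(!is.finite(object@pedestal[ok])))
    return("pedestal must be finite on unmasked pixels")
  if (any(object@gain[ok] <= 0, na.rm = FALSE) ||
      any(!is.finite(object@gain[ok])))
    return("gain must be positive and finite on unmasked pixels")
  if (any(object@readNoise[ok] < 0))
    return("read noise must be non-negative")
  TRUE
})

#' @param pedestal,readNoise,gain numeric matrices (scalars are recycled to
#'   the pedestal's shape).
#' @param badPixels logical matrix, TRUE = bad; default none.
#' @rdname CalibrationSet-class
#' @export
CalibrationSet <- function(pedestal, readNoise = 0, gain = 1,
                           badPixels = NULL) {
  d <- dim(pedestal)
  full <- function(x) if (is.matrix(x)) x else matrix(x, d[1L], d[2L])
  if (is.null(badPixels)) badPixels <- matrix(FALSE, d[1L], d[2L])
  new("CalibrationSet", pedestal = pedestal, readNoise = full(readNoise),
      gain = full(gain), badPixels = badPixels)
}

#' @export
setGeneric("meanGain", function(x) standardGeneric("meanGain"))
#' @describeIn CalibrationSet-class mean gain over unmasked pixels
#'   (the detector-average ADU per photon).
#' @export
setMethod("meanGain", "CalibrationSet",
          function(x) mean(x@gain[!x@badPixels]))

setMethod("show", "CalibrationSet", function(object) {
  ok <- !object@badPixels
  cat(sprintf(
    "CalibrationSet: %d x %d px, %d bad; pedestal %.2f ADU, gain %.2f ADU/ph\n",
    nrow(object@pedestal), ncol(object@pedestal), sum(!ok),
    mean(object@pedestal[ok]), mean(object@gain[ok])))
})
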