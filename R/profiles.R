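## Hit finding, radial averaging, and the hit-vs-blank signal-resolution
## analysis.

#' Radial profile of a frame
#'
#' Mean photons per pixel in contiguous half-open annuli \code{[lo, hi)} of
#' fixed width about the beam centre; annulus membership by pixel-centre
#' radius.  Empty bins are NA and flagged via \code{npix = 0}.
#'
#' @slot rLo,rHi bin edges (pixels).
#' @slot mean mean photons per pixel per bin (NA where empty).
#' @slot npix unmasked pixels per bin.
#' @slot counts summed photons per bin.
#' @slot q,resolution momentum transfer (1/A) and half-period resolution (A)
#'   at bin centres.
#' @slot binWidth bin width (pixels).
#' @export
setClass("RadialProfile",
  slots = c(rLo = "numeric", rHi = "numeric", mean = "numeric",
            npix = "integer", counts = "numeric", q = "numeric",
            resolution = "numeric", binWidth = "numeric"))

setValidity("RadialProfile", function(object) {
  n <- length(object@rLo)
  if (length(object@rHi) != n || length(object@mean) != n ||
      length(object@npix) != n)
    return("profile vectors must share one length")
  if (any(object@rHi <= object@rLo)) return("bins must have positive width")
  if (n > 1 && any(abs(object@rLo[-1] - object@rHi[-n]) > 1e-9))
    return("bins must be contiguous and non-overlapping")
  TRUE
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf(
    "RadialProfile: %d bins of %.3g px, %d empty; peak mean %.3g ph/px\n",
    length(object@rLo), object@binWidth, sum(object@npix == 0L),
    max(object@mean, na.rm = TRUE)))
})

#' Compute the radial average of a frame
#'
#' @param frame a [PhotonFrame-class], count matrix, or any per-pixel image
#'   (e.g. a frame sum or a background average).
#' @param map a [PixelMap-class] about the desired centre.
#' @param mask optional extra logical mask (TRUE = exclude), combined with a
#'   PhotonFrame's own mask.
#' @param binWidth bin width in pixels, > 0.
#' @return A [RadialProfile-class].
#' @export
radialAverage <- function(frame, map, mask = NULL, binWidth = 1) {
  if (binWidth <= 0) stop("binWidth must be positive")
  x <- if (is(frame, "PhotonFrame")) frame@counts else frame
  fmask <- if (is(frame, "PhotonFrame")) frame@mask else NULL
  ok <- map@valid
  if (!is.null(fmask)) ok <- ok & !fmask
  if (!is.null(mask)) ok <- ok & !mask
  if (!identical(dim(x), dim(map@radiusPx)))
    stop("incompatible-inputs: frame and map shapes differ")
  binIdx <- .radialBinIndex(map, binWidth)
  nBins <- max(binIdx[ok])
  counts <- .binCounts(x, binIdx, ok, nBins)
  npix <- integer(nBins)
  tb <- table(binIdx[ok])
  npix[as.integer(names(tb))] <- as.integer(tb)
  meanv <- ifelse(npix > 0L, counts / npix, NA_real_)
  rLo <- (seq_len(nBins) - 1) * binWidth
  rHi <- seq_len(nBins) * binWidth
  rMid <- (rLo + rHi) / 2
  geom <- map@geometry
  qv <- numeric(nBins); dv <- numeric(nBins)
  posMid <- rMid > 0
  alpha <- atan(rMid[posMid] * geom@pixelSize / 1000 / geom@distance)
  qv[posMid] <- (4 * pi / geom@wavelength) * sin(alpha / 2)
  dv[posMid] <- geom@wavelength / (2 * sin(alpha))
  dv[!posMid] <- Inf
  new("RadialProfile", rLo = rLo, rHi = rHi, mean = meanv, npix = npix,
      counts = counts, q = qv, resolution = dv, binWidth = binWidth)
}

#' Find hits by lit-pixel counting
#'
#' A frame is a hit iff at least \code{minLitPixels} unmasked pixels carry
#' \code{>= litThreshold} photons — the standard lit-pixel hit finder for
#' photonized small-angle detector data.
#'
#' @param frames stack of photonized frames (3-D array, list of matrices or
#'   [PhotonFrame-class] objects).
#' @param litThreshold photons per pixel at or above which a pixel is lit.
#' @param minLitPixels lit pixels at or above which a frame is a hit.
#' @param mask logical matrix (TRUE = exclude) shared by the stack.
#' @return Logical vector, one entry per frame.
#' @export
findHits <- function(frames, litThreshold = 1, minLitPixels = 50L,
                     mask = NULL) {
  arr <- .stackArray(frames)
  if (is.list(frames) && length(frames) && is(frames[[1L]], "PhotonFrame") &&
      is.null(mask))
    mask <- frames[[1L]]@mask
  if (is.null(mask)) mask <- matrix(FALSE, dim(arr)[1L], dim(arr)[2L])
  okv <- as.vector(!mask)
  apply(arr, 3L, function(f) sum(f[okv] >= litThreshold) >= minLitPixels)
}

#' Lit-pixel budget for hit finding under a known background
#'
#' The number of lit pixels on a pure-background frame is approximately
#' Poisson with mean \code{nPixels P(k >= litThreshold | backgroundRate)}.
#' This returns a \code{minLitPixels} one count above its upper
#' \code{1 - alpha} quantile, so blanks are called hits with probability
#' below \code{alpha} while genuine particle scattering (thousands of lit
#' pixels) passes easily.
#'
#' @param nPixels unmasked pixels per frame.
#' @param backgroundRate background photons per pixel per frame.
#' @param litThreshold photons at or above which a pixel counts as lit.
#' @param alpha acceptable blank false-positive probability.
#' @return Suggested \code{minLitPixels} (integer).
#' @export
suggestMinLitPixels <- function(nPixels, backgroundRate, litThreshold = 2,
                                alpha = 1e-6) {
  p <- ppois(litThreshold - 1, backgroundRate, lower.tail = FALSE)
  as.integer(qpois(1 - alpha, nPixels * p)) + 1L
}

#' Signal-above-background resolution limit
#'
#' Compares a hit radial profile against a blank (background) profile on
#' identical bins and returns the outer edge of the last bin belonging to a
#' run of at least \code{runLength} consecutive bins in which the hit signal
#' exceeds \code{excessFactor} times the blank signal, converted to a
#' resolution through the detector geometry.
#'
#' @param hitProfile,blankProfile [RadialProfile-class] objects on the same
#'   bins.
#' @param excessFactor multiplicative excess required, default 1.2.
#' @param runLength consecutive elevated bins required, default 3.
#' @param geom a [DetectorGeometry-class] for the resolution conversion;
#'   NULL returns only the radius.
#' @return list(found, radiusPx, resolutionA); \code{found = FALSE} with NA
#'   values when no qualifying run exists.
#' @export
signalResolutionLimit <- function(hitProfile, blankProfile,
                                  excessFactor = 1.2, runLength = 3L,
                                  geom = NULL) {
  if (length(hitProfile@rLo) != length(blankProfile@rLo) ||
      any(abs(hitProfile@rLo - blankProfile@rLo) > 1e-9) ||
      hitProfile@binWidth != blankProfile@binWidth)
    stop("incompatible-profiles: profiles must share identical bins")
  h <- hitProfile@mean; b <- blankProfile@mean
  exceed <- !is.na(h) & !is.na(b) & (h > excessFactor * b)
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  good <- which(r$values & r$lengths >= runLength)
  if (!length(good))
    return(list(found = FALSE, radiusPx = NA_real_, resolutionA = NA_real_))
  lastBin <- max(ends[good])
  radius <- hitProfile@rHi[lastBin]
  resol <- if (is.null(geom)) NA_real_ else radiusToResolution(radius, geom)
  list(found = TRUE, radiusPx = radius, resolutionA = resol)
}
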