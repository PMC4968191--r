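## Calibration: raw ADU -> photon counts.
## Pipeline: pedestal subtraction -> per-panel common-mode correction ->
## per-pixel gain flattening -> ceil-rule photonization with the detector
## average gain.  Gain itself is estimated from flat-field single-photon
## histograms by a two-Gaussian fit.

#' Estimate pedestal and read noise from dark frames
#'
#' Per-pixel mean (pedestal) and sample standard deviation (read noise) over
#' a stack of dark exposures.
#'
#' @param darkFrames a stack of dark frames: 3-D array \code{[row, col, n]},
#'   list of matrices, or list of [RawFrame-class] objects; at least two.
#' @return A list with matrices \code{pedestal} and \code{readNoise}.
#' @examples
#' darks <- array(rnorm(16 * 16 * 50, mean = 20, sd = 3), c(16, 16, 50))
#' ped <- estimatePedestal(darks)
#' @export
estimatePedestal <- function(darkFrames) {
  arr <- .stackArray(darkFrames)
  n <- dim(arr)[3L]
  if (n < 2L)
    stop("insufficient-darks: need at least 2 dark frames, got ", n)
  pedestal <- rowMeans(arr, dims = 2L)
  dev2 <- rowSums((arr - as.vector(pedestal))^2, dims = 2L)
  readNoise <- sqrt(dev2 / (n - 1))
  list(pedestal = pedestal, readNoise = readNoise)
}

#' Subtract the pedestal from a raw frame
#'
#' @param frame a [RawFrame-class].
#' @param cal a [CalibrationSet-class].
#' @return A [CalibratedFrame-class] carrying the bad-pixel mask.
#' @export
subtractPedestal <- function(frame, cal) {
  stopifnot(is(frame, "RawFrame"), is(cal, "CalibrationSet"))
  if (!identical(dim(frame@data), dim(cal@pedestal)))
    stop("frame and calibration shapes differ")
  new("CalibratedFrame", data = frame@data - cal@pedestal,
      panel = frame@panel, mask = cal@badPixels, id = frame@id,
      flaggedPanels = integer())
}

#' Per-panel common-mode correction
#'
#' Shot-to-shot correlated readout offsets are estimated per panel as the
#' median of unmasked pixels below a signal cut (so genuine photon signal
#' does not bias the estimate) and subtracted.  Panels with no sub-threshold
#' pixels are left unchanged and recorded in \code{flaggedPanels}.
#'
#' @param frame a pedestal-subtracted [CalibratedFrame-class].
#' @param cal a [CalibrationSet-class] (for the bad-pixel mask); optional.
#' @param signalCut ADU threshold below which a pixel is treated as
#'   signal-free; default half the mean gain (half a photon).
#' @return A corrected [CalibratedFrame-class].
#' @export
commonModeCorrect <- function(frame, cal = NULL, signalCut = NULL) {
  stopifnot(is(frame, "CalibratedFrame"))
  mask <- frame@mask
  if (!is.null(cal)) mask <- mask | cal@badPixels
  if (is.null(signalCut)) {
    if (is.null(cal))
      stop("signalCut must be given when no CalibrationSet supplies a gain")
    signalCut <- 0.5 * meanGain(cal)
  }
  out <- frame@data
  flagged <- integer()
  for (p in sort(unique(as.vector(frame@panel)))) {
    inPanel <- frame@panel == p
    sub <- inPanel & !mask & frame@data < signalCut
    if (!any(sub)) {
      flagged <- c(flagged, p)
      next
    }
    out[inPanel] <- out[inPanel] - median(frame@data[sub])
  }
  new("CalibratedFrame", data = out, panel = frame@panel, mask = mask,
      id = frame@id, flaggedPanels = flagged)
}

#' Flatten per-pixel gain variations
#'
#' Rescales each pixel by \code{meanGain(cal) / gain_i} so the whole frame
#' shares the detector-average ADU-per-photon scale expected by
#' [photonize()].
#'
#' @param frame a [CalibratedFrame-class].
#' @param cal a [CalibrationSet-class].
#' @return A gain-corrected [CalibratedFrame-class].
#' @export
gainCorrect <- function(frame, cal) {
  stopifnot(is(frame, "CalibratedFrame"), is(cal, "CalibrationSet"))
  gbar <- meanGain(cal)
  scale <- gbar / cal@gain
  scale[cal@badPixels] <- 1
  new("CalibratedFrame", data = frame@data * scale, panel = frame@panel,
      mask = frame@mask | cal@badPixels, id = frame@id,
      flaggedPanels = frame@flaggedPanels)
}

#' Photonize a corrected ADU frame (ceil rule)
#'
#' Converts dark-, common-mode- and gain-corrected ADU values \code{A_i} to
#' photon counts with \code{k_i = ceil((A_i - 0.5 gamma) / gamma)}, i.e. the
#' threshold between \code{n-1} and \code{n} photons sits at
#' \code{(n - 0.5) gamma}.  Negative results (large downward noise
#' fluctuations) are clamped to zero so counts remain valid Poisson data.
#'
#' @param frame a [CalibratedFrame-class] or a numeric matrix of corrected
#'   ADU.
#' @param gamma detector-average gain, ADU per photon, > 0.
#' @param mask optional logical matrix (TRUE = bad) when \code{frame} is a
#'   bare matrix.
#' @param id frame identifier when \code{frame} is a bare matrix.
#' @return A [PhotonFrame-class]; masked pixels carry count 0 and stay
#'   masked.
#' @examples
#' photonize(matrix(c(16.4, 17, 49.5, 50), 2), gamma = 33)
#' @export
photonize <- function(frame, gamma, mask = NULL, id = "frame-0") {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("invalid-gain: gamma must be a single positive ADU/photon value")
  if (is(frame, "CalibratedFrame")) {
    A <- frame@data; mask <- frame@mask; id <- frame@id
  } else {
    A <- frame
    if (is.null(mask)) mask <- matrix(FALSE, nrow(A), ncol(A))
  }
  k <- ceiling((A - 0.5 * gamma) / gamma)
  k <- pmax(k, 0)
  k[mask] <- 0
  storage.mode(k) <- "integer"
  new("PhotonFrame", counts = k, mask = mask, id = id)
}

#' Full calibration chain for one frame
#'
#' Pedestal subtraction, optional common-mode correction, gain flattening
#' and photonization in one call.
#'
#' @param frame a [RawFrame-class].
#' @param cal a [CalibrationSet-class].
#' @param commonMode apply the per-panel common-mode correction?
#' @param signalCut common-mode signal cut; default half the mean gain.
#' @return A [PhotonFrame-class].
#' @export
calibrateFrame <- function(frame, cal, commonMode = TRUE, signalCut = NULL) {
  f <- subtractPedestal(frame, cal)
  if (commonMode) f <- commonModeCorrect(f, cal, signalCut)
  f <- gainCorrect(f, cal)
  photonize(f, meanGain(cal))
}

#' Estimate per-pixel gain from flat-field frames
#'
#' At low occupancy a pedestal-subtracted flat-field pixel histogram is
#' bimodal: a noise peak near 0 ADU and a single-photon peak near the gain.
#' For every pixel a two-Gaussian model is least-squares fitted to the
#' histogram (1-ADU bins over \code{[-5 sigma, 2.5 gamma0]}) and the gain is
#' returned as the separation of the fitted means.  Fits that fail, or whose
#' peak separation is below \code{3 sigma}, yield \code{NA} (masked).
#'
#' @param flatFrames stack of pedestal-subtracted flat-field frames (3-D
#'   array or list); occupancy should be well below ~0.5 photons/pixel/frame.
#' @param cal a [CalibrationSet-class] providing per-pixel read noise and
#'   the bad-pixel mask.
#' @param gamma0 initial gain guess (ADU/photon); located automatically from
#'   the aggregate histogram when NULL.
#' @param minFrames minimum frames required per pixel.
#' @param strict error (\code{insufficient-statistics}) if no pixel could be
#'   fitted?
#' @return Numeric matrix of per-pixel gains, \code{NA} where the fit failed.
#' @export
estimateGain <- function(flatFrames, cal, gamma0 = NULL, minFrames = 100L,
                         strict = FALSE) {
  arr <- .stackArray(flatFrames)
  d <- dim(arr)
  if (d[3L] < minFrames)
    stop("insufficient-statistics: need >= ", minFrames,
         " flat-field frames, got ", d[3L])
  sigbar <- mean(cal@readNoise[!cal@badPixels])
  if (is.null(gamma0)) {
    ## aggregate histogram; photon peak = mode beyond 3 sigma
    v <- as.vector(arr)
    v <- v[v > 3 * sigbar]
    if (!length(v)) gamma0 <- NA_real_
    else {
      h <- tabulate(pmax(1L, as.integer(round(v))), nbins = 1000L)
      gamma0 <- if (max(h) >= 10) which.max(h) else NA_real_
    }
  }
  gain <- matrix(NA_real_, d[1L], d[2L])
  if (is.na(gamma0)) {
    if (strict) stop("insufficient-statistics: no single-photon peak found")
    return(gain)
  }
  lo <- -5 * sigbar
  hi <- 2.5 * gamma0
  breaks <- seq(floor(lo), ceiling(hi), by = 1)
  mids <- head(breaks, -1L) + 0.5
  twoGauss <- function(par, m)
    par[1L] * exp(-(m - par[2L])^2 / (2 * par[3L]^2)) +
    par[4L] * exp(-(m - par[5L])^2 / (2 * par[6L]^2))
  ## peak means are kept inside physically meaningful windows so the
  ## least-squares fit cannot chase the (rare) two-photon shoulder
  lower <- c(0, -3 * sigbar - 1, 0.3, 0, 0.5 * gamma0, 0.3)
  upper <- c(Inf, 3 * sigbar + 1, 3 * sigbar + 2, Inf, 1.5 * gamma0,
             3 * sigbar + 2)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    if (cal@badPixels[i, j]) next
    v <- arr[i, j, ]
    v <- v[v >= lo & v <= hi]
    if (length(v) < minFrames) next
    isPhot <- v > 0.5 * gamma0 & v <= 1.5 * gamma0
    if (sum(isPhot) < 10L) next
    h <- hist(v, breaks = breaks, plot = FALSE)$counts
    s0 <- min(max(cal@readNoise[i, j], 1), 3 * sigbar + 1)
    start <- c(max(h[abs(mids) < 3 * s0], 1), mean(v[v <= 0.5 * gamma0]), s0,
               max(h[abs(mids - gamma0) < 3 * s0], 1), mean(v[isPhot]), s0)
    start <- pmin(pmax(start, lower + 1e-6), upper)
    start[!is.finite(start)] <- c(1, 0, s0, 1, gamma0, s0)[!is.finite(start)]
    fit <- tryCatch(
      suppressWarnings(optim(start, function(par)
        sum((h - twoGauss(par, mids))^2),
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = 500L))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sep <- fit$par[5L] - fit$par[2L]
    if (!is.finite(sep) || sep < 3 * fit$par[3L]) next
    gain[i, j] <- sep
  }
  if (strict && all(is.na(gain)))
    stop("insufficient-statistics: gain fit failed on every pixel")
  gain
}

#' Average background from non-hit, non-dark frames
#'
#' Pixel-wise mean over frames labelled neither \code{"hit"} nor
#' \code{"dark"} (clusters count as hits).
#'
#' @param frames a stack (3-D array or list of frames).
#' @param labels character vector of per-frame class labels.
#' @return Numeric matrix, the mean background image.
#' @export
averageBackground <- function(frames, labels) {
  arr <- .stackArray(frames)
  if (length(labels) != dim(arr)[3L])
    stop("one label per frame required")
  keep <- !(labels %in% c("hit", "dark", "cluster"))
  if (!any(keep))
    stop("no-background-frames: every frame is a hit or a dark")
  rowMeans(arr[, , keep, drop = FALSE], dims = 2L)
}
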