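## Poisson surprise: model-validation statistic for photon-count frames.
##
## Given expected photons n_i and observed counts k_i, the surprise is the
## negative Poisson log-likelihood S = -sum_i log P(n_i, k_i) (nats).  Its
## mean <S> = sum_i H(n_i) (H the Poisson entropy) and standard deviation
## sigma_S are data-independent, so z = (S - <S>) / sigma_S measures the
## consistency of the data with the model: |z| >> 1 means the frame is
## "surprising" under the model.
##
## Numerical recipe: per-pixel moments of log P under Poisson(n) by truncated
## summation over k = 0..K with K = ceil(n + 12 sqrt(n) + 30), whose omitted
## upper-tail mass is far below 1e-12.

#' Poisson log-probability mass (nats)
#'
#' \code{log P(k; n) = k log n - n - log k!}, with the zero-rate conventions
#' \code{log P(0; 0) = 0} and \code{log P(k>0; 0) = -Inf}.  Computed via
#' log-gamma, stable for large counts.
#'
#' @param n expected counts, >= 0 (vectorized).
#' @param k observed counts, non-negative integers (vectorized).
#' @return Log-probabilities in nats.
#' @examples
#' poissonLogPmf(1, 0:1)    # both -1
#' poissonLogPmf(2, 2)      # log(2) - 2
#' @export
poissonLogPmf <- function(n, k) {
  if (any(!is.finite(k)) || any(k < 0) || any(k != round(k)))
    stop("invalid-count: observed counts must be non-negative integers")
  if (any(n < 0)) stop("expected counts must be non-negative")
  dpois(k, lambda = n, log = TRUE)
}

## Truncated first and second moments of -log P(k; n) under Poisson(n).
## Returns list(mean = E[-log P], second = E[(log P)^2]), vectorized over n.
.poissonNllMoments <- function(n) {
  n <- as.vector(n)
  if (!length(n)) return(list(mean = numeric(), second = numeric()))
  Kmax <- max(ceiling(n + 12 * sqrt(n) + 30))
  ## multiplicative recurrence: p_{k+1} = p_k n/(k+1),
  ## log p_{k+1} = log p_k + log n - log(k+1); avoids a dpois call per k
  logn <- suppressWarnings(log(n))      # -Inf at n = 0, handled via p = 0
  p <- exp(-n)
  lp <- -n
  m1 <- numeric(length(n))
  m2 <- numeric(length(n))
  for (k in 0:Kmax) {
    zero <- p == 0
    contrib <- p * lp
    contrib[zero] <- 0
    contrib2 <- contrib * lp
    contrib2[zero] <- 0
    m1 <- m1 - contrib
    m2 <- m2 + contrib2
    lp <- lp + logn - log(k + 1)
    p <- p * n / (k + 1)
  }
  list(mean = m1, second = m2)
}

#' Expected surprise of a model
#'
#' \code{<S> = sum_i H(n_i)} with \code{H} the Shannon entropy (nats) of a
#' Poisson distribution, by truncated summation.  Independent of any
#' observed data; pixels with \code{n_i = 0} contribute zero.
#'
#' @param modelN matrix (or vector) of expected photons per pixel.
#' @param mask optional logical matrix, TRUE = exclude.
#' @return \code{<S>} in nats.
#' @export
expectedSurprise <- function(modelN, mask = NULL) {
  n <- if (is.null(mask)) as.vector(modelN) else as.vector(modelN)[!mask]
  sum(.poissonNllMoments(n)$mean)
}

#' Standard deviation of the surprise
#'
#' \code{sigma_S = sqrt(sum_i Var[log P(n_i, k)])} with per-pixel moments by
#' the same truncated summation as [expectedSurprise()].
#'
#' @inheritParams expectedSurprise
#' @return \code{sigma_S} in nats.
#' @export
surpriseStd <- function(modelN, mask = NULL) {
  n <- if (is.null(mask)) as.vector(modelN) else as.vector(modelN)[!mask]
  mom <- .poissonNllMoments(n)
  sqrt(sum(pmax(mom$second - mom$mean^2, 0)))
}

#' Surprise of an observed frame under a model
#'
#' \code{S = -sum_i log P(n_i, k_i)} over unmasked pixels.  If any unmasked
#' pixel has \code{n_i = 0} but \code{k_i > 0} the surprise is \code{+Inf}
#' and the result carries attribute \code{infinite = TRUE}.
#'
#' @param frame a [PhotonFrame-class] or an integer count matrix.
#' @param modelN matrix of expected photons, same shape.
#' @param mask optional extra logical mask (TRUE = exclude), combined with
#'   the frame's own mask.
#' @return \code{S} (nats), with attribute \code{infinite}.
#' @export
surpriseScore <- function(frame, modelN, mask = NULL) {
  k <- if (is(frame, "PhotonFrame")) frame@counts else frame
  fmask <- if (is(frame, "PhotonFrame")) frame@mask else
    matrix(FALSE, nrow(k), ncol(k))
  if (!identical(dim(k), dim(modelN)))
    stop("incompatible-inputs: frame and model shapes differ")
  if (!is.null(mask)) fmask <- fmask | mask
  ok <- !fmask
  kk <- k[ok]; nn <- modelN[ok]
  inf <- any(nn == 0 & kk > 0)
  S <- if (inf) Inf else -sum(poissonLogPmf(nn, kk))
  structure(S, infinite = inf)
}

#' Surprise analysis result
#'
#' @slot S surprise (nats).
#' @slot expectedS analytic mean of S under the model.
#' @slot sigmaS analytic standard deviation of S.
#' @slot z z-score \code{(S - <S>) / sigma_S}.
#' @slot fluence best/assumed fluence (NA when not searched).
#' @slot orientation best/assumed orientation quaternion (NA when n/a).
#' @slot nPixels unmasked pixels used.
#' @slot infinite TRUE when a zero-rate pixel observed a photon.
#' @export
setClass("SurpriseResult",
  slots = c(S = "numeric", expectedS = "numeric", sigmaS = "numeric",
            z = "numeric", fluence = "numeric", orientation = "numeric",
            nPixels = "integer", infinite = "logical"))

setMethod("show", "SurpriseResult", function(object) {
  cat(sprintf(
    "SurpriseResult: S = %.2f, <S> = %.2f, sigma_S = %.3f, z = %.3f (N = %d)%s\n",
    object@S, object@expectedS, object@sigmaS, object@z, object@nPixels,
    if (object@infinite) " [infinite]" else ""))
  if (!is.na(object@fluence))
    cat(sprintf("  best fluence %.4g ph/um^2\n", object@fluence))
})

#' z-score of a frame against a model
#'
#' \code{z = (S - <S>) / sigma_S}.  A degenerate model (\code{sigma_S = 0})
#' signals an error; an infinite surprise yields \code{z = +Inf} with the
#' infinite flag set.
#'
#' @inheritParams surpriseScore
#' @param fluence,orientation recorded in the result for bookkeeping.
#' @return A [SurpriseResult-class].
#' @export
zScore <- function(frame, modelN, mask = NULL, fluence = NA_real_,
                   orientation = rep(NA_real_, 4L)) {
  fmask <- if (is(frame, "PhotonFrame")) frame@mask else NULL
  useMask <- mask
  if (!is.null(fmask)) useMask <- if (is.null(mask)) fmask else fmask | mask
  S <- surpriseScore(frame, modelN, mask)
  ES <- expectedSurprise(modelN, useMask)
  sigS <- surpriseStd(modelN, useMask)
  if (sigS == 0 && is.finite(S))
    stop("degenerate-model: sigma_S is zero")
  nPix <- if (is.null(useMask)) length(modelN) else sum(!useMask)
  z <- if (is.infinite(S)) Inf else (as.numeric(S) - ES) / sigS
  new("SurpriseResult", S = as.numeric(S), expectedS = ES, sigmaS = sigS,
      z = z, fluence = fluence, orientation = as.numeric(orientation),
      nPixels = as.integer(nPix), infinite = isTRUE(attr(S, "infinite")))
}

#' Minimize the surprise over a fluence and orientation grid
#'
#' Evaluates \code{S} on the Cartesian grid of candidate fluences and
#' candidate model patterns (one per orientation; a single pattern for an
#' orientation-free sphere model), returns the minimizing pair and the
#' z-score computed at the selected model.  Because the expected pattern is
#' linear in fluence, \code{S(Phi) = Phi T - K log Phi - D + C} with
#' frame-level sufficient statistics \code{T = sum n0_i},
#' \code{D = sum k_i log n0_i}, \code{K = sum k_i}, so the scan is exact and
#' fast.  Ties are broken by the first (fluence-major within orientation)
#' grid point.
#'
#' @param frame a [PhotonFrame-class] or count matrix.
#' @param models a single expected-photon matrix at unit fluence, or a list
#'   of such matrices (one per candidate orientation).
#' @param fluences numeric vector of candidate fluence scale factors.
#' @param mask optional extra mask (TRUE = exclude).
#' @param orientations optional matrix (one row per model) of quaternions,
#'   echoed into the result.
#' @param floor fluence-independent uniform background rate (photons/pixel)
#'   added to every candidate pattern after fluence scaling,
#'   \code{n(Phi) = Phi n0 + floor}; avoids infinite surprise at exact model
#'   zeros.  Default 0.
#' @return A [SurpriseResult-class] with \code{fluence} and
#'   \code{orientation} filled in.
#' @export
minimizeSurprise <- function(frame, models, fluences, mask = NULL,
                             orientations = NULL, floor = 0) {
  if (is.matrix(models)) models <- list(models)
  if (!length(models) || !length(fluences))
    stop("invalid-search: fluence and orientation grids must be non-empty")
  k <- if (is(frame, "PhotonFrame")) frame@counts else frame
  fmask <- if (is(frame, "PhotonFrame")) frame@mask else
    matrix(FALSE, nrow(k), ncol(k))
  if (!is.null(mask)) fmask <- fmask | mask
  ok <- !fmask
  kk <- k[ok]
  Ksum <- sum(kk)
  Cterm <- sum(lgamma(kk + 1))
  bestS <- Inf; bestM <- 1L; bestF <- 1L
  for (m in seq_along(models)) {
    n0 <- models[[m]][ok]
    if (floor == 0) {
      ## the pattern is linear in fluence, so S(Phi) separates into
      ## sufficient statistics and the whole fluence grid is one expression
      Tt <- sum(n0)
      pos <- n0 > 0
      D <- if (any(kk[!pos] > 0)) -Inf else sum(kk[pos] * log(n0[pos]))
      S <- fluences * Tt - log(fluences) * Ksum - D + Cterm
    } else {
      S <- vapply(fluences, function(f) {
        nn <- f * n0 + floor
        if (any(nn == 0 & kk > 0)) return(Inf)
        pos <- nn > 0
        sum(nn) - sum(kk[pos] * log(nn[pos])) + Cterm
      }, numeric(1))
    }
    iBest <- which.min(S)
    if (length(iBest) && S[iBest] < bestS) {
      bestS <- S[iBest]; bestM <- m; bestF <- iBest
    }
  }
  orient <- if (is.null(orientations)) rep(NA_real_, 4L)
            else as.numeric(orientations[bestM, ])
  res <- zScore(frame, fluences[bestF] * models[[bestM]] + floor,
                mask = mask, fluence = fluences[bestF], orientation = orient)
  attr(res, "modelIndex") <- bestM
  res
}
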