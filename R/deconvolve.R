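#' @include AllClasses.R
NULL

#' Evaluate a sum of Gaussian components
#'
#' Computes \eqn{g(x) = \sum_i a_i \exp(-(x - c_i)^2 / (2 \sigma_i^2))}
#' elementwise. Amplitudes are apex heights, so the model is linear in them.
#'
#' @param x Numeric wavenumber vector (cm-1).
#' @param comps \code{data.frame} with columns \code{center},
#'   \code{amplitude}, \code{sigma} (one row per component, sigma > 0).
#' @return Numeric vector of absorbances, same length as \code{x}.
#' @examples
#' gaussianSum(1121, data.frame(center = 1121, amplitude = 1, sigma = 5))  # 1
#' @export
gaussianSum <- function(x, comps) {
  comps <- as.data.frame(comps)
  if (nrow(comps) < 1) stop("comps must contain at least one component")
  if (any(comps$sigma <= 0)) stop("component sigmas must be > 0")
  y <- numeric(length(x))
  for (i in seq_len(nrow(comps))) {
    y <- y + comps$amplitude[i] *
      exp(-(x - comps$center[i])^2 / (2 * comps$sigma[i]^2))
  }
  y
}

#' Adjusted coefficient of determination
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - p - 1)} with
#' \eqn{R^2 = 1 - SSE/SST}; the penalty accounts for the p fitted
#' parameters (3 per Gaussian component).
#'
#' @param observed Numeric vector of data values.
#' @param fitted Numeric vector of model values, same length.
#' @param p Number of fitted parameters; requires \code{length(observed) > p + 1}.
#' @return The adjusted R-squared (a scalar in (-Inf, 1]).
#' @export
adjustedR2 <- function(observed, fitted, p) {
  n <- length(observed)
  if (length(fitted) != n) stop("observed and fitted must have equal length")
  if (n <= p + 1) stop(sprintf("need n > p + 1 (n = %d, p = %d)", n, p))
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("zero total variance: adjusted R-squared is undefined")
  sse <- sum((observed - fitted)^2)
  r2 <- 1 - sse / sst
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Candidate peak centers from the smoothed second derivative
#'
#' Smooths the region with a Savitzky-Golay filter and locates interior
#' local minima of its second derivative (band centers of overlapped
#' Gaussians show up as curvature dips well before they separate into
#' distinct maxima). Candidates are ranked by curvature depth and capped at
#' \code{nMax}; when nothing qualifies (a monotone ramp, say) the global
#' absorbance maximum is returned as a single fallback candidate.
#'
#' @param s A \linkS4class{Spectrum} region (>= 8 points).
#' @param nMax Maximum number of candidates returned.
#' @param sgWindow Odd Savitzky-Golay window length in points; must not
#'   exceed the region length.
#' @param sgOrder Savitzky-Golay polynomial order.
#' @return Numeric vector of candidate centers (cm-1), most prominent first.
#' @export
initialPeaks <- function(s, nMax = 10L, sgWindow = 15L, sgOrder = 3L) {
  stopifnot(methods::is(s, "Spectrum"))
  n <- length(s@wavenumbers)
  if (sgWindow %% 2 != 1) stop("sgWindow must be odd")
  if (sgWindow > n)
    stop(sprintf("sgWindow (%d) exceeds region length (%d)", sgWindow, n))
  if (sgOrder >= sgWindow) stop("sgOrder must be smaller than sgWindow")
  y <- s@absorbance
  d2 <- signal::sgolayfilt(y, p = sgOrder, n = sgWindow, m = 2)
  # interior minima only: the filter's edge fits can dip spuriously; the
  # curvature floor keeps numerical ripple on featureless traces out
  border <- max(2, (sgWindow + 1) %/% 2)
  floorD2 <- -1e-8 * max(diff(range(y)), .Machine$double.eps)
  cand <- integer(0)
  for (i in seq(border + 1, n - border)) {
    if (d2[i] < d2[i - 1] && d2[i] <= d2[i + 1] && d2[i] < floorD2) cand <- c(cand, i)
  }
  if (!length(cand)) return(s@wavenumbers[which.max(y)])
  cand <- cand[order(d2[cand])]
  s@wavenumbers[utils::head(cand, nMax)]
}

## Pack/unpack the 3k parameter vector (a1, c1, s1, a2, ...)
packPars <- function(comps) as.numeric(t(as.matrix(comps[, c("amplitude", "center", "sigma")])))
unpackPars <- function(par) {
  m <- matrix(par, ncol = 3, byrow = TRUE)
  data.frame(amplitude = m[, 1], center = m[, 2], sigma = m[, 3])[, c("center", "amplitude", "sigma")]
}

#' Fit a fixed number of Gaussian components to a region
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) over the 3k
#' parameters of a k-component Gaussian sum: centers are confined to the
#' region extended by a 10 cm-1 margin, amplitudes kept positive and sigmas
#' to [1, width/2] cm-1. Initialization comes either from candidate centers
#' (amplitudes read off the data, a mid-range sigma) or, for warm starts
#' during model growth, from a full component table; the optimizer never
#' worsens its initialization's residual sum of squares. Non-convergence is
#' reported through the \code{converged} flag, not an error.
#'
#' @param s A \linkS4class{Spectrum} region (baseline corrected).
#' @param init Either a numeric vector of initial centers (one per
#'   component) or a \code{data.frame}(center, amplitude, sigma) warm start.
#' @param centerMargin How far (cm-1) centers may move outside the region.
#' @param maxIter Maximum Levenberg-Marquardt iterations.
#' @return A \linkS4class{RegionFit} with components sorted by center.
#' @seealso \code{\link{selectModel}} for automatic component-count choice.
#' @export
fitFixedK <- function(s, init, centerMargin = 10, maxIter = 200L) {
  stopifnot(methods::is(s, "Spectrum"))
  x <- s@wavenumbers
  y <- s@absorbance
  lo <- min(x)
  hi <- max(x)
  width <- hi - lo
  sigMax <- max(width / 2, 1.5)
  if (is.data.frame(init)) {
    comps0 <- init[, c("center", "amplitude", "sigma")]
  } else {
    centers <- as.numeric(init)
    sig0 <- min(8, sigMax * 0.9)
    # model is linear in amplitudes: start from their least-squares solution
    # at the candidate centers (overlap-corrected, unlike raw data heights)
    G <- vapply(centers, function(cc) exp(-(x - cc)^2 / (2 * sig0^2)),
                numeric(length(x)))
    amp0 <- tryCatch(stats::coef(stats::lm.fit(G, y)), error = function(e) NULL)
    if (is.null(amp0) || any(!is.finite(amp0))) {
      amp0 <- vapply(centers, function(cc) y[which.min(abs(x - cc))], numeric(1))
    }
    comps0 <- data.frame(center = centers, amplitude = pmax(amp0, 1e-3),
                         sigma = sig0)
  }
  k <- nrow(comps0)
  if (k < 1) stop("init must define at least one component")
  comps0$center <- pmin(pmax(comps0$center, lo - centerMargin), hi + centerMargin)
  comps0$amplitude <- pmax(comps0$amplitude, 1e-6)
  comps0$sigma <- pmin(pmax(comps0$sigma, 1), sigMax)
  lower <- rep(c(1e-6, lo - centerMargin, 1), k)
  upper <- rep(c(Inf, hi + centerMargin, sigMax), k)
  res <- minpack.lm::nls.lm(
    par = packPars(comps0),
    lower = lower, upper = upper,
    fn = function(par) gaussianSum(x, unpackPars(par)) - y,
    control = minpack.lm::nls.lm.control(maxiter = as.integer(maxIter))
  )
  comps <- unpackPars(res$par)
  fitted <- gaussianSum(x, comps)
  n <- length(x)
  p <- 3L * k
  a2 <- if (n > p + 1 && stats::var(y) > 0) adjustedR2(y, fitted, p) else -Inf
  RegionFit(
    regionId = "", components = comps, adjR2 = a2, nPoints = n,
    converged = res$info %in% 1:4,
    residualRms = sqrt(mean((y - fitted)^2))
  )
}

#' Select the number of Gaussian components for a region
#'
#' Deterministic residual-guided model growth. The starting component count
#' is the number of curvature-detected candidates (clamped to
#' [\code{nMin}, \code{nMax}]); while the adjusted R-squared falls short of
#' \code{adjR2Min} and the cap has not been reached, one component is
#' inserted at the wavenumber of the largest absolute residual and the model
#' is refit from the previous solution. The first fit meeting the criterion
#' is returned; if none does by \code{nMax} components, the best fit seen
#' (highest adjusted R-squared) is returned instead -- fit quality is never
#' an error.
#'
#' @param s A \linkS4class{Spectrum} region (baseline corrected,
#'   normalized).
#' @param adjR2Min Adjusted R-squared acceptance threshold (default 0.999).
#' @param nMin,nMax Component-count bounds (defaults 1 and 10).
#' @param sgWindow,sgOrder Savitzky-Golay settings for
#'   \code{\link{initialPeaks}}; the window is shrunk automatically for
#'   short regions.
#' @param regionId Label stored on the returned fit.
#' @param maxIter Solver iteration cap per fit.
#' @return A \linkS4class{RegionFit} with \code{nMin <= k <= nMax}
#'   components.
#' @examples
#' truth <- data.frame(center = c(1629, 1688, 1740), amplitude = 1, sigma = 8)
#' x <- seq(1600, 1750, 2)
#' fit <- selectModel(Spectrum(x, gaussianSum(x, truth)))
#' nrow(components(fit))  # 3
#' @export
selectModel <- function(s, adjR2Min = 0.999, nMin = 1L, nMax = 10L,
                        sgWindow = 15L, sgOrder = 3L, regionId = "",
                        maxIter = 200L) {
  stopifnot(methods::is(s, "Spectrum"))
  if (nMin < 1 || nMax < nMin) stop("need 1 <= nMin <= nMax")
  x <- s@wavenumbers
  y <- s@absorbance
  n <- length(x)
  # keep the fit overdetermined: n > 3k + 1
  kCap <- min(nMax, max(1L, (n - 2L) %/% 3L))
  win <- min(sgWindow, if (n %% 2 == 1) n else n - 1L)
  cand <- initialPeaks(s, nMax = kCap, sgWindow = win, sgOrder = min(sgOrder, win - 1L))
  k0 <- min(max(length(cand), nMin), kCap)
  fit <- fitFixedK(s, init = cand[seq_len(min(k0, length(cand)))], maxIter = maxIter)
  grow <- function(fit) {
    resid <- y - gaussianSum(x, fit@components)
    i <- which.max(abs(resid))
    warm <- rbind(
      fit@components,
      data.frame(center = x[i], amplitude = max(abs(resid[i]), 1e-3), sigma = 5)
    )
    fitFixedK(s, init = warm, maxIter = maxIter)
  }
  while (nrow(fit@components) < nMin) fit <- grow(fit)
  best <- fit
  while (fit@adjR2 < adjR2Min && nrow(fit@components) < kCap) {
    fit <- grow(fit)
    if (fit@adjR2 > best@adjR2) best <- fit
  }
  out <- if (fit@adjR2 >= adjR2Min) fit else best
  methods::initialize(out, regionId = regionId)
}
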