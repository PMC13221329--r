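#' @include AllClasses.R
NULL

polyEval <- function(coefs, x) {
  y <- numeric(length(x)) + coefs[1]
  if (length(coefs) >= 2) y <- y + coefs[2] * x
  if (length(coefs) >= 3) y <- y + coefs[3] * x^2
  y
}

#' Generate a spectrum from a synthetic truth
#'
#' Evaluates the truth's Gaussian-sum signal on its grid, adds the
#' polynomial baseline and iid Gaussian noise drawn under the truth's seed.
#' The same truth always produces the bitwise-identical spectrum; the
#' caller's RNG state is left untouched.
#'
#' @param truth A \linkS4class{SyntheticTruth}.
#' @param siteId Site label stored on the spectrum.
#' @return A \linkS4class{Spectrum}.
#' @examples
#' truth <- SyntheticTruth(data.frame(center = 1121, amplitude = 1, sigma = 5),
#'                         noiseSd = 0.01, grid = c(1000, 1200, 2), seed = 7)
#' generateSpectrum(truth)
#' @export
generateSpectrum <- function(truth, siteId = "synthetic") {
  stopifnot(methods::is(truth, "SyntheticTruth"))
  g <- truth@grid
  x <- seq(g[1], g[2], by = g[3])
  if (length(x) < 8) stop("grid yields fewer than 8 points")
  y <- polyEval(truth@baseline, x)
  if (nrow(truth@components)) y <- y + gaussianSum(x, truth@components)
  if (truth@noiseSd > 0) {
    y <- y + withr::with_seed(truth@seed, stats::rnorm(length(x), 0, truth@noiseSd))
  }
  Spectrum(x, y, siteId = siteId,
           meta = list(synthetic = TRUE, seed = truth@seed, noise_sd = truth@noiseSd))
}

#' Synthetic fixture emulating one survey site
#'
#' Places one Gaussian component at every bundled band center of the chosen
#' survey site (fingerprint window through the high-wavenumber region),
#' drawing amplitudes and widths uniformly from the given ranges under the
#' seed, and renders the spectrum on a 600--3600 cm-1 grid at a 2 cm-1 step
#' (finer than the 4 cm-1 instrument resolution, so grid quantization stays
#' well below the 5 cm-1 matching tolerance). Real spectra these fixtures
#' emulate only in band-center structure: amplitudes and widths are
#' unpublished, so intensities are synthetic by construction.
#'
#' @param site One of "SSV", "SMTL", "TL", "C", "SPC", "SAC".
#' @param amplitudeRange Uniform amplitude range, a.u. (default [0.2, 1]).
#' @param sigmaRange Uniform sigma range, cm-1 (default [5, 12] -- typical
#'   mid-infrared bandwidths).
#' @param snr Signal-to-noise ratio: noise sd = max drawn amplitude / snr
#'   (default 50). Ignored when \code{noiseSd} is given.
#' @param noiseSd Explicit noise standard deviation, a.u. (optional).
#' @param baseline Polynomial baseline coefficients (default none).
#' @param seed Integer RNG seed.
#' @return List with \code{spectrum} (a \linkS4class{Spectrum}) and
#'   \code{truth} (the \linkS4class{SyntheticTruth} behind it).
#' @examples
#' fx <- siteFixture("SSV", seed = 1)
#' fx$truth
#' @export
siteFixture <- function(site, amplitudeRange = c(0.2, 1.0), sigmaRange = c(5, 12),
                        snr = 50, noiseSd = NULL, baseline = 0, seed = 1L) {
  centers <- peakCenters(surveyPeakLists(), site)
  if (!length(centers)) stop("unknown site: ", site)
  k <- length(centers)
  draws <- withr::with_seed(as.integer(seed), list(
    amplitude = stats::runif(k, amplitudeRange[1], amplitudeRange[2]),
    sigma = stats::runif(k, sigmaRange[1], sigmaRange[2])
  ))
  if (is.null(noiseSd)) noiseSd <- max(draws$amplitude) / snr
  truth <- SyntheticTruth(
    components = data.frame(center = centers, amplitude = draws$amplitude,
                            sigma = draws$sigma),
    baseline = baseline, noiseSd = noiseSd, grid = c(600, 3600, 2),
    seed = as.integer(seed)
  )
  list(spectrum = generateSpectrum(truth, siteId = site), truth = truth)
}

#' Random multi-Gaussian fixture on one region
#'
#' Places k component centers uniformly at random inside the region (inset
#' from the edges) conditional on every pairwise separation reaching
#' \code{minSeparation}, then draws amplitudes and widths uniformly and sets
#' the noise level from the requested signal-to-noise ratio. Used for recovery and property testing,
#' where the constraint separation >= 2.5 sigma keeps the components
#' resolvable.
#'
#' @param k Number of components, >= 1.
#' @param minSeparation Minimum pairwise center separation, cm-1.
#' @param snr Signal-to-noise ratio; \code{Inf} gives a noiseless fixture.
#' @param region Region id (see \code{\link{defaultRegions}}) or a one-row
#'   region data.frame.
#' @param seed Integer RNG seed.
#' @param amplitudeRange,sigmaRange Uniform sampling ranges.
#' @param edgeInset Keep centers this far (cm-1) from the region edges.
#' @return List with \code{spectrum} and \code{truth}, as
#'   \code{\link{siteFixture}}.
#' @examples
#' fx <- randomFixture(3, minSeparation = 30, snr = Inf, region = "R4", seed = 2)
#' components(fx$truth)
#' @export
randomFixture <- function(k, minSeparation, snr = Inf, region = "R4", seed = 1L,
                          amplitudeRange = c(0.2, 1.0), sigmaRange = c(5, 12),
                          edgeInset = 15) {
  if (k < 1) stop("k must be >= 1")
  if (is.character(region)) {
    regs <- defaultRegions()
    region <- regs[regs$region_id == region, , drop = FALSE]
    if (!nrow(region)) stop("unknown region id")
  }
  lo <- region$lo + edgeInset
  hi <- region$hi - edgeInset
  if (hi - lo < (k - 1) * minSeparation)
    stop(sprintf("cannot place %d centers %.0f cm-1 apart in [%.0f, %.0f]",
                 k, minSeparation, lo, hi))
  draws <- withr::with_seed(as.integer(seed), {
    # uniform placement conditional on all gaps >= minSeparation: sort k
    # uniforms over the slack width, then restore the mandatory spacing
    slack <- (hi - lo) - (k - 1) * minSeparation
    centers <- lo + sort(stats::runif(k, 0, slack)) +
      (seq_len(k) - 1) * minSeparation
    list(
      centers = centers,
      amplitude = stats::runif(k, amplitudeRange[1], amplitudeRange[2]),
      sigma = stats::runif(k, sigmaRange[1], sigmaRange[2])
    )
  })
  noiseSd <- if (is.finite(snr)) max(draws$amplitude) / snr else 0
  truth <- SyntheticTruth(
    components = data.frame(center = draws$centers, amplitude = draws$amplitude,
                            sigma = draws$sigma),
    baseline = 0, noiseSd = noiseSd,
    grid = c(region$lo, region$hi, 2), seed = as.integer(seed)
  )
  list(spectrum = generateSpectrum(truth), truth = truth)
}
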