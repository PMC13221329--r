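#' @include AllClasses.R
NULL

## Asymmetric least squares (Eilers-Boelens) baseline estimate. Penalized
## weighted regression: minimize sum(w (y - z)^2) + lambda ||D2 z||^2 with
## weights pushed towards the lower envelope (w = p above the baseline,
## 1 - p below). The banded system is solved sparsely.
alsBaseline <- function(y, smoothness, asymmetry, iterations) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2, diagonals = list(
    rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2)
  ))
  P <- smoothness * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iterations)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(n, w) + P, w * y))
    w <- ifelse(y > z, asymmetry, 1 - asymmetry)
  }
  z
}

#' Baseline-correct a spectrum
#'
#' Estimates a smooth additive baseline by asymmetric least squares and
#' subtracts it. The asymmetry parameter pulls the estimate towards the lower
#' envelope of the data so that absorption bands sit on top of it; the
#' smoothness penalty (on the second difference) keeps the estimate too stiff
#' to follow the bands themselves. Peak apex positions are preserved to
#' within a grid step for band-on-smooth-baseline data, and applying the
#' correction twice changes very little (the second estimated baseline is
#' nearly zero).
#'
#' @param s A \linkS4class{Spectrum}.
#' @param smoothness Positive second-difference penalty weight
#'   (default 1e5; larger = stiffer baseline).
#' @param asymmetry Fraction in (0, 1); weight given to points above the
#'   baseline (default 0.01).
#' @param iterations Number of reweighting iterations (default 10).
#' @return The corrected \linkS4class{Spectrum}.
#' @examples
#' x <- seq(1600, 1750, 2)
#' y <- 0.5 + 1e-4 * (x - 1600) + exp(-(x - 1680)^2 / (2 * 8^2))
#' corrected <- correctBaseline(Spectrum(x, y))
#' @export
correctBaseline <- function(s, smoothness = 1e5, asymmetry = 0.01, iterations = 10L) {
  stopifnot(methods::is(s, "Spectrum"))
  if (!is.numeric(smoothness) || length(smoothness) != 1 || smoothness <= 0)
    stop("smoothness must be a positive number")
  if (asymmetry <= 0 || asymmetry >= 1)
    stop("asymmetry must lie strictly between 0 and 1")
  if (iterations < 1) stop("iterations must be a positive integer")
  z <- alsBaseline(s@absorbance, smoothness, asymmetry, as.integer(iterations))
  methods::initialize(s, absorbance = s@absorbance - z)
}

#' Min-max normalize a spectrum
#'
#' Rescales the absorbance axis linearly so its minimum maps to 0 and its
#' maximum to 1; the value ordering (and hence every peak position) is
#' unchanged, and the map is idempotent. Normalization is applied to the
#' whole spectrum, not per region, so relative intensities between regions
#' remain comparable.
#'
#' @param s A \linkS4class{Spectrum} with non-constant absorbance.
#' @return The normalized \linkS4class{Spectrum}.
#' @export
normalizeSpectrum <- function(s) {
  stopifnot(methods::is(s, "Spectrum"))
  a <- s@absorbance
  rng <- range(a)
  if (rng[1] == rng[2])
    stop("cannot normalize a constant spectrum (zero intensity range)")
  methods::initialize(s, absorbance = (a - rng[1]) / (rng[2] - rng[1]))
}

#' Segment a spectrum into analysis regions
#'
#' Slices out, for each region, exactly the points whose wavenumber lies in
#' the closed interval [lo, hi]; a point on a shared endpoint therefore
#' belongs to both neighbouring regions. Regions covered by fewer than 8
#' points are omitted with a warning; no points are ever fabricated.
#'
#' @param s A \linkS4class{Spectrum}.
#' @param regions Region table (see \code{\link{defaultRegions}}).
#' @return Named list of \linkS4class{Spectrum} sub-spectra, one per region
#'   retained, in the order of \code{regions}.
#' @examples
#' x <- seq(600, 3700, 2)
#' segs <- segmentSpectrum(Spectrum(x, rep(0.5 + 1e-3, length(x)) + 1e-4 * sin(x)))
#' length(segs$R3)  # 76 points across 1600-1750 at 2 cm-1
#' @export
segmentSpectrum <- function(s, regions = defaultRegions()) {
  stopifnot(methods::is(s, "Spectrum"))
  out <- list()
  for (i in seq_len(nrow(regions))) {
    sel <- s@wavenumbers >= regions$lo[i] & s@wavenumbers <= regions$hi[i]
    n <- sum(sel)
    if (n == 0) next
    if (n < 8) {
      warning(sprintf(
        "region %s covered by only %d point(s); omitted", regions$region_id[i], n
      ))
      next
    }
    out[[regions$region_id[i]]] <- methods::initialize(
      s,
      wavenumbers = s@wavenumbers[sel], absorbance = s@absorbance[sel]
    )
  }
  if (!length(out)) stop("spectrum does not overlap any analysis region")
  out
}

#' Detect peaks by local maxima
#'
#' Direct band location for regions that are not Gaussian-deconvolved (the
#' 600--1000 cm-1 fingerprint window by default): interior local maxima of
#' the absorbance trace, kept when their prominence (height above the higher
#' of the two flanking valleys, walking out to the nearest taller point)
#' exceeds a threshold.
#'
#' @param s A \linkS4class{Spectrum} (typically one region, baseline
#'   corrected and normalized).
#' @param minProminence Minimum prominence in the spectrum's intensity units.
#' @return Numeric vector of peak wavenumbers, ascending (possibly empty).
#' @export
detectPeaks <- function(s, minProminence = 0.05) {
  stopifnot(methods::is(s, "Spectrum"))
  y <- s@absorbance
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  keep <- vapply(idx, function(i) {
    lmin <- y[i]
    j <- i
    while (j > 1 && y[j] <= y[i]) {
      j <- j - 1
      lmin <- min(lmin, y[j])
    }
    rmin <- y[i]
    j <- i
    while (j < n && y[j] <= y[i]) {
      j <- j + 1
      rmin <- min(rmin, y[j])
    }
    y[i] - max(lmin, rmin) >= minProminence
  }, logical(1))
  sort(s@wavenumbers[idx[keep]])
}
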