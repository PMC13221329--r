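#' @include AllGenerics.R
NULL

REGION_IDS <- c("FP", "R1", "R2", "R3", "R4")

#' Default analysis regions
#'
#' The wavenumber windows into which a spectrum is segmented before band
#' analysis. Four regions are deconvolved into Gaussian components: R1
#' (1000--1200 cm-1, C-O stretching of esters and ethers), R2 (1200--1600
#' cm-1, C-H bending and aromatic ring modes), R3 (1600--1750 cm-1, carbonyl
#' stretching of amides, esters and ketones) and R4 (2800--3600 cm-1, C-H and
#' O-H stretching). The low fingerprint window FP (600--1000 cm-1) is handled
#' by direct peak detection rather than Gaussian fitting (\code{mode
#' "detect_only"}); switch its mode to \code{"deconvolve"} to fit it too.
#' Bounds are closed on both sides, so adjacent regions share their endpoint.
#'
#' @return A \code{data.frame} with columns \code{region_id}, \code{lo},
#'   \code{hi} (cm-1) and \code{mode}.
#' @examples
#' defaultRegions()
#' @export
defaultRegions <- function() {
  data.frame(
    region_id = REGION_IDS,
    lo = c(600, 1000, 1200, 1600, 2800),
    hi = c(1000, 1200, 1600, 1750, 3600),
    mode = c("detect_only", "deconvolve", "deconvolve", "deconvolve", "deconvolve"),
    stringsAsFactors = FALSE
  )
}

## ---- Spectrum ------------------------------------------------------------

#' Spectrum: a single-beam absorption spectrum
#'
#' Holds one infrared absorption spectrum on a strictly ascending wavenumber
#' grid, together with a site label and free-form metadata. The ascending
#' convention is enforced on construction even though FTIR spectra are
#' conventionally plotted with the axis reversed; all region bounds in the
#' package are closed intervals in cm-1 on this axis.
#'
#' @slot wavenumbers Numeric, strictly ascending, within [400, 4500] cm-1.
#' @slot absorbance Numeric of the same length, finite, arbitrary units.
#' @slot siteId Character scalar site label (may be "").
#' @slot meta Named list of free-form metadata (resolution, source file, ...).
#' @name Spectrum-class
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    wavenumbers = "numeric",
    absorbance = "numeric",
    siteId = "character",
    meta = "list"
  ),
  prototype(siteId = "", meta = list())
)

setValidity("Spectrum", function(object) {
  w <- object@wavenumbers
  a <- object@absorbance
  msg <- character()
  if (length(w) != length(a))
    msg <- c(msg, "wavenumbers and absorbance must have equal length")
  if (length(w) < 8)
    msg <- c(msg, sprintf("a spectrum needs at least 8 points (got %d)", length(w)))
  if (length(w) >= 2 && any(diff(w) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (length(w) && (min(w) < 400 || max(w) > 4500))
    msg <- c(msg, "wavenumbers must lie within [400, 4500] cm-1")
  if (length(a) && !all(is.finite(a)))
    msg <- c(msg, "absorbance values must all be finite")
  if (length(object@siteId) != 1)
    msg <- c(msg, "siteId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Points are re-ordered so the wavenumber axis is strictly ascending,
#' whatever the input order.
#'
#' @param wavenumbers Numeric vector of wavenumbers (cm-1).
#' @param absorbance Numeric vector of absorbances, same length.
#' @param siteId Site label.
#' @param meta Named list of metadata.
#' @return A \linkS4class{Spectrum}.
#' @examples
#' s <- Spectrum(seq(600, 700, by = 4), rnorm(26, 1, 0.01), siteId = "demo")
#' s
#' @export
Spectrum <- function(wavenumbers, absorbance, siteId = "", meta = list()) {
  o <- order(wavenumbers)
  methods::new("Spectrum",
    wavenumbers = as.numeric(wavenumbers[o]),
    absorbance = as.numeric(absorbance[o]),
    siteId = as.character(siteId), meta = meta
  )
}

#' @rdname accessors
#' @export
setMethod("wavenumbers", "Spectrum", function(x) x@wavenumbers)

#' @rdname accessors
#' @export
setMethod("absorbance", "Spectrum", function(x) x@absorbance)

#' @rdname accessors
#' @export
setMethod("siteId", "Spectrum", function(x) x@siteId)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf(
    "Spectrum%s: %d points, %.0f-%.0f cm-1, absorbance range [%.4g, %.4g]\n",
    if (nzchar(object@siteId)) paste0(" [", object@siteId, "]") else "",
    length(object@wavenumbers), min(object@wavenumbers), max(object@wavenumbers),
    min(object@absorbance), max(object@absorbance)
  ))
})

#' @export
setMethod("length", "Spectrum", function(x) length(x@wavenumbers))

## ---- PeakSet -------------------------------------------------------------

#' PeakSet: band centers grouped by site and region
#'
#' A tidy table of deconvolved (or directly read) band centers, one row per
#' (site, region, center). On construction rows are sorted by site, region and
#' ascending center, exact duplicates are removed, and each center is checked
#' against its region's bounds. Printed band tables occasionally file a center
#' in the nearest region column even when it falls slightly outside the bound
#' (carbonyl bands just above 1750 cm-1 end up in the 1600--1750 column, for
#' instance), so containment is enforced with a bucket margin rather than
#' strictly; centers beyond the margin are rejected.
#'
#' @slot peaks \code{data.frame} with columns \code{site_id}, \code{region_id},
#'   \code{center}.
#' @slot regions The region table the centers were validated against.
#' @slot margin Containment margin in cm-1.
#' @name PeakSet-class
#' @aliases PeakSet-class
#' @exportClass PeakSet
setClass("PeakSet",
  representation(peaks = "data.frame", regions = "data.frame", margin = "numeric")
)

setValidity("PeakSet", function(object) {
  p <- object@peaks
  msg <- character()
  need <- c("site_id", "region_id", "center")
  if (!all(need %in% names(p)))
    return("peaks must have columns site_id, region_id, center")
  bad <- setdiff(unique(p$region_id), object@regions$region_id)
  if (length(bad))
    msg <- c(msg, paste0("unknown region_id: ", paste(bad, collapse = ", ")))
  if (nrow(p)) {
    reg <- object@regions[match(p$region_id, object@regions$region_id), ]
    out <- !is.na(reg$lo) &
      (p$center < reg$lo - object@margin | p$center > reg$hi + object@margin)
    if (any(out)) {
      off <- sprintf("%s/%s %.1f", p$site_id[out], p$region_id[out], p$center[out])
      msg <- c(msg, paste0(
        "centers outside their region (margin ", object@margin, " cm-1): ",
        paste(off, collapse = "; ")
      ))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param peaks \code{data.frame} with columns \code{site_id},
#'   \code{region_id}, \code{center}.
#' @param regions Region table (see \code{\link{defaultRegions}}).
#' @param margin Containment margin in cm-1 around each region's bounds.
#' @return A \linkS4class{PeakSet} with rows sorted and deduplicated.
#' @examples
#' PeakSet(data.frame(site_id = "SSV", region_id = "R3", center = c(1713, 1640)))
#' @export
PeakSet <- function(peaks, regions = defaultRegions(), margin = 50) {
  peaks <- as.data.frame(peaks)[, c("site_id", "region_id", "center")]
  peaks$site_id <- as.character(peaks$site_id)
  peaks$region_id <- as.character(peaks$region_id)
  peaks$center <- as.numeric(peaks$center)
  peaks <- unique(peaks)
  peaks <- peaks[order(peaks$site_id, peaks$region_id, peaks$center), , drop = FALSE]
  rownames(peaks) <- NULL
  methods::new("PeakSet", peaks = peaks, regions = regions, margin = margin)
}

#' @rdname accessors
#' @export
setMethod("peakTable", "PeakSet", function(x) x@peaks)

setMethod("show", "PeakSet", function(object) {
  cat(sprintf(
    "PeakSet: %d centers, %d site(s) [%s]\n", nrow(object@peaks),
    length(unique(object@peaks$site_id)),
    paste(unique(object@peaks$site_id), collapse = ", ")
  ))
})

#' Extract peak centers for one site
#'
#' @param x A \linkS4class{PeakSet}.
#' @param site Site label.
#' @param region Optional region id; if omitted, centers from all regions.
#' @return Sorted numeric vector of centers (cm-1).
#' @examples
#' peakCenters(surveyPeakLists(), "SSV", "R3")
#' @export
peakCenters <- function(x, site, region = NULL) {
  stopifnot(methods::is(x, "PeakSet"))
  p <- x@peaks[x@peaks$site_id == site, , drop = FALSE]
  if (!is.null(region)) p <- p[p$region_id == region, , drop = FALSE]
  sort(p$center)
}

## ---- RegionFit -----------------------------------------------------------

emptyComponents <- function() {
  data.frame(center = numeric(), amplitude = numeric(), sigma = numeric())
}

#' RegionFit: a multi-Gaussian fit of one spectral region
#'
#' The result of fitting k Gaussian components
#' \eqn{g(x) = \sum_i a_i \exp(-(x - c_i)^2 / (2 \sigma_i^2))}
#' to one region's absorbance profile. Components are stored sorted by
#' center; amplitudes are apex heights (not areas) and widths are Gaussian
#' sigma (FWHM = 2 sqrt(2 ln 2) sigma).
#'
#' @slot regionId Region identifier.
#' @slot components \code{data.frame} with columns \code{center},
#'   \code{amplitude}, \code{sigma}, sorted by center.
#' @slot adjR2 Adjusted R-squared of the fit, with p = 3k parameters.
#' @slot nPoints Number of data points fitted.
#' @slot converged Logical solver-convergence flag.
#' @slot residualRms Root-mean-square residual (absorbance units).
#' @name RegionFit-class
#' @aliases RegionFit-class
#' @exportClass RegionFit
setClass("RegionFit",
  representation(
    regionId = "character",
    components = "data.frame",
    adjR2 = "numeric",
    nPoints = "integer",
    converged = "logical",
    residualRms = "numeric"
  )
)

setValidity("RegionFit", function(object) {
  cmp <- object@components
  msg <- character()
  if (!all(c("center", "amplitude", "sigma") %in% names(cmp)))
    return("components must have columns center, amplitude, sigma")
  if (nrow(cmp) < 1) msg <- c(msg, "a fit must have at least one component")
  if (nrow(cmp) && any(cmp$amplitude <= 0)) msg <- c(msg, "amplitudes must be > 0")
  if (nrow(cmp) && any(cmp$sigma <= 0)) msg <- c(msg, "sigmas must be > 0")
  if (nrow(cmp) && is.unsorted(cmp$center)) msg <- c(msg, "components must be sorted by center")
  if (length(object@adjR2) != 1 || object@adjR2 > 1 + 1e-12)
    msg <- c(msg, "adjR2 must be a scalar <= 1")
  if (length(msg)) msg else TRUE
})

RegionFit <- function(regionId, components, adjR2, nPoints, converged, residualRms) {
  components <- components[order(components$center), , drop = FALSE]
  rownames(components) <- NULL
  methods::new("RegionFit",
    regionId = regionId, components = components, adjR2 = adjR2,
    nPoints = as.integer(nPoints), converged = converged, residualRms = residualRms
  )
}

#' @rdname accessors
#' @export
setMethod("components", "RegionFit", function(x) x@components)

#' @rdname accessors
#' @export
setMethod("adjR2", "RegionFit", function(x) x@adjR2)

setMethod("show", "RegionFit", function(object) {
  cat(sprintf(
    "RegionFit [%s]: %d component(s), adj. R2 = %.6f, rms = %.3g%s\n",
    object@regionId, nrow(object@components), object@adjR2, object@residualRms,
    if (object@converged) "" else " (NOT converged)"
  ))
  print(round(object@components, 3))
})

## ---- BandLibrary ---------------------------------------------------------

#' BandLibrary: reference infrared band assignments
#'
#' A table of literature-style reference bands against which observed peak
#' centers are matched. A band is either a \code{point} (a single position,
#' matched within a tolerance tau) or an \code{interval} (a closed wavenumber
#' range, matched by containment without tolerance expansion -- the printed
#' range already encodes the spread). Each band carries a functional-group
#' tag used by the polymer rules.
#'
#' @slot bandTable \code{data.frame} with columns \code{band_id}, \code{kind}
#'   ("point"/"interval"), \code{center}, \code{lo}, \code{hi}, \code{group},
#'   \code{label}.
#' @name BandLibrary-class
#' @aliases BandLibrary-class
#' @exportClass BandLibrary
setClass("BandLibrary", representation(bandTable = "data.frame"))

setValidity("BandLibrary", function(object) {
  b <- object@bandTable
  msg <- character()
  need <- c("band_id", "kind", "center", "lo", "hi", "group", "label")
  if (!all(need %in% names(b)))
    return(paste("bandTable must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(b$band_id)) msg <- c(msg, "band_id values must be unique")
  if (!all(b$kind %in% c("point", "interval")))
    msg <- c(msg, "kind must be 'point' or 'interval'")
  pt <- b$kind == "point"
  if (any(pt & !is.finite(b$center))) msg <- c(msg, "point bands need a finite center")
  if (any(!pt & (!is.finite(b$lo) | !is.finite(b$hi) | b$lo >= b$hi)))
    msg <- c(msg, "interval bands need finite lo < hi")
  if (length(msg)) msg else TRUE
})

#' Construct a BandLibrary
#'
#' @param bandTable See \linkS4class{BandLibrary}.
#' @return A \linkS4class{BandLibrary}.
#' @export
BandLibrary <- function(bandTable) {
  bandTable <- as.data.frame(bandTable)
  if (!"center" %in% names(bandTable)) bandTable$center <- NA_real_
  if (!"lo" %in% names(bandTable)) bandTable$lo <- NA_real_
  if (!"hi" %in% names(bandTable)) bandTable$hi <- NA_real_
  if (!"label" %in% names(bandTable)) bandTable$label <- ""
  rownames(bandTable) <- NULL
  methods::new("BandLibrary", bandTable = bandTable[, c(
    "band_id", "kind", "center", "lo", "hi", "group", "label"
  )])
}

#' @rdname accessors
#' @export
setMethod("bands", "BandLibrary", function(x) x@bandTable)

setMethod("show", "BandLibrary", function(object) {
  b <- object@bandTable
  cat(sprintf(
    "BandLibrary: %d bands (%d point, %d interval), %d functional groups\n",
    nrow(b), sum(b$kind == "point"), sum(b$kind == "interval"),
    length(unique(b$group))
  ))
})

#' @export
setMethod("length", "BandLibrary", function(x) nrow(x@bandTable))

## ---- OccurrenceMatrix ----------------------------------------------------

#' OccurrenceMatrix: site-by-polymer presence table
#'
#' Logical matrix with one row per site and one column per polymer rule,
#' TRUE where every required band group of that polymer's rule was matched by
#' at least one peak at that site, plus the per-cell match evidence
#' (band id and matched peak center per required group).
#'
#' @slot flags Logical matrix, sites x polymers, with dimnames.
#' @slot evidence Nested list: \code{evidence[[site]][[polymer]]} is a list of
#'   per-group \code{data.frame}s of (band_id, center) matches.
#' @name OccurrenceMatrix-class
#' @aliases OccurrenceMatrix-class
#' @exportClass OccurrenceMatrix
setClass("OccurrenceMatrix", representation(flags = "matrix", evidence = "list"))

setValidity("OccurrenceMatrix", function(object) {
  f <- object@flags
  if (!is.logical(f)) return("flags must be a logical matrix")
  if (nrow(f) > 0 && is.null(rownames(f)))
    return("flags must have site rownames")
  if (ncol(f) > 0 && is.null(colnames(f)))
    return("flags must have polymer colnames")
  TRUE
})

OccurrenceMatrix <- function(flags, evidence = list()) {
  methods::new("OccurrenceMatrix", flags = flags, evidence = evidence)
}

#' @rdname accessors
#' @export
setMethod("occurrenceFlags", "OccurrenceMatrix", function(x) x@flags)

#' @rdname accessors
#' @export
setMethod("occurrenceEvidence", "OccurrenceMatrix", function(x) x@evidence)

setMethod("show", "OccurrenceMatrix", function(object) {
  cat(sprintf(
    "OccurrenceMatrix: %d site(s) x %d polymer feature(s)\n",
    nrow(object@flags), ncol(object@flags)
  ))
  disp <- ifelse(object@flags, "present", "absent")
  print(as.data.frame(disp))
})

#' @export
setMethod("dim", "OccurrenceMatrix", function(x) dim(x@flags))

## ---- SyntheticTruth ------------------------------------------------------

#' SyntheticTruth: ground truth behind a generated spectrum
#'
#' The generative recipe for a synthetic spectrum: Gaussian components, a
#' polynomial baseline of degree at most 2 (coefficients \code{b0 + b1 x +
#' b2 x^2} over cm-1), additive iid Gaussian noise, a regular wavenumber grid
#' and the RNG seed, so that every downstream result can be checked against
#' the construction.
#'
#' @slot components \code{data.frame}(center, amplitude, sigma).
#' @slot baseline Numeric polynomial coefficients, length 1--3.
#' @slot noiseSd Noise standard deviation (a.u.), >= 0.
#' @slot grid Numeric c(lo, hi, step) in cm-1.
#' @slot seed Integer RNG seed.
#' @name SyntheticTruth-class
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    components = "data.frame", baseline = "numeric",
    noiseSd = "numeric", grid = "numeric", seed = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  g <- object@grid
  cmp <- object@components
  if (length(g) != 3 || g[3] <= 0 || g[1] >= g[2])
    msg <- c(msg, "grid must be c(lo, hi, step) with lo < hi and step > 0")
  if (length(object@baseline) < 1 || length(object@baseline) > 3)
    msg <- c(msg, "baseline polynomial degree must be <= 2")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (nrow(cmp)) {
    if (any(cmp$amplitude <= 0) || any(cmp$sigma <= 0))
      msg <- c(msg, "component amplitudes and sigmas must be > 0")
    if (object@noiseSd >= max(cmp$amplitude) && object@noiseSd > 0)
      msg <- c(msg, "noiseSd must be smaller than the largest amplitude")
    if (length(g) == 3 && (min(cmp$center) < g[1] || max(cmp$center) > g[2]))
      msg <- c(msg, "component centers must lie within the grid")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticTruth
#'
#' @param components \code{data.frame}(center, amplitude, sigma).
#' @param baseline Polynomial coefficients (intercept first), degree <= 2.
#' @param noiseSd Additive Gaussian noise standard deviation (a.u.).
#' @param grid \code{c(lo, hi, step)} in cm-1.
#' @param seed Integer RNG seed used when noise is drawn.
#' @return A \linkS4class{SyntheticTruth}.
#' @examples
#' SyntheticTruth(data.frame(center = 1121, amplitude = 1, sigma = 5),
#'                grid = c(1000, 1200, 2))
#' @export
SyntheticTruth <- function(components, baseline = 0, noiseSd = 0,
                           grid = c(600, 3600, 2), seed = 1L) {
  components <- as.data.frame(components)[, c("center", "amplitude", "sigma")]
  components <- components[order(components$center), , drop = FALSE]
  rownames(components) <- NULL
  methods::new("SyntheticTruth",
    components = components, baseline = as.numeric(baseline),
    noiseSd = noiseSd, grid = as.numeric(grid), seed = as.integer(seed)
  )
}

#' @rdname accessors
#' @export
setMethod("components", "SyntheticTruth", function(x) x@components)

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d component(s), grid %g-%g cm-1 step %g, noise sd %g, seed %d\n",
    nrow(object@components), object@grid[1], object@grid[2], object@grid[3],
    object@noiseSd, object@seed
  ))
})
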