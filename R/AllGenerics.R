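#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Accessors for the core classes: \code{wavenumbers} and \code{absorbance}
#' return the two axes of a \linkS4class{Spectrum}; \code{siteId} its site
#' label; \code{components} the fitted Gaussian parameter table of a
#' \linkS4class{RegionFit} (or the true component table of a
#' \linkS4class{SyntheticTruth}); \code{adjR2} the adjusted coefficient of
#' determination of a fit; \code{bands} the band table of a
#' \linkS4class{BandLibrary}; \code{occurrenceFlags} the logical
#' site-by-polymer matrix of an \linkS4class{OccurrenceMatrix} and
#' \code{occurrenceEvidence} its per-cell match evidence; \code{peakTable}
#' the (site, region, center) table of a \linkS4class{PeakSet}.
#'
#' @param x An object of the appropriate class.
#' @return The slot content described above.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @rdname accessors
#' @export
setGeneric("adjR2", function(x) standardGeneric("adjR2"))

#' @rdname accessors
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))

#' @rdname accessors
#' @export
setGeneric("occurrenceFlags", function(x) standardGeneric("occurrenceFlags"))

#' @rdname accessors
#' @export
setGeneric("occurrenceEvidence", function(x) standardGeneric("occurrenceEvidence"))

#' @rdname accessors
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))
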