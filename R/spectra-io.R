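#' @include AllClasses.R
NULL

#' Read a spectrum from a delimited or JCAMP-DX file
#'
#' Delimited dialects expect two numeric columns (wavenumber in cm-1,
#' absorbance); non-numeric header rows are skipped, and a row with exactly
#' one numeric field is treated as malformed and reported with its line
#' number. Files listed with the wavenumber axis descending are re-ordered
#' ascending. The \code{jcampdx} dialect reads simple uncompressed
#' \code{XYPOINTS=(XY..XY)} and \code{XYDATA=(X++(Y..Y))} blocks.
#'
#' @param path Path to the file.
#' @param dialect One of \code{"csv"}, \code{"tsv"}, \code{"jcampdx"}.
#' @param siteId Optional site label; defaults to the file's base name (or
#'   the JCAMP TITLE when present).
#' @return A \linkS4class{Spectrum}.
#' @seealso \code{\link{writeSpectrum}}
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeSpectrum(Spectrum(seq(600, 660, 4), rep(c(0.1, 0.2), 8)), f)
#' readSpectrum(f)
#' @export
readSpectrum <- function(path, dialect = c("csv", "tsv", "jcampdx"), siteId = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "jcampdx") return(readJCAMP(path, siteId = siteId))
  sep <- if (dialect == "csv") "," else "\t"
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  w <- numeric(0)
  a <- numeric(0)
  for (i in keep) {
    fields <- trimws(strsplit(lines[[i]], sep, fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields)]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) >= 2 && all(is.finite(vals[1:2]))) {
      w <- c(w, vals[1])
      a <- c(a, vals[2])
    } else if (any(is.finite(vals))) {
      stop(sprintf("malformed spectrum row at line %d of %s: '%s'", i, path, lines[[i]]))
    } # else: header / comment row, skipped
  }
  if (length(w) < 8)
    stop(sprintf("spectrum in %s has %d points; at least 8 required", path, length(w)))
  if (is.null(siteId)) siteId <- tools::file_path_sans_ext(basename(path))
  Spectrum(w, a, siteId = siteId, meta = list(source = path, dialect = dialect))
}

#' Write a spectrum to a delimited or JCAMP-DX file
#'
#' Delimited output has a \code{wavenumber_cm1}, \code{absorbance} header.
#' Values are written with enough digits that a write-then-read round trip
#' reproduces the spectrum to better than 1e-9.
#'
#' @param s A \linkS4class{Spectrum}.
#' @param path Output path.
#' @param dialect One of \code{"csv"}, \code{"tsv"}, \code{"jcampdx"}.
#' @return \code{path}, invisibly.
#' @export
writeSpectrum <- function(s, path, dialect = c("csv", "tsv", "jcampdx")) {
  dialect <- match.arg(dialect)
  stopifnot(methods::is(s, "Spectrum"))
  if (dialect == "jcampdx") return(writeJCAMP(s, path))
  sep <- if (dialect == "csv") "," else "\t"
  lines <- c(
    paste("wavenumber_cm1", "absorbance", sep = sep),
    paste(sprintf("%.10g", s@wavenumbers), sprintf("%.12g", s@absorbance), sep = sep)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a peak list file
#'
#' Expects delimited text (tab or comma separated, sniffed from the header)
#' with columns \code{site_id}, \code{region_id}, \code{center}. Centers are
#' grouped by (site, region), sorted ascending and deduplicated, whatever
#' their order in the file. Unknown region ids, or centers falling outside
#' their region's bounds beyond the bucket margin, raise a validation error
#' listing the offenders.
#'
#' @param path Path to the file.
#' @param regions Region table (see \code{\link{defaultRegions}}).
#' @param margin Containment margin in cm-1 (see \linkS4class{PeakSet}).
#' @return A \linkS4class{PeakSet}; empty file gives an empty PeakSet.
#' @seealso \code{\link{writePeakList}}, \code{\link{surveyPeakLists}}
#' @export
readPeakList <- function(path, regions = defaultRegions(), margin = 50) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(PeakSet(
      data.frame(site_id = character(), region_id = character(), center = numeric()),
      regions = regions, margin = margin
    ))
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  df <- utils::read.table(
    text = lines, sep = sep, header = TRUE,
    stringsAsFactors = FALSE, strip.white = TRUE
  )
  need <- c("site_id", "region_id", "center")
  if (!all(need %in% names(df)))
    stop("peak list must have columns site_id, region_id, center; got: ",
         paste(names(df), collapse = ", "))
  PeakSet(df, regions = regions, margin = margin)
}

#' Write a peak list file
#'
#' Tab-separated, three columns, one row per (site, region, center); reading
#' it back with \code{\link{readPeakList}} is the identity.
#'
#' @param x A \linkS4class{PeakSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePeakList <- function(x, path) {
  stopifnot(methods::is(x, "PeakSet"))
  p <- x@peaks
  lines <- c(
    "site_id\tregion_id\tcenter",
    sprintf("%s\t%s\t%.10g", p$site_id, p$region_id, p$center)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a screening report
#'
#' Writes the occurrence matrix as a tab-separated table, one row per site
#' and one column per polymer label with cells \code{present}/\code{absent};
#' when region fits are supplied, a companion \code{*_fits.tsv} file lists
#' the fitted components per site and region.
#'
#' @param matrix An \linkS4class{OccurrenceMatrix} (must be non-empty).
#' @param path Output TSV path.
#' @param fits Optional named list (by site) of lists of
#'   \linkS4class{RegionFit} objects.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readReport}}
#' @export
writeReport <- function(matrix, path, fits = NULL) {
  stopifnot(methods::is(matrix, "OccurrenceMatrix"))
  f <- matrix@flags
  if (nrow(f) == 0) stop("cannot write a report for an empty occurrence matrix")
  header <- paste(c("site_id", colnames(f)), collapse = "\t")
  rows <- vapply(seq_len(nrow(f)), function(i) {
    paste(c(rownames(f)[i], ifelse(f[i, ], "present", "absent")), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  if (!is.null(fits) && length(fits)) {
    fitPath <- paste0(tools::file_path_sans_ext(path), "_fits.tsv")
    lines <- "site_id\tregion_id\tcenter\tamplitude\tsigma\tadj_r2\tconverged"
    for (site in names(fits)) {
      for (rf in fits[[site]]) {
        cmp <- rf@components
        lines <- c(lines, sprintf(
          "%s\t%s\t%.6g\t%.6g\t%.6g\t%.8f\t%s",
          site, rf@regionId, cmp$center, cmp$amplitude, cmp$sigma,
          rf@adjR2, rf@converged
        ))
      }
    }
    writeLines(lines, fitPath)
  }
  invisible(path)
}

#' Read back an occurrence report
#'
#' Parses a TSV written by \code{\link{writeReport}} into an
#' \linkS4class{OccurrenceMatrix} (flags only; evidence is not serialized).
#'
#' @param path Path to the report TSV.
#' @return An \linkS4class{OccurrenceMatrix}.
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"site_id" %in% names(df)) stop("report must have a site_id column")
  flags <- as.matrix(df[, setdiff(names(df), "site_id"), drop = FALSE]) == "present"
  rownames(flags) <- df$site_id
  OccurrenceMatrix(flags)
}

#' Write region fits to JSON
#'
#' Serializes a list of \linkS4class{RegionFit} objects (or a named list of
#' such lists, one per site) as JSON: per region, the component table,
#' adjusted R-squared, convergence flag and residual rms.
#'
#' @param fits A list of \linkS4class{RegionFit}, or a named list of lists.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFitsJSON <- function(fits, path) {
  asRec <- function(rf) list(
    region_id = rf@regionId,
    components = rf@components,
    adj_r2 = rf@adjR2,
    n_points = rf@nPoints,
    converged = rf@converged,
    residual_rms = rf@residualRms
  )
  obj <- if (length(fits) && methods::is(fits[[1]], "RegionFit")) {
    lapply(fits, asRec)
  } else {
    lapply(fits, function(siteFits) lapply(siteFits, asRec))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bundled survey peak lists
#'
#' Deconvolved band centers reported for six sampling sites (SSV, SMTL, TL,
#' C, SPC, SAC) along an industrially impacted river system, as ingested from
#' the package's \code{extdata/survey_peaks.tsv}. These printed lists are the
#' screening pipeline's reference input: they exercise matching and rule
#' evaluation without any raw spectra.
#'
#' @return A \linkS4class{PeakSet} with six sites across regions FP, R1--R4.
#' @examples
#' peakCenters(surveyPeakLists(), "SPC", "R1")
#' @export
surveyPeakLists <- function() {
  readPeakList(system.file("extdata", "survey_peaks.tsv", package = "irscreen",
                           mustWork = TRUE))
}

#' Bundled survey occurrence reference
#'
#' The published site-by-polymer presence calls for the six survey sites,
#' used as the comparison reference for \code{\link{compareToReference}}.
#' The calls embed expert spectral judgment, so the default rule set is not
#' expected to reproduce them cell-for-cell (see the package vignette).
#'
#' @return An \linkS4class{OccurrenceMatrix}.
#' @export
surveyOccurrence <- function() {
  readReport(system.file("extdata", "survey_occurrence.tsv", package = "irscreen",
                         mustWork = TRUE))
}
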