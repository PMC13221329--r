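#' @include AllClasses.R
NULL

#' Default polymer reference-band library
#'
#' Literature-style infrared assignments for the functional groups screened
#' by the default rules: ester and carbonate carbonyls, C-O stretches,
#' aliphatic CH2/CH3 bending and stretching, C-Cl stretching, aromatic ring
#' and C-H modes, amide I/II, and the sulfonate S=O indicator near 1121 cm-1
#' associated with textile dye residues. Single literature positions are
#' \code{point} bands (matched within the tolerance tau, default 5 cm-1);
#' ranges are \code{interval} bands matched by closed containment with no
#' tolerance expansion.
#'
#' @return A \linkS4class{BandLibrary} of 18 bands.
#' @seealso \code{\link{defaultPolymerRules}}, \code{\link{matchBand}}
#' @export
defaultBandLibrary <- function() {
  iv <- function(id, lo, hi, group, label) {
    data.frame(band_id = id, kind = "interval", center = NA_real_,
               lo = lo, hi = hi, group = group, label = label)
  }
  pt <- function(id, center, group, label) {
    data.frame(band_id = id, kind = "point", center = center,
               lo = NA_real_, hi = NA_real_, group = group, label = label)
  }
  BandLibrary(rbind(
    pt("sulfonate_SO", 1121, "sulfonate", "S=O stretch (sulfonated dye indicator)"),
    iv("ester_CO_stretch", 1713, 1750, "ester_carbonyl", "ester C=O stretch"),
    iv("ester_C_O", 1290, 1340, "ester_C_O", "ester C-O stretch"),
    iv("ester_CH_bend", 1410, 1470, "ester_CH_bend", "C-H bend / aromatic-related"),
    iv("carbonate_CO", 1760, 1770, "carbonate_carbonyl", "carbonate C=O stretch"),
    iv("carbonate_C_O", 1200, 1300, "carbonate_C_O", "C-O stretch (carbonate support)"),
    iv("carbonate_aromatic", 1450, 1500, "carbonate_aromatic", "aromatic ring (carbonate support)"),
    iv("C_Cl_stretch", 616, 691, "chlorinated", "C-Cl stretch"),
    iv("CH2_def_chlorinated", 1250, 1330, "chlorinated_CH", "CH2 deformation (chlorinated support)"),
    iv("CH2_stretch_broad", 2800, 3000, "CH2_stretch_broad", "CH2 stretch (broad window)"),
    iv("PE_CH2_bend", 1462, 1475, "PE_CH2_bend", "CH2 scissoring (polyethylene)"),
    iv("CH2_stretch", 2840, 2950, "aliphatic_CH_stretch", "sym/asym CH2 stretch"),
    pt("PP_CH3_bend", 1375, "CH3_bend", "CH3 symmetric bend (polypropylene)"),
    iv("aromatic_oop", 690, 700, "aromatic_oop", "aromatic C-H out-of-plane bend"),
    iv("aromatic_ring", 1450, 1600, "aromatic_ring", "aromatic ring stretch"),
    iv("aromatic_CH_stretch", 3000, 3100, "aromatic_CH", "aromatic C-H stretch"),
    iv("amide_I", 1637, 1650, "amide_I", "amide I (C=O stretch)"),
    iv("amide_II", 1537, 1540, "amide_II", "amide II (N-H bend / C-N stretch)")
  ))
}

#' Default polymer-compatibility rules
#'
#' Each rule is a conjunction of band groups; a group is satisfied when at
#' least one of its member bands matches any peak of the site, and a polymer
#' feature is flagged present only when every required group is satisfied.
#' The default conjunctions pair the diagnostic carbonyl/halide/aromatic
#' band of each polymer class with its supporting absorptions; amide II is
#' carried as optional corroborating evidence for the amide rule rather
#' than required, since amide I alone is the robust observable in
#' protein-rich environmental matrices.
#'
#' @return A list of rules, each
#'   \code{list(polymer =, groups = list(<band_id vectors>), optional = ...)}.
#' @seealso \code{\link{evaluateRules}}, \code{\link{buildOccurrenceMatrix}}
#' @export
defaultPolymerRules <- function() {
  list(
    list(polymer = "PE-like",
         groups = list("PE_CH2_bend", "CH2_stretch")),
    list(polymer = "PET-like",
         groups = list("ester_CO_stretch", "ester_C_O", "ester_CH_bend")),
    list(polymer = "PP-like",
         groups = list("PP_CH3_bend", "CH2_stretch")),
    list(polymer = "PVC-like",
         groups = list("C_Cl_stretch", "CH2_def_chlorinated", "CH2_stretch_broad")),
    list(polymer = "PC-like",
         groups = list("carbonate_CO", "carbonate_C_O", "carbonate_aromatic")),
    list(polymer = "PS-like",
         groups = list("aromatic_oop", "aromatic_ring", "aromatic_CH_stretch")),
    list(polymer = "Amide-like",
         groups = list("amide_I"), optional = list("amide_II"))
  )
}

#' Match one peak center against a reference band
#'
#' Point bands match when |c_peak - center| <= tau; interval bands match by
#' closed containment lo <= c_peak <= hi, with no tolerance expansion.
#' With tau = 0, point matching reduces to exact equality, and the point
#' match set can only grow as tau grows.
#'
#' @param cPeak Numeric vector of peak centers (cm-1).
#' @param band One band: a single-row \code{data.frame} (or list) with
#'   fields \code{kind} and \code{center} or \code{lo}/\code{hi}.
#' @param tau Matching tolerance for point bands, cm-1, >= 0 (default 5).
#' @return Logical vector, one flag per element of \code{cPeak}.
#' @examples
#' sulf <- bands(defaultBandLibrary())[1, ]
#' matchBand(c(1119, 1147), sulf)  # TRUE FALSE
#' @export
matchBand <- function(cPeak, band, tau = 5) {
  if (tau < 0) stop("tau must be >= 0")
  band <- as.list(band)
  if (identical(band$kind, "point")) {
    abs(cPeak - band$center) <= tau
  } else if (identical(band$kind, "interval")) {
    cPeak >= band$lo & cPeak <= band$hi
  } else {
    stop("band kind must be 'point' or 'interval'")
  }
}

#' Assign peaks to reference bands
#'
#' Tests every (peak, band) pair for the given site(s); a peak may match
#' several bands and a band several peaks. Rows are ordered
#' deterministically by site, then peak center, then band id.
#'
#' @param peaks A \linkS4class{PeakSet}.
#' @param library A non-empty \linkS4class{BandLibrary}.
#' @param tau Point-band tolerance, cm-1.
#' @return \code{data.frame} with columns \code{site_id}, \code{region_id},
#'   \code{center}, \code{band_id}, \code{group}, one row per matched pair
#'   (zero rows when nothing matches).
#' @examples
#' ssv <- surveyPeakLists()
#' amide <- assignPeaks(ssv, defaultBandLibrary())
#' subset(amide, site_id == "SSV" & band_id == "amide_I")
#' @export
assignPeaks <- function(peaks, library, tau = 5) {
  stopifnot(methods::is(peaks, "PeakSet"), methods::is(library, "BandLibrary"))
  b <- library@bandTable
  if (nrow(b) == 0) stop("band library is empty")
  p <- peaks@peaks
  out <- list()
  for (j in seq_len(nrow(b))) {
    hit <- matchBand(p$center, b[j, ], tau = tau)
    if (any(hit)) {
      out[[length(out) + 1]] <- data.frame(
        site_id = p$site_id[hit], region_id = p$region_id[hit],
        center = p$center[hit], band_id = b$band_id[j], group = b$group[j]
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    site_id = character(), region_id = character(), center = numeric(),
    band_id = character(), group = character()
  )
  res <- res[order(res$site_id, res$center, res$band_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

checkRules <- function(rules, library) {
  ids <- library@bandTable$band_id
  for (r in rules) {
    if (is.null(r$polymer) || !length(r$groups))
      stop("each rule needs a polymer label and at least one required group")
    ref <- unique(unlist(c(r$groups, r$optional)))
    bad <- setdiff(ref, ids)
    if (length(bad))
      stop(sprintf("rule '%s' references bands absent from the library: %s",
                   r$polymer, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Evaluate polymer rules against a site's band assignments
#'
#' A polymer is flagged present iff every required group of its rule has at
#' least one matched band among the site's assignments; the evidence lists
#' the (band, matched center) pairs per group, with optional groups'
#' matches appended as corroboration that does not affect the flag.
#'
#' @param assignments Assignment table from \code{\link{assignPeaks}} for a
#'   single site.
#' @param rules Rule list (see \code{\link{defaultPolymerRules}}).
#' @return List with \code{flags} (named logical vector) and
#'   \code{evidence} (per polymer, a list of per-group match tables).
#' @export
evaluateRules <- function(assignments, rules) {
  flags <- logical(length(rules))
  names(flags) <- vapply(rules, `[[`, character(1), "polymer")
  evidence <- stats::setNames(vector("list", length(rules)), names(flags))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    ev <- list()
    ok <- TRUE
    for (g in seq_along(r$groups)) {
      hit <- assignments[assignments$band_id %in% r$groups[[g]], c("band_id", "center")]
      rownames(hit) <- NULL
      ev[[paste0("group", g)]] <- hit
      if (nrow(hit) == 0) ok <- FALSE
    }
    if (!is.null(r$optional)) {
      for (g in seq_along(r$optional)) {
        hit <- assignments[assignments$band_id %in% r$optional[[g]], c("band_id", "center")]
        if (nrow(hit)) {
          rownames(hit) <- NULL
          ev[[paste0("optional", g)]] <- hit
        }
      }
    }
    flags[i] <- ok
    evidence[[i]] <- ev
  }
  list(flags = flags, evidence = evidence)
}

#' Build the site-by-polymer occurrence matrix
#'
#' Runs \code{\link{assignPeaks}} and \code{\link{evaluateRules}} for every
#' site in the peak set; the result is deterministic for a given input,
#' library, rule set and tolerance.
#'
#' @param peaks A \linkS4class{PeakSet} with at least one site.
#' @param library A \linkS4class{BandLibrary}.
#' @param rules Rule list; validated against the library.
#' @param tau Point-band tolerance, cm-1.
#' @return An \linkS4class{OccurrenceMatrix}.
#' @examples
#' m <- buildOccurrenceMatrix(surveyPeakLists())
#' occurrenceFlags(m)[, "PC-like"]
#' @export
buildOccurrenceMatrix <- function(peaks, library = defaultBandLibrary(),
                                  rules = defaultPolymerRules(), tau = 5) {
  stopifnot(methods::is(peaks, "PeakSet"))
  sites <- unique(peaks@peaks$site_id)
  if (!length(sites)) stop("peak set contains no sites")
  checkRules(rules, library)
  polymers <- vapply(rules, `[[`, character(1), "polymer")
  asg <- assignPeaks(peaks, library, tau = tau)
  flags <- matrix(FALSE, nrow = length(sites), ncol = length(polymers),
                  dimnames = list(sites, polymers))
  evidence <- stats::setNames(vector("list", length(sites)), sites)
  for (site in sites) {
    res <- evaluateRules(asg[asg$site_id == site, , drop = FALSE], rules)
    flags[site, ] <- res$flags
    evidence[[site]] <- res$evidence
  }
  OccurrenceMatrix(flags, evidence)
}

#' Amplitude of the fitted component matching an indicator band
#'
#' Looks up, in a region fit, the component whose center lies within tau of
#' a point indicator band (the 1121 cm-1 sulfonate band, typically) and
#' returns its fitted apex amplitude -- the quantity compared across sites
#' when screening for textile-influenced inputs. The nearest center wins;
#' exact distance ties resolve to the lower wavenumber.
#'
#' @param fit A \linkS4class{RegionFit} for the region containing the
#'   indicator.
#' @param band A point \code{ReferenceBand} row (see
#'   \code{\link{defaultBandLibrary}}).
#' @param tau Tolerance, cm-1.
#' @return The matched component's amplitude, or \code{NA_real_} when no
#'   component matches.
#' @export
indicatorIntensity <- function(fit, band, tau = 5) {
  stopifnot(methods::is(fit, "RegionFit"))
  band <- as.list(band)
  if (!identical(band$kind, "point"))
    stop("indicatorIntensity expects a point band")
  cmp <- fit@components
  d <- abs(cmp$center - band$center)
  ok <- which(d <= tau)
  if (!length(ok)) return(NA_real_)
  best <- ok[order(d[ok], cmp$center[ok])][1]
  cmp$amplitude[best]
}

#' Compare an occurrence matrix against a reference
#'
#' Reports every (site, polymer) cell where the computed matrix disagrees
#' with a reference matrix, plus the overall agreement fraction. Site and
#' polymer label sets must coincide (order may differ).
#'
#' @param matrix Computed \linkS4class{OccurrenceMatrix}.
#' @param reference Reference \linkS4class{OccurrenceMatrix}.
#' @return List with \code{differences} (\code{data.frame} site_id, polymer,
#'   observed, reference) and \code{agreement} (fraction of agreeing cells).
#' @examples
#' cmp <- compareToReference(buildOccurrenceMatrix(surveyPeakLists()),
#'                           surveyOccurrence())
#' cmp$agreement
#' @export
compareToReference <- function(matrix, reference) {
  stopifnot(methods::is(matrix, "OccurrenceMatrix"),
            methods::is(reference, "OccurrenceMatrix"))
  f <- matrix@flags
  r <- reference@flags
  if (!setequal(rownames(f), rownames(r)))
    stop("site labels differ between matrix and reference")
  if (!setequal(colnames(f), colnames(r)))
    stop("polymer labels differ between matrix and reference")
  r <- r[rownames(f), colnames(f), drop = FALSE]
  diffIdx <- which(f != r, arr.ind = TRUE)
  differences <- data.frame(
    site_id = rownames(f)[diffIdx[, 1]],
    polymer = colnames(f)[diffIdx[, 2]],
    observed = f[diffIdx],
    reference = r[diffIdx]
  )
  differences <- differences[order(differences$site_id, differences$polymer), , drop = FALSE]
  rownames(differences) <- NULL
  list(differences = differences, agreement = 1 - nrow(differences) / length(f))
}
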