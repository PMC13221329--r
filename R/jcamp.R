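#' @include AllClasses.R
NULL

## Minimal JCAMP-DX support: uncompressed XYPOINTS=(XY..XY) and
## XYDATA=(X++(Y..Y)) with AFFN numerics only. SQZ/DIF/DUP compressed forms
## are rejected with a clear error; vendor binary formats are out of scope.

readJCAMP <- function(path, siteId = NULL) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub("^##[^=]*=", "", hit[[1]]))
  }
  start <- grep("^##(XYDATA|XYPOINTS)\\s*=", lines, ignore.case = TRUE)
  if (!length(start))
    stop("no XYDATA or XYPOINTS block found in JCAMP-DX file ", path)
  start <- start[[1]]
  form <- toupper(trimws(sub("^##[^=]*=", "", lines[[start]])))
  isTabular <- grepl("XY\\.\\.XY", form)
  if (!isTabular && !grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
    stop("unsupported JCAMP-DX data form '", form, "' in ", path,
         " (only (XY..XY) and (X++(Y..Y)) are supported)")
  end <- grep("^##", lines[-seq_len(start)])
  end <- if (length(end)) start + end[[1]] - 1 else length(lines)
  body <- lines[seq(start + 1, end)]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("[A-DF-Za-df-z%@]", body)))
    stop("compressed (SQZ/DIF/DUP) JCAMP-DX data are not supported: ", path)
  xf <- suppressWarnings(as.numeric(ldr("XFACTOR")))
  yf <- suppressWarnings(as.numeric(ldr("YFACTOR")))
  if (is.na(xf)) xf <- 1
  if (is.na(yf)) yf <- 1
  toks <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[,;[:space:]]+")[[1]]))
    if (any(is.na(v))) stop("malformed JCAMP-DX data line in ", path, ": '", l, "'")
    v
  })
  if (isTabular) {
    v <- unlist(toks)
    if (length(v) %% 2 != 0)
      stop("odd number of values in JCAMP-DX XYPOINTS block of ", path)
    w <- v[seq(1, length(v), by = 2)] * xf
    a <- v[seq(2, length(v), by = 2)] * yf
  } else {
    w <- numeric(0)
    a <- numeric(0)
    npt <- suppressWarnings(as.numeric(ldr("NPOINTS")))
    firstx <- suppressWarnings(as.numeric(ldr("FIRSTX")))
    lastx <- suppressWarnings(as.numeric(ldr("LASTX")))
    dx <- if (is.finite(firstx) && is.finite(lastx) && is.finite(npt) && npt > 1) {
      (lastx - firstx) / (npt - 1)
    } else {
      NA_real_
    }
    for (v in toks) {
      if (length(v) < 2) stop("JCAMP-DX X++(Y..Y) line with no Y values in ", path)
      x0 <- v[1] * xf
      ys <- v[-1] * yf
      step <- if (is.finite(dx)) dx else {
        stop("cannot infer DELTAX for X++(Y..Y) block of ", path,
             " (FIRSTX/LASTX/NPOINTS missing)")
      }
      w <- c(w, x0 + step * (seq_along(ys) - 1))
      a <- c(a, ys)
    }
  }
  if (length(w) < 8)
    stop(sprintf("spectrum in %s has %d points; at least 8 required", path, length(w)))
  if (is.null(siteId)) {
    siteId <- ldr("TITLE")
    if (is.na(siteId) || !nzchar(siteId))
      siteId <- tools::file_path_sans_ext(basename(path))
  }
  Spectrum(w, a, siteId = siteId, meta = list(source = path, dialect = "jcampdx"))
}

writeJCAMP <- function(s, path) {
  w <- s@wavenumbers
  a <- s@absorbance
  pairs <- sprintf("%.10g, %.12g", w, a)
  lines <- c(
    paste0("##TITLE=", if (nzchar(s@siteId)) s@siteId else "spectrum"),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.10g", w[1]),
    sprintf("##LASTX=%.10g", w[length(w)]),
    sprintf("##NPOINTS=%d", length(w)),
    "##XYPOINTS=(XY..XY)",
    pairs,
    "##END="
  )
  writeLines(lines, path)
  invisible(path)
}
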