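test_that("delimited spectra round-trip and enforce the ascending axis", {
  s <- gridSpectrum(600, 700, 4)
  for (dialect in c("csv", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    writeSpectrum(s, f, dialect = dialect)
    r <- readSpectrum(f, dialect = dialect)
    expect_equal(wavenumbers(r), wavenumbers(s))
    expect_equal(absorbance(r), absorbance(s), tolerance = 1e-9)
  }
  # descending file order comes back ascending
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "wavenumber_cm1,absorbance",
    sprintf("%d,%g", seq(700, 600, by = -4), seq(0.1, 0.6, length.out = 26))
  ), f)
  r <- readSpectrum(f)
  expect_false(is.unsorted(wavenumbers(r)))
  expect_equal(absorbance(r)[1], 0.6)  # the value that came with 600
})

test_that("spectrum reader rejects tiny and malformed files with line info", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm1,absorbance", "600,0.01", "604,0.02", "608,0.01"), f)
  expect_error(readSpectrum(f), "at least 8")
  writeLines(c("wavenumber_cm1,absorbance", "600,0.01", "604,oops"), f)
  expect_error(readSpectrum(f), "line 3")
  expect_error(readSpectrum(tempfile()), "not found")
})

test_that("JCAMP-DX output round-trips to an identical spectrum", {
  s <- Spectrum(seq(600, 1400, 4), exp(-seq(-3, 3, length.out = 201)^2) + 0.01,
                siteId = "SSV")
  f <- withr::local_tempfile(fileext = ".jdx")
  writeSpectrum(s, f, dialect = "jcampdx")
  r <- readSpectrum(f, dialect = "jcampdx")
  expect_equal(wavenumbers(r), wavenumbers(s))
  expect_equal(absorbance(r), absorbance(s), tolerance = 1e-9)
  expect_equal(siteId(r), "SSV")
})

test_that("JCAMP-DX reader handles X++(Y..Y) and rejects compressed data", {
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=demo", "##JCAMP-DX=4.24", "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##FIRSTX=600", "##LASTX=618", "##NPOINTS=10",
    "##XFACTOR=1", "##YFACTOR=0.001",
    "##XYDATA=(X++(Y..Y))",
    "600 10 20 30 40 50", "610 60 70 80 90 100",
    "##END="
  ), f)
  r <- readSpectrum(f, dialect = "jcampdx")
  expect_equal(wavenumbers(r), seq(600, 618, by = 2))
  expect_equal(absorbance(r), seq(0.01, 0.1, by = 0.01))
  writeLines(c(
    "##TITLE=demo", "##FIRSTX=600", "##LASTX=618", "##NPOINTS=10",
    "##XYDATA=(X++(Y..Y))", "600 A10 J20 K30", "##END="
  ), f)
  expect_error(readSpectrum(f, dialect = "jcampdx"), "compressed")
})

test_that("peak lists are sorted, deduplicated and validated on ingestion", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "site_id\tregion_id\tcenter",
    "SMTL\tR4\t2863", "SMTL\tR4\t2916", "SMTL\tR4\t2986", "SMTL\tR4\t2966",
    "SSV\tR1\t1024", "SSV\tR1\t1024"
  ), f)
  ps <- readPeakList(f)
  expect_equal(peakCenters(ps, "SMTL", "R4"), c(2863, 2916, 2966, 2986))
  expect_equal(peakCenters(ps, "SSV", "R1"), 1024)  # duplicate collapsed

  writeLines(c("site_id\tregion_id\tcenter", "SSV\tR9\t1024"), f)
  expect_error(readPeakList(f), "unknown region")
  writeLines(c("site_id\tregion_id\tcenter", "SSV\tR1\t1500"), f)
  expect_error(readPeakList(f), "outside their region.*1500")

  # empty file -> empty peak set
  writeLines(character(), f)
  expect_equal(nrow(peakTable(readPeakList(f))), 0L)
})

test_that("peak list ingestion is idempotent through its own serialization", {
  ps <- surveyPeakLists()
  f <- withr::local_tempfile(fileext = ".tsv")
  writePeakList(ps, f)
  expect_identical(peakTable(readPeakList(f)), peakTable(ps))
})

test_that("bundled survey lists carry the printed band centers", {
  ps <- surveyPeakLists()
  expect_setequal(unique(peakTable(ps)$site_id),
                  c("SSV", "SMTL", "TL", "C", "SPC", "SAC"))
  expect_equal(peakCenters(ps, "SSV", "R3"), c(1640, 1654, 1664, 1713, 1743))
  expect_equal(peakCenters(ps, "SMTL", "R1"),
               c(1011, 1050, 1086, 1104, 1124, 1134, 1155))
  expect_length(peakCenters(ps, "SPC", "R1"), 7)
})

test_that("occurrence reports write one row per site and round-trip", {
  m <- buildOccurrenceMatrix(surveyPeakLists())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeReport(m, f)
  expect_length(readLines(f), 7L)  # header + six sites
  r <- readReport(f)
  expect_identical(occurrenceFlags(r), occurrenceFlags(m))

  one <- OccurrenceMatrix(matrix(TRUE, 1, 1, dimnames = list("S", "PET-like")))
  writeReport(one, f)
  expect_length(readLines(f), 2L)
  empty <- OccurrenceMatrix(matrix(logical(), 0, 1, dimnames = list(NULL, "x")))
  expect_error(writeReport(empty, f), "empty")
})

test_that("fits serialize to JSON with full parameter tables", {
  fit <- fitFixedK(gaussSpectrum(data.frame(center = 1680, amplitude = 1, sigma = 8),
                                 1600, 1750), init = 1680)
  f <- withr::local_tempfile(fileext = ".json")
  writeFitsJSON(list(R3 = fit), f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$R3$components$center, components(fit)$center, tolerance = 1e-6)
  expect_true(is.numeric(parsed$R3$adj_r2))
})
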