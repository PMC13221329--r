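sulfonate <- function() {
  b <- bands(defaultBandLibrary())
  b[b$band_id == "sulfonate_SO", ]
}

test_that("point and interval matching follow the tolerance rules", {
  expect_true(matchBand(1119, sulfonate(), tau = 5))
  expect_true(matchBand(1121, sulfonate(), tau = 5))
  expect_false(matchBand(1147, sulfonate(), tau = 5))  # |1147 - 1121| = 26
  # tau = 0 reduces to exact equality
  expect_true(matchBand(1121, sulfonate(), tau = 0))
  expect_false(matchBand(1121.5, sulfonate(), tau = 0))
  expect_error(matchBand(1121, sulfonate(), tau = -1), "tau")
  # interval containment is closed and not tau-expanded
  amide <- bands(defaultBandLibrary())
  amide <- amide[amide$band_id == "amide_I", ]
  expect_true(matchBand(1637, amide))
  expect_true(matchBand(1650, amide))
  expect_false(matchBand(1651, amide, tau = 100))
})

test_that("point matches grow monotonically with tolerance", {
  centers <- peakCenters(surveyPeakLists(), "SPC")
  taus <- c(0, 2, 5, 10, 26)
  prev <- character()
  for (tau in taus) {
    hit <- centers[matchBand(centers, sulfonate(), tau = tau)]
    expect_true(all(prev %in% as.character(hit)))
    prev <- as.character(hit)
  }
})

test_that("peak assignment reproduces the worked survey examples", {
  ps <- surveyPeakLists()
  asg <- assignPeaks(ps, defaultBandLibrary())
  ssvAmide <- asg[asg$site_id == "SSV" & asg$band_id == "amide_I", ]
  expect_equal(ssvAmide$center, 1640)  # exactly one of 1640/1654/1664/1713/1743
  cCarbonate <- asg[asg$site_id == "C" & asg$band_id == "carbonate_CO", ]
  expect_equal(cCarbonate$center, 1768)
  # ordering is deterministic: site, then center, then band id
  expect_false(is.unsorted(order(asg$site_id, asg$center, asg$band_id)))
  # empty peak set -> empty table; empty library -> error
  empty <- PeakSet(data.frame(site_id = character(), region_id = character(),
                              center = numeric()))
  expect_equal(nrow(assignPeaks(empty, defaultBandLibrary())), 0L)
  expect_error(assignPeaks(ps, BandLibrary(bands(defaultBandLibrary())[0, ])),
               "empty")
})

test_that("assignment agrees with the brute-force all-pairs oracle", {
  ps <- surveyPeakLists()
  expect_equal(assignPeaks(ps, defaultBandLibrary(), tau = 5),
               bruteForceAssign(ps, defaultBandLibrary(), tau = 5))
})

test_that("rule evaluation demands every required group", {
  ps <- surveyPeakLists()
  lib <- defaultBandLibrary()
  rules <- defaultPolymerRules()
  asg <- assignPeaks(ps, lib)
  # Cuautlancingo: carbonate 1768 and 1267/1291 match, but nothing in [1450,1500]
  resC <- evaluateRules(asg[asg$site_id == "C", ], rules)
  expect_false(resC$flags[["PC-like"]])
  # SPC satisfies all three carbonate groups (1768, 1276, 1458)
  resSPC <- evaluateRules(asg[asg$site_id == "SPC", ], rules)
  expect_true(resSPC$flags[["PC-like"]])
  ev <- resSPC$evidence[["PC-like"]]
  expect_true(1768 %in% ev$group1$center)
  expect_true(1458 %in% ev$group3$center)
  # a rule whose single group finds nothing is false with empty evidence
  none <- list(list(polymer = "X", groups = list("carbonate_CO")))
  resSSV <- evaluateRules(asg[asg$site_id == "SSV", ], none)
  expect_false(resSSV$flags[["X"]])
  expect_equal(nrow(resSSV$evidence$X$group1), 0L)
})

test_that("flags always agree with their evidence", {
  m <- buildOccurrenceMatrix(surveyPeakLists())
  flags <- occurrenceFlags(m)
  ev <- occurrenceEvidence(m)
  for (site in rownames(flags)) {
    for (pol in colnames(flags)) {
      groups <- ev[[site]][[pol]]
      required <- groups[grepl("^group", names(groups))]
      allMatched <- all(vapply(required, nrow, integer(1)) > 0)
      expect_identical(flags[site, pol], allMatched)
    }
  }
})

test_that("occurrence matrix is deterministic and label-faithful", {
  ps <- surveyPeakLists()
  m1 <- buildOccurrenceMatrix(ps)
  m2 <- buildOccurrenceMatrix(ps)
  expect_identical(occurrenceFlags(m1), occurrenceFlags(m2))
  expect_equal(dim(m1), c(6L, 7L))
  # duplicating a site under a new label reproduces its row exactly
  p <- peakTable(ps)
  twin <- p[p$site_id == "SPC", ]
  twin$site_id <- "SPC2"
  m3 <- buildOccurrenceMatrix(PeakSet(rbind(p, twin)))
  expect_identical(unname(occurrenceFlags(m3)["SPC2", ]),
                   unname(occurrenceFlags(m3)["SPC", ]))
  # zero rules -> zero polymer columns
  m0 <- buildOccurrenceMatrix(ps, rules = list())
  expect_equal(ncol(occurrenceFlags(m0)), 0L)
  # rules referencing unknown bands are rejected
  bad <- list(list(polymer = "X", groups = list("no_such_band")))
  expect_error(buildOccurrenceMatrix(ps, rules = bad), "no_such_band")
})

test_that("adding peaks never clears a polymer flag", {
  ps <- surveyPeakLists()
  before <- occurrenceFlags(buildOccurrenceMatrix(ps))
  extra <- data.frame(site_id = rep(rownames(before), each = 2),
                      region_id = "R2", center = rep(c(1375, 1460), 6))
  after <- occurrenceFlags(buildOccurrenceMatrix(PeakSet(rbind(peakTable(ps), extra))))
  expect_true(all(after[before] ))  # every TRUE stays TRUE
})

test_that("indicator intensity looks up the nearest matching component", {
  fit <- RegionFitForTest <- fitFixedK(
    gaussSpectrum(data.frame(center = 1119, amplitude = 0.42, sigma = 6), 1000, 1200),
    init = 1119
  )
  expect_equal(indicatorIntensity(fit, sulfonate()), 0.42, tolerance = 1e-4)
  # nearest-center tie-break: 1117 vs 1124 around 1121 -> 1124 (distance 3 < 4)
  twin <- fitFixedK(
    gaussSpectrum(data.frame(center = c(1117, 1124), amplitude = c(0.3, 0.6),
                             sigma = c(5, 5)), 1000, 1200),
    init = c(1117, 1124)
  )
  expect_equal(indicatorIntensity(twin, sulfonate()), 0.6, tolerance = 1e-3)
  # nothing within tau -> absent
  far <- fitFixedK(
    gaussSpectrum(data.frame(center = 1050, amplitude = 1, sigma = 6), 1000, 1200),
    init = 1050
  )
  expect_true(is.na(indicatorIntensity(far, sulfonate())))
  expect_error(indicatorIntensity(fit, bands(defaultBandLibrary())[2, ]), "point")
})

test_that("reference comparison counts disagreements exactly", {
  m <- buildOccurrenceMatrix(surveyPeakLists())
  self <- compareToReference(m, m)
  expect_equal(self$agreement, 1)
  expect_equal(nrow(self$differences), 0L)
  # one flipped cell in 6 x 7 -> agreement 41/42
  flipped <- occurrenceFlags(m)
  flipped["SSV", "PE-like"] <- !flipped["SSV", "PE-like"]
  one <- compareToReference(m, OccurrenceMatrix(flipped))
  expect_equal(one$agreement, 41 / 42)
  expect_equal(one$differences$site_id, "SSV")
  # mismatched site sets are rejected
  sub <- OccurrenceMatrix(occurrenceFlags(m)[1:5, ])
  expect_error(compareToReference(m, sub), "site labels")
})
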