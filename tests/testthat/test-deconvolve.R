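test_that("gaussianSum matches the closed form and is linear in amplitude", {
  one <- data.frame(center = 1121, amplitude = 1, sigma = 5)
  expect_equal(gaussianSum(1121, one), 1)
  expect_equal(gaussianSum(1126, one), exp(-0.5))
  x <- seq(1100, 1140, 2)
  expect_equal(gaussianSum(x, rbind(one, one)), 2 * gaussianSum(x, one))
  expect_error(gaussianSum(x, data.frame(center = 1121, amplitude = 1, sigma = 0)),
               "sigma")
})

test_that("adjustedR2 follows its formula and guards degenerate input", {
  y <- c(1, 2, 3, 4, 5, 4, 3, 2)
  expect_equal(adjustedR2(y, y, p = 3), 1)
  expect_equal(adjustedR2(y, rep(mean(y), 8), p = 0), 0)
  # n = 100, SSE/SST = 0.01, p = 30 -> 1 - 0.01 * 99 / 69
  obs <- seq_len(100)
  sst <- sum((obs - mean(obs))^2)
  fitted <- obs + sqrt(0.01 * sst / 100)  # constant shift: SSE = 0.01 * SST
  expect_equal(adjustedR2(obs, fitted, p = 30), 1 - 0.01 * 99 / 69, tolerance = 1e-12)
  expect_error(adjustedR2(rep(1, 8), rep(1, 8), p = 0), "zero total variance")
  expect_error(adjustedR2(y, y, p = 7), "n > p")
})

test_that("curvature-based detection locates well-separated components", {
  truth <- data.frame(center = c(1629, 1688, 1768), amplitude = 1, sigma = 8)
  s <- gaussSpectrum(truth, 1600, 1820)
  cand <- initialPeaks(s)
  expect_length(cand, 3)
  expect_true(all(vapply(truth$center,
                         function(cc) min(abs(cand - cc)), numeric(1)) <= 2))
  # single component
  s1 <- gaussSpectrum(truth[1, ], 1600, 1750)
  expect_lte(abs(initialPeaks(s1) - 1629), 2)
  # monotone ramp: fallback at the maximum
  ramp <- Spectrum(seq(1600, 1750, 2), seq(0, 1, length.out = 76))
  expect_equal(initialPeaks(ramp), 1750)
  expect_error(initialPeaks(gridSpectrum(600, 620, 2), sgWindow = 99), "exceeds")
  expect_error(initialPeaks(s, sgWindow = 14), "odd")
})

test_that("fixed-k fits recover noiseless constructions", {
  truth <- data.frame(center = c(1629, 1688, 1740), amplitude = c(1, 0.5, 0.8),
                      sigma = c(8, 7, 9))
  s <- gaussSpectrum(truth, 1600, 1770)
  fit <- fitFixedK(s, init = truth$center + c(1, -1, 2))
  expect_true(all(centerErrors(fit, truth$center) < 0.5))
  expect_gt(adjR2(fit), 0.9999)
  expect_true(fit@converged)
  # k = 1 on a clean single Gaussian: parameters to solver tolerance
  s1 <- gaussSpectrum(data.frame(center = 3075, amplitude = 0.6, sigma = 11),
                      2800, 3600)
  f1 <- fitFixedK(s1, init = 3070)
  expect_equal(components(f1)$center, 3075, tolerance = 1e-4)
  expect_equal(components(f1)$amplitude, 0.6, tolerance = 1e-4)
  expect_equal(components(f1)$sigma, 11, tolerance = 1e-4)
})

test_that("residual rms reflects injected noise on a seeded fixture", {
  truth <- data.frame(center = c(1629, 1688, 1740), amplitude = c(1, 0.5, 0.8),
                      sigma = c(8, 7, 9))
  s <- gaussSpectrum(truth, 1600, 1770, noiseSd = 0.005, seed = 99)
  fit <- fitFixedK(s, init = truth$center)
  expect_gte(fit@residualRms, 0.5 * 0.005)
  expect_lte(fit@residualRms, 2 * 0.005)
})

test_that("model selection finds the true component count on clean fixtures", {
  truth <- data.frame(center = c(2850, 2930, 3080, 3230, 3400),
                      amplitude = c(0.8, 0.5, 1, 0.4, 0.7),
                      sigma = c(8, 10, 7, 9, 11))
  s <- gaussSpectrum(truth, 2800, 3600)
  fit <- selectModel(s)
  expect_equal(nrow(components(fit)), 5)
  expect_gt(adjR2(fit), 0.999)
  expect_true(all(centerErrors(fit, truth$center) < 0.5))
  # four components cannot reach the criterion on this construction
  capped <- selectModel(s, nMax = 4)
  expect_lt(adjR2(capped), 0.999)
  # single clean Gaussian: k = 1, essentially perfect
  one <- gaussSpectrum(data.frame(center = 1680, amplitude = 1, sigma = 8), 1600, 1750)
  f1 <- selectModel(one)
  expect_equal(nrow(components(f1)), 1)
  expect_gt(adjR2(f1), 0.9999)
})

test_that("selection respects the component-count bounds", {
  truth <- data.frame(center = c(2850, 2930, 3080), amplitude = 1, sigma = 8)
  s <- gaussSpectrum(truth, 2800, 3600, noiseSd = 0.02, seed = 5)
  for (nMax in c(2L, 6L, 10L)) {
    fit <- selectModel(s, nMax = nMax, nMin = 2L)
    expect_gte(nrow(components(fit)), 2L)
    expect_lte(nrow(components(fit)), nMax)
  }
})

test_that("warm-started growth never increases the minimized SSE", {
  truth <- data.frame(center = c(2850, 2930, 3080, 3230), amplitude = c(1, .6, .8, .4),
                      sigma = c(8, 10, 7, 9))
  s <- gaussSpectrum(truth, 2800, 3600, noiseSd = 0.01, seed = 17)
  x <- wavenumbers(s)
  y <- absorbance(s)
  fit <- fitFixedK(s, init = initialPeaks(s, nMax = 2))
  sse <- sum((y - gaussianSum(x, components(fit)))^2)
  for (step in 1:4) {
    resid <- y - gaussianSum(x, components(fit))
    i <- which.max(abs(resid))
    warm <- rbind(components(fit),
                  data.frame(center = x[i], amplitude = max(abs(resid[i]), 1e-3),
                             sigma = 5))
    fit <- fitFixedK(s, init = warm)
    sseNew <- sum((y - gaussianSum(x, components(fit)))^2)
    expect_lte(sseNew, sse * (1 + 1e-9))
    sse <- sseNew
  }
})

test_that("survey-style seven-band region is resolved by the growth procedure", {
  centers <- c(1011, 1050, 1086, 1104, 1124, 1134, 1155)
  # frozen fixture: draws under seed 1, noise at 1/50 of the strongest band
  tr <- withr::with_seed(1, data.frame(
    center = centers, amplitude = runif(7, 0.3, 1), sigma = runif(7, 6, 10)
  ))
  truth <- SyntheticTruth(tr, noiseSd = max(tr$amplitude) / 50,
                          grid = c(1000, 1200, 2), seed = 1)
  fit <- selectModel(generateSpectrum(truth))
  expect_lte(nrow(components(fit)), 10)
  expect_true(all(centerErrors(fit, centers) <= 3))
  # ensemble behaviour: the 1124/1134 pair (10 cm-1 apart) can merge for
  # unfavourable width draws, but at least five bands resolve in every draw
  for (sd in 2:5) {
    tr <- withr::with_seed(sd, data.frame(
      center = centers, amplitude = runif(7, 0.3, 1), sigma = runif(7, 6, 10)
    ))
    truth <- SyntheticTruth(tr, noiseSd = max(tr$amplitude) / 50,
                            grid = c(1000, 1200, 2), seed = sd)
    fit <- selectModel(generateSpectrum(truth))
    expect_lte(nrow(components(fit)), 10)
    expect_gte(sum(centerErrors(fit, centers) <= 3), 5)
  }
})
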