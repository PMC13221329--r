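# Shared fixture builders: everything is generated in code at test time.

# Flat-topped harmless spectrum on a regular grid
gridSpectrum <- function(lo = 600, hi = 3700, step = 2, values = NULL, site = "fx") {
  x <- seq(lo, hi, by = step)
  if (is.null(values)) values <- rep(0.5, length(x)) + 1e-4 * sin(x / 50)
  Spectrum(x, values, siteId = site)
}

# Gaussian-sum spectrum on a region grid, optional ramp baseline + seeded noise
gaussSpectrum <- function(comps, lo, hi, step = 2, baseline = 0, noiseSd = 0, seed = 1) {
  x <- seq(lo, hi, by = step)
  y <- gaussianSum(x, comps) + polyBase(baseline, x)
  if (noiseSd > 0) y <- y + withr::with_seed(seed, rnorm(length(x), 0, noiseSd))
  Spectrum(x, y)
}

polyBase <- function(coefs, x) {
  y <- numeric(length(x)) + coefs[1]
  if (length(coefs) >= 2) y <- y + coefs[2] * x
  if (length(coefs) >= 3) y <- y + coefs[3] * x^2
  y
}

# Minimum distance from each true center to any fitted center
centerErrors <- function(fit, trueCenters) {
  vapply(trueCenters, function(cc) min(abs(components(fit)$center - cc)), numeric(1))
}

# Independent brute-force band matcher: plain double loop, no vectorization,
# used as the oracle against assignPeaks
bruteForceAssign <- function(peakSet, library, tau = 5) {
  p <- peakTable(peakSet)
  b <- bands(library)
  rows <- list()
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(b))) {
      hit <- if (b$kind[j] == "point") {
        abs(p$center[i] - b$center[j]) <= tau
      } else {
        p$center[i] >= b$lo[j] && p$center[i] <= b$hi[j]
      }
      if (hit) {
        rows[[length(rows) + 1]] <- data.frame(
          site_id = p$site_id[i], region_id = p$region_id[i],
          center = p$center[i], band_id = b$band_id[j], group = b$group[j]
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$site_id, out$center, out$band_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
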