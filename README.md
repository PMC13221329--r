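# irscreen

Exploratory screening of **polymer-compatible spectral features** in
ATR-FTIR spectra of untreated environmental water samples — the kind of
rapid, digestion-free assessment used to flag potential microplastic and
industrial-pollution hotspots in heavily impacted rivers before committing
to particle-level analysis. The package is aimed at environmental
analytical chemists who have overlapped mid-infrared spectra (or published
band-center tables) of suspended matter and want a reproducible, auditable
path from raw absorbance to a site × polymer presence table.

## What it computes

Each spectral region is resolved into Gaussian band components

```
g(x) = Σᵢ aᵢ · exp(−(x − cᵢ)² / (2σᵢ²))
```

with apex amplitude `aᵢ`, center `cᵢ` (cm⁻¹) and width `σᵢ`. The pipeline:

1. **Preprocess** — asymmetric-least-squares baseline correction, min–max
   normalization to [0, 1], segmentation into the fingerprint window FP
   [600, 1000] cm⁻¹ and four deconvolution regions R1 [1000, 1200],
   R2 [1200, 1600], R3 [1600, 1750], R4 [2800, 3600].
2. **Deconvolve** — bounded Levenberg–Marquardt multi-Gaussian fits with
   automatic component-count selection: grow from curvature-detected
   candidates, inserting a component at the largest residual until the
   adjusted R² ( `1 − (1−R²)(n−1)/(n−p−1)`, `p = 3k` ) reaches 0.999 or the
   cap of 10 components is hit.
3. **Match** — compare fitted centers against a polymer reference-band
   library: single literature positions within ±5 cm⁻¹, literature ranges
   by closed containment.
4. **Screen** — evaluate conjunctive polymer rules (e.g. PC-like =
   carbonate C=O 1760–1770 AND C–O 1200–1300 AND aromatic 1450–1500) into
   an occurrence matrix with per-cell band evidence.

A synthetic-spectrum generator with full ground truth (components,
baseline, noise, seed) backs every validation claim. Band libraries and
rules are editable configuration, because presence calls of this kind
ultimately encode expert judgment.

## Worked example

The package bundles the deconvolved band-center lists of a six-site survey
of an industrially impacted river system (sites SSV, SMTL, TL, C, SPC,
SAC). Screening them with the default library and rules:

```r
library(irscreen)
res <- runScreen(surveyPeakLists())
res$occurrence
#> OccurrenceMatrix: 6 site(s) x 7 polymer feature(s)
#>      PE-like PET-like PP-like PVC-like PC-like PS-like Amide-like
#> C     absent   absent  absent  present  absent  absent     absent
#> SAC  present  present  absent   absent  absent present    present
#> SMTL present  present present  present present present     absent
#> SPC   absent  present  absent  present present present    present
#> SSV   absent  present  absent   absent  absent present    present
#> TL    absent  present present  present  absent  absent    present
```

Each `present` means every required band group of that polymer's rule was
matched by at least one site peak — e.g. PC-like fires only for SMTL
(1768, 1273, 1466 cm⁻¹) and SPC (1768, 1276, 1458 cm⁻¹). Comparing against
the bundled published presence calls enumerates where fixed rules and
expert judgment part ways:

```r
cmp <- compareToReference(res$occurrence, surveyOccurrence())
cmp$agreement
#> [1] 0.7142857
```

The spectra route runs the full deconvolution. On a synthetic SMTL fixture
(a Gaussian component at every bundled SMTL band center, SNR 50, seed 1):

```r
fx  <- siteFixture("SMTL", seed = 1)
out <- runScreen(list(fx$spectrum))
out$fits$SMTL$R1
#> RegionFit [R1]: 10 component(s), adj. R2 = 0.996341, rms = 0.0154 (NOT converged)
#>      center amplitude  sigma
#> ...
#> 7  1125.940     0.761  9.333
#> ...
indicatorIntensity(out$fits$SMTL$R1, bands(defaultBandLibrary())[1, ])
#> [1] 0.7612826
```

The component fitted at 1125.9 cm⁻¹ matches the sulfonate S=O indicator
band (1121 ± 5 cm⁻¹, a textile-pollution marker), and
`indicatorIntensity()` returns its apex amplitude for cross-site
comparison.

A thin command-line wrapper ships in `inst/scripts/irscreen`
(`screen`, `fit`, `assign`, `simulate` subcommands).

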