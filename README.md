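# shellcal

Pteropod shell transparency as a calibrated bioindicator of
ocean-acidification exposure.

Thecosome pteropods ("sea butterflies") build thin aragonite shells that
lose optical transparency when seawater aragonite saturation state
(Ω<sub>Ar</sub>) drops below a biological threshold near 1.5. Because the
loss accumulates with both the intensity and the duration of exposure, a
single shell photographed from a net tow integrates the carbonate-chemistry
history of the water it lived in — something no point chemical measurement
can provide. `shellcal` is for researchers and monitoring programmes who
want to use that signal quantitatively: it turns micrographs and water
chemistry into a fitted calibration, and turns an observed shell back into
the set of exposures that could have produced it.

## The model

Transparency `T` (mean shell-pixel greyscale / 255; 1 = pristine white)
after ~4 days at saturation state Ω follows a seasonal power law, and
longer exposures below the Ω ≈ 1.5 threshold depress it linearly:

```
T = alpha_s * Omega^b            (Day-4 baseline, "D4T")
T_obs - D4T = s * D + beta       (duration deficit, medium/high only)
alpha = 1.0293 * T_Day0 - 0.1087 (seasonal intercept from field shells)
```

with `b = 0.255` (mean of five independent seasonal fits, SE 0.032) and
`s = -0.0238` transparency per day. Inverting the chain yields Ω at an
assumed duration, duration at an assumed Ω, and — swept over Ω up to the
1.5 threshold — an *exposure envelope* for one observed shell. The
package also provides the supporting blocks: a DIC/TA ↔ pH/pCO₂/Ω
carbonate-system solver (total scale, Mehrbach-refit K1/K2, Dickson
KHSO₄, Mucci aragonite Ksp), micrograph segmentation and scoring,
Q10-normalised respiration rates, a gene-expression biomarker screen
(|R| > 0.5, R² > 0.4 against Ω), and synthetic-data generators that make
the whole chain testable end to end.

## Worked example

Speciate a high-CO₂ treatment's mean chemistry (November, DIC = 2199.7,
TA = 2202.4 µmol kg⁻¹, S = 33, 7.57 °C):

```r
library(shellcal)
solve_from_dic_ta(2199.7, 2202.4, 33, 7.57)
#>   salinity temperature_C dic_umol_kg ta_umol_kg       ph pco2_uatm omega_ar
#> 1       33          7.57      2199.7     2202.4 7.571358  1246.274 0.631547
```

Ω<sub>Ar</sub> = 0.63: corrosive to aragonite. Fit the calibration chain
on a synthetic seasonal campaign and inspect the fitted model:

```r
d   <- generate_transparency_dataset(generator_config(), seed = 42)
fit <- fit_transparency_model(d)
fit
#> Seasonal shell-transparency calibration (T = alpha * Omega^b)
#>   420 records, 5 seasons
#>   exponent b: 0.2599 (SE 0.02091, n = 5 seasons)
#>   duration slope: -0.02293 transparency/day, beta: 0.09666 (n = 280)
#>   alpha = 1.006 * Day0 -0.0945 (R2 0.999); pristine alpha 0.8108
```

The refit recovers the generating exponent (0.255) and duration slope
(−0.0238) within their standard errors, and the usual methods
(`coef`, `predict`, `residuals`, `simulate`, `plot`) apply. Finally,
invert one wild-caught shell scored at `T = 0.65`:

```r
env <- exposure_envelope(0.65)
head(env, 3)
#>   omega_ar duration_days
#> 1     0.50      8.834043
#> 2     0.51      8.851069
#> 3     0.52      8.867773
```

Reading: a shell this altered implies roughly 8.8–9.8 days of exposure
anywhere on the Ω grid up to the 1.5 threshold — severe, sustained
exposure, though intensity and duration are only jointly identified.
`emergence_time("eq6_verbatim")` (≈ 2.3 days) gives the shortest
exposure at which transparency changes become detectable at all.

## Layout

- `R/` — carbonate solver, image scoring, calibration fit (`shellcal`
  S3 class), exposure inversion, respiration, biomarker screen,
  synthetic-data generators
- `tests/testthat/` — unit, property and acceptance suites (all
  fixtures generated in code)
- `vignettes/shell-transparency-bioindicator.Rmd` — the methods
  vignette: model, assumptions, parameter choices, generator design,
  limitations
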