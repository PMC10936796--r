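# trawlniche

Catch-weighted thermal-niche and life-history analysis for demersal
fishes sampled by seasonal bottom-trawl research surveys.

Research surveys record, for every tow, where the net fished (depth,
bottom temperature) and how many individuals of a species it caught —
including the zero-catch tows. For data-poor species such as deep-water
sharks, these records are often the only basis for describing habitat
preference, maturity, and abundance. trawlniche turns the three standard
survey tables (stations, specimens, stomachs) into that species profile,
and ships a synthetic survey generator with known parameters so every
statistic can be validated against closed forms.

## What it computes

For station temperatures (or depths) `T_i` with catch counts `w_i`, the
catch-weighted quantile `Q_w(p)` is the type-7 quantile of the expanded
per-individual vector (each `T_i` repeated `w_i` times). On top of this
primitive:

* **Thermal bias** `TB = Q_w(0.5) − Q_1(0.5)`: catch-weighted median
  temperature minus the median over *all* stations (zero-catch tows
  included). `TB > 0` ⇒ warmwater species.
* **Steno index** `Q_w(0.95) − Q_w(0.05)`: width of the central 90% of
  the catch-weighted temperature distribution; small ⇒ stenothermal.
* **Weighted/unweighted ECDFs and occupancy intervals** for temperature
  and depth, per season or pooled.
* **Maturity ogive** `logit P(mature) = β0 + β1·TL`, fitted by in-package
  IRLS with separation detection; `L50 = −β0/β1`, bootstrap percentile CI.
* **Length–weight** `ln W = log a + b·ln TL` by OLS on the log-log scale.
* **Diet**: vacuity, frequency of occurrence (denominator: non-empty
  stomachs), weight percentages.
* **Habitat envelopes** of subgroups (juveniles, late-stage females) and
  their overlap — the descriptive construction for critical-habitat
  delineation.
* **Annual abundance index**: mean catch per tow per season-year, with an
  optional OLS trend.

## Worked example

Simulate a two-season survey of 4,000 tows of a stenothermal warmwater
species and profile it:

```r
library(trawlniche)

cfg <- generator_config(n_stations = c(spring = 2000, autumn = 2000))
sv  <- generate_survey(cfg, seed = 42)

niche_summary(sv$stations, "temperature")
#> Catch-weighted niche summary: temperature (both surveys)
#>   thermal bias: 1.41 degC (warm-water)
#>   central 90% width (Steno): 1.98 degC
#>   weighted   5-95% interval: [6.2, 8.2] degC
#>   unweighted 5-95% interval: [1.5, 9.8] degC
#>   stations used: 4000 (excluded for missing temperature: 0), total catch 4229
```

The species is caught in a 2 °C band although the survey fished an 8 °C
range, and sits 1.4 °C warmer than the typical station: a stenothermal,
warmwater profile. The generator's parameters imply closed-form values
TB = 1.46 and Steno = 2.09 (catch-weighted temperature is exactly
Normal(7.150, 0.6352)); the estimates above differ only by sampling
noise at 4,000 tows.

```r
fem <- subset(sv$samples, sex == "female" & !is.na(maturity_stage))
fit_maturity_ogive(fem$total_length, binarize_maturity(fem$maturity_stage))
#> Logistic maturity ogive
#>   beta0 = -12.1001, beta1 = 0.2418 (per cm)
#>   L50 = 50.05 cm, L95 = 62.23 cm
#>   n = 1965 (418 mature), 7 iterations

wt <- subset(sv$samples, !is.na(weight))
fit_length_weight(wt$total_length, wt$weight)
#> Allometric length-weight fit: ln W = -5.715 + 3.056 ln TL
#>   a = 0.0033 g cm^-b, r2 (log scale) = 0.980, n = 3794
```

Both fits recover the generating biology (L50 = 50 cm;
ln W = −5.73 + 3.06 ln TL) to within sampling error. The whole pipeline —
simulate/read, validate, niche, ogive, length–weight, diet, envelopes,
abundance, JSON report — runs from one configuration via
`run_pipeline()`, or from a shell via the thin front end in
`inst/cli/trawlniche.R` (subcommands `simulate`, `validate`, `niche`,
`ogive`, `lw`, `diet`, `envelope`, `abundance`, `run`).

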