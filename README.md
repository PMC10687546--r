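# qwanat

Quantitative wood anatomy (QWA) turns images of tree rings into
tracheid-level measurements — lumen areas, wall thicknesses, wall areas —
that carry a far finer ecophysiological signal than ring width alone.
`qwanat` is an R package for the full analysis chain that connects those
cell tables to climate: earlywood/latewood trait chronologies, bootstrapped
monthly climate–growth correlations, drought calendars from the
Standardized Precipitation Evapotranspiration Index (SPEI), normalized
intra-annual trait profiles, Gini inequality of those profiles, and
drought-legacy contrasts between forest types (e.g. pure pine stands versus
pine–oak admixtures).

It is written for dendroecologists and quantitative wood anatomists who
have per-cell output from image-analysis software (one CSV row per
tracheid with a relative ring position) plus ring widths and monthly
climate, and want a tested, scriptable pipeline from raw cells to
statistics.

## The core quantities

Per cell, with lumen area $A$, radial/tangential wall thickness
$t_r, t_t$ and wall area $W$:

- hydraulic diameter $d = 2\sqrt{A/\pi}$, and per ring part the
  hydraulically weighted mean $D_H = \sum d^5 / \sum d^4$;
- cell wall thickness $CWT = (t_r + t_t)/2$;
- anatomical density $AD = W / (W + A) \in [0,1]$;
- Mork's index $m = 4\,t_r / \ell_r$ (radial lumen diameter $\ell_r$):
  a sector is latewood when $m \ge 1$.

Rings are divided into 100 equal-width tangential sectors by relative cell
position; sector-level medians give intra-annual profiles, which are
min–max normalized per ring ($x' = (x - \min x)/(\max x - \min x)$).
Annual per-tree medians are detrended with a cubic smoothing spline whose
frequency response is 50% at a 30-year wavelength (ratio indices),
prewhitened with an AIC-selected autoregressive model, and averaged across
trees with Tukey's biweight robust mean. Chronologies are then correlated
with monthly temperature, precipitation and 6-month SPEI from previous-year
March to current-year October, with case-resampling bootstrap confidence
intervals. Drought years are flagged when 3-month SPEI (log-logistic,
unbiased probability-weighted moments) drops below −1.5 in March–October.
Profile inequality uses the Gini coefficient with percentile and BCa
bootstrap intervals.

A first-class synthetic-data generator (`synthetic_config()`,
`generate_climate()`, `generate_cells()`) emulates the whole study design —
planted drought years, group-specific post-drought wall thickening — so
every stage is testable against known ground truth.

## Worked example

```r
library(qwanat)
library(dplyr)

cfg <- synthetic_config(seed = 7)          # 62 years, 9 + 9 trees
climate <- generate_climate(cfg)
dat <- generate_cells(cfg, climate)

cells <- dat$cells |> classify_cells() |> filter_outlier_cells()
annual <- aggregate_annual(cells, dat$rings)

balance <- climate |> thornthwaite_pet(cfg$latitude) |> water_balance()
flagged <- flag_drought_years(spei(balance, 3))
all(cfg$droughts$year %in% flagged)   # planted droughts are all detected
#> [1] TRUE

profiles <- cells |> build_sector_profiles() |> minmax_normalize()
legacy <- drought_phase_profiles(profiles, cfg$droughts$year,
                                 traits = "AD", seed = 7)
legacy$ks |> filter(pair == "before_vs_after")
```

```
# A tibble: 2 × 8
  group trait pair            d_stat p_value    n1    n2 method
  <chr> <chr> <chr>            <dbl>   <dbl> <int> <int> <chr>
1 mixed AD    before_vs_after 0.0134   0.75   5394  5396 permutation
2 pure  AD    before_vs_after 0.102    0.002  5391  5388 permutation
```

The planted signal — pure-stand pines laying down ~15% denser earlywood
the year after a drought, mixed-stand pines unaffected — is exactly what
the contrast recovers: the pure group's before-vs-after profile
distributions differ (D = 0.10, permutation p = 0.002) while the mixed
group's do not (p = 0.75). `autoplot()` methods draw the phase profiles,
correlation bars and chronologies.

Stand-level context (stem density, basal area, Reineke's Stand Density
Index `SDI = N (D_q/25)^{1.605}`) is available via `quadratic_mean_dbh()`,
`reineke_sdi()` and the bundled two-site plot table `pine_oak_stands()`.

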