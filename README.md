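# spizonal

Zonal disparity analysis of percentage-valued survey health indicators,
for epidemiologists and health-policy analysts working with
factsheet-level data (NFHS-style tables: one row per region — an urban
or rural stratum of a state, e.g. `u_Assam` — one column per indicator).

The pipeline answers: *which administrative zones lag on maternal
healthcare utilisation (MHU), women empowerment (WE) and delivery care
(DC), and are the differences statistically significant?*

## The method

1. **SPI scoring.** Each region gets one score per pillar via a
   Statistical Performance Index style hierarchy. With each indicator
   its own equally weighted dimension (the default),

   SPI.PIL<sub>cp</sub> = Σ<sub>d</sub> ω<sub>pd</sub> · SPI.DIM<sub>cpd</sub> / N<sub>d</sub>,  SPI.DIM<sub>cpd</sub> = Σ<sub>i</sub> SPI.IND<sub>cpdi</sub> / N<sub>I</sub>,

   with missing indicators contributing zero to the numerator and
   excluded from the denominator (the score is the mean of the
   non-missing values; an all-missing pillar is undefined, not zero).
2. **Quantile classification.** Per pillar, regions are binned at the
   25th/50th/75th percentiles into Q1 (poor) … Q4 (excellent); ties go
   to the lower bin, and explicit cutpoints can be supplied.
3. **Favourability.** For zone *z* and pillar *y*:
   Fav(y, z) = 100 · (# regions of *z* in Q3∪Q4) / (# regions of *z*),
   rounded half away from zero to one decimal.
4. **Inference.** Zonal MANOVA (Pillai's trace) plus per-pillar one-way
   F tests — F(5, 65) under the default 71-region, 6-zone layout —
   followed by Bonferroni post-hoc comparisons of all 15 zone pairs per
   pillar on the pooled within-zone mean square, and a region-level OLS
   regression MHU = b·WE + a with R².

A seeded generator (`generate_survey()`) emulates the survey layout
(71 regions in zones C/E/N/NE/S/W of sizes 6/8/17/16/16/8, 22
indicators) so everything runs without any download.

## Worked example

```r
library(spizonal)
cfg <- synthetic_config(seed = 42)
sim <- generate_survey(cfg)
fit <- spi_analysis(sim$table, sim$registry, synthetic_pillar_config(cfg))
print(fit)
```

```
SPI zonal disparity analysis: 71 regions, 3 pillars

Zonal favourability (% of zone regions in Q3/Q4)
 zone n_total n_q34_MHU n_q34_WE n_q34_DC fav_MHU fav_WE fav_DC
    C       6         0        0        0     0.0    0.0    0.0
    E       8         0        0        1     0.0    0.0   12.5
    N      17        11       13        5    64.7   76.5   29.4
   NE      16         0        6        5     0.0   37.5   31.3
    S      16        16       16       16   100.0  100.0  100.0
    W       8         8        0        8   100.0    0.0  100.0

Zonal MANOVA: 71 regions, 6 zones (C, E, N, NE, S, W)
  Pillai's trace = 2.3490, approx F(15, 195) = 46.909, p = 2.422e-56
  MHU: F(5, 65) = 353.898, p = 1.003e-45
  WE: F(5, 65) = 56.551, p = 2.327e-22
  DC: F(5, 65) = 104.200, p = 1.142e-29

Post-hoc: 38 of 45 pairwise comparisons significant at adjusted alpha 0.05

MHU = 0.6296 * WE + 30.4370   (R^2 = 0.114, n = 71 regions)
```

Reading the output: each zone's favourability is the percentage of its
regions in the upper two quantiles for that pillar (the injected
defaults make the South dominate every pillar and the Northeast lag on
MHU despite mid-range WE); the F tests confirm zonal differences on all
pillars; the low R² shows WE alone explains little of the region-level
variation in MHU.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/spizonal.R all --seed 42 --out out/
# out/ now holds registry, indicators, scores, assignments,
# favourability, MANOVA, post-hoc and regression CSVs plus report.md
```

For real data, pass your own `--registry`, `--indicators` and
`--pillar-config` files (formats documented in `?read_region_registry`,
`?read_indicator_table`, `?read_pillar_config`), or call
`external_validation()` on a factsheet-derived table.

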