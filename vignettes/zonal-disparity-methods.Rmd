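---
title: "Methods: SPI scoring, quantile classification and zonal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPI scoring, quantile classification and zonal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spizonal)
```

## The problem

Large household health surveys such as India's National Family Health
Survey publish factsheet tables of percentage-valued indicators for each
*region* — an urban or rural stratum of a state or union territory (for
example `u_Assam`, urban Assam). Policy questions, however, are often
posed at the level of the six administrative *zones* of the Zonal
Council system (Central, East, North, Northeast, South, West): which
zones lag on maternal healthcare utilisation (MHU), women empowerment
(WE) or delivery care (DC), and by how much?

`spizonal` implements that analysis as a tested pipeline: composite
scoring of each region per pillar, classification of regions into four
performance quantiles, a zonal favourability score, multivariate and
univariate analysis of variance across zones with Bonferroni-adjusted
pairwise comparisons, and a region-level regression of MHU on WE.

## The scoring model

Scoring follows a Statistical Performance Index (SPI) style hierarchy
indicator → dimension → pillar. For region $c$, pillar $p$ and dimension
$d$ with $N_I$ indicators,

$$\mathrm{DIM}_{cpd} = \sum_{i=1}^{N_I} \frac{\mathrm{IND}_{cpdi}}{N_I},
\qquad
\mathrm{PIL}_{cp} = \sum_{d=1}^{N_d} \frac{\omega_{pd}\,\mathrm{DIM}_{cpd}}{N_d}.$$

In the default configuration every indicator is its own dimension with
weight $\omega_{pd} = 1$, so the pillar score is simply the unweighted
mean of the pillar's indicators, and `DIM = IND` for each of them.

**Missing values.** A missing indicator contributes zero to the
numerator and is excluded from the denominator — equivalently, the score
is the mean of the non-missing values. A pillar with *every* indicator
missing is flagged undefined (`NA`) and excluded downstream (from
quantiles and from MANOVA via listwise deletion), never coerced to 0:
coercion would conflate "no data" with "worst possible performance".

**Weights.** The unweighted case is the model of record; with general
nonnegative weights the package uses
$\sum \omega d / \sum \omega$ over the *defined* dimensions, which keeps
the unweighted rule as the $\omega \equiv 1$ special case.

**Polarity.** Indicator values are used raw, as percentages on
$[0, 100]$; no normalisation is applied before averaging. For indicators
where a higher value is worse, a per-indicator `inverse` polarity
($x \mapsto 100 - x$) is available in the configuration and is off by
default, because indicator directionality is survey-specific.

## Quantile classification and favourability

Per pillar, regions with defined scores are classified into quartile
bins Q1 (poor) to Q4 (excellent). Unless cutpoints are supplied, the
three cutpoints are the 25th/50th/75th percentiles of the defined
scores, computed with the linear-interpolation convention of
`stats::quantile()` type 7. Ties at a cutpoint go deterministically to
the **lower** bin: Q1 is $s \le c_{25}$, Q4 is $s > c_{75}$.

Published quantile-occupancy shares from comparable analyses are often
not equal across the four bins, and the binning software's exact rule is
rarely stated; rather than reverse-engineer one proprietary convention,
`assign_quantiles()` makes its own convention explicit and accepts
verbatim cutpoints as an escape hatch, so any alternative binning can be
reproduced exactly.

The zonal favourability score for pillar $y$ and zone $z$ is

$$\mathrm{Fav}(y, z) = 100 \times
\frac{\#\{\text{regions of } z \text{ in Q3 or Q4 for } y\}}
     {\#\{\text{regions of } z\}},$$

reported to one decimal with **half-away-from-zero** rounding
(`round_half_up()`), the rule pinned down by published values such as
$5/16 \to 31.3$ and $15/16 \to 93.8$. Regions with undefined pillar
scores count in the denominator (they are regions *in the zone*) but can
never be favourable.

```{r favourability}
counts <- read.csv(system.file("extdata", "zone_quantile_counts.csv",
                               package = "spizonal"))
data.frame(zone = counts$zone,
           fav_MHU = favourability_score(counts$n_q34_MHU, counts$n_total),
           fav_WE  = favourability_score(counts$n_q34_WE,  counts$n_total),
           fav_DC  = favourability_score(counts$n_q34_DC,  counts$n_total))
```

## Zonal inference

`zonal_manova()` stacks the pillar scores into a multivariate response
and tests for zone differences. Regions missing any pillar score are
excluded listwise, since the multivariate test needs complete response
vectors. Pillai's trace is the omnibus statistic — chosen as the most
robust of the classical MANOVA statistics to covariance heterogeneity —
and each pillar additionally gets its one-way between-zones $F$ test
with $df = (\text{zones} - 1,\ \text{regions} - \text{zones})$; with the
default 71-region registry and six zones that is $F(5, 65)$.

`bonferroni_posthoc()` compares all $\binom{k}{2}$ unordered zone pairs
per pillar (15 with six zones). The unadjusted p-value comes from the
two-sided $t$ statistic built on the pooled within-zone mean square of
that pillar's one-way ANOVA, and the Bonferroni family is the set of
pairwise comparisons *within* the pillar: $p_{adj} = \min(1, 15p)$. The
mean difference is reported as *first zone minus second zone*, so a
negative entry means the first zone underperforms. Both conventions
match the layout of standard statistical-package output for this design
and are configurable at the function surface.

`fit_we_mhu_regression()` fits ordinary least squares of the MHU score
on the WE score at **region** level (not zone-aggregated: the region is
the analysis unit throughout), returning intercept, slope, $R^2$ and a
scatter-ready data frame. $R^2$ is computed as the squared sample
correlation, with a constant response defined to give $R^2 = 0$.

## The synthetic-data generator

`generate_survey()` emulates the structure of a factsheet-level survey
export so the whole pipeline is testable without downloads. For region
$r$ in zone $z$ and indicator $j$ of pillar $p$:

$$v_{rj} = \mathrm{clip}\!\left(\mu_{zp} + o_j + \varepsilon_{rj},\ 0,\ 100\right),$$

with a per-indicator offset $o_j \sim N(0, \sigma_I^2)$ drawn once, cell
noise $\varepsilon_{rj} \sim N(0, \sigma_R^2)$, and completely-at-random
missingness at a configurable rate. Defaults, chosen once:

* zone sizes 6/8/17/16/16/8 (C/E/N/NE/S/W), 71 regions in total — the
  zone totals of the published favourability table, consistent with the
  error degrees of freedom (65) of the zonal $F$ tests;
* 22 indicators split 8/7/7 across MHU/WE/DC; the split is arbitrary
  (the authoritative assignment is survey configuration, not package
  code) and fully configurable;
* zone mean levels (`default_zone_means()`) mirroring the qualitative
  zonal ordering of Indian maternal-health data: the South leads on all
  pillars, the Northeast lags on utilisation while ranking high on
  empowerment, the Central zone lags on empowerment;
* $\sigma_I = 5$, $\sigma_R = 8$ percentage points, `missing_rate = 0` —
  spreads typical of between-indicator and between-region variation in
  factsheet percentages, large enough that quantile boundaries are
  exercised and small enough that clipping at the $[0, 100]$ bounds is
  rare (clipping events are counted and returned).

What the generator does **not** emulate: survey sampling design and
weights, within-pillar indicator correlation beyond the shared zone
level (real indicators co-move more), non-random missingness, and
bounded skewness near 0/100. Passing tests therefore demonstrate the
pipeline's correctness and calibration under a clean Gaussian data
model, not robustness to every artefact of real factsheet data.

`recovery_experiment()` runs generate → score → classify → favourability
→ MANOVA → post-hoc over replicates and reports the per-pillar rejection
rate (type-I error under equal zone means, power otherwise), the mean
absolute rank error of the favourability ordering against the injected
zone-mean ordering, and post-hoc true/false positive rates against the
injected pairwise differences.

```{r recovery}
zm <- default_zone_means()
zm[] <- 50; zm["S", ] <- 65
res <- recovery_experiment(synthetic_config(zone_means = zm, seed = 17),
                           n_replicates = 5)
res$rejection_rate
```

## Numerical and design choices

* **Rounding** is half away from zero at reporting precision only
  (1 decimal for percentages, 2 for mean differences, 3 for $F$);
  internal scores keep full double precision. Inputs to the rounding
  routine are pre-rounded at 8 decimals to cancel binary representation
  error before the half-point comparison.
* **Ties** at quantile cutpoints go to the lower bin; with all scores
  identical every region is Q1.
* **Degenerate inputs** are errors, not warnings: empty dimensions,
  all-zero weights, a zone with fewer than two usable regions, zero
  within-zone variance everywhere, zero predictor variance in the
  regression, unresolvable region ids.
* **Region count.** Published accounts of such surveys vary in the
  number of regions analysed; the registry is data, not code, so any
  count works. The default fixture uses 71 because that is what the
  published zone totals sum to and what the reported error degrees of
  freedom imply.
* **Determinism.** All randomness flows through the seed in
  `synthetic_config()`; the generator restores the caller's RNG state.
  Pipeline reruns with identical inputs are byte-identical.
* **Problem sizes in the test suite.** Property tests use tables up to
  10 regions where exhaustive oracles (sort-and-split over permutations)
  are feasible; the null-calibration experiment uses the full 71-region
  layout over 1000 replicates, enough for a binomial 95% band of about
  ±0.014 around the nominal 0.05.

## Limitations

Quantities that depend on the full external survey factsheet — the
published zonal $F$ statistics, post-hoc mean differences, the
regression $R^2$, and national quantile-occupancy shares — cannot be
reproduced from package data. `external_validation()` reruns the entire
pipeline on a user-supplied factsheet-derived table so those numbers can
be compared side by side once the data are obtained.
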