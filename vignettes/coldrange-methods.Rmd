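---
title: "From winter climate to overwintering range and pesticide resistance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From winter climate to overwintering range and pesticide resistance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldrange)
```

## The scientific problem

Many migratory crop pests persist year-round only where winters are mild
enough, recolonising colder regions each season. Where a pest overwinters,
local populations are exposed to the same pesticides year after year, so
resistance alleles can accumulate; where it is only a seasonal visitor, each
spring's immigrants arrive from elsewhere and local selection is reset.
`coldrange` implements the full inference chain connecting these two
observations for a chill-limited insect: a degree-day metric of chronic cold
exposure, an experimentally parameterised winter-survival model, its
projection onto gridded climate to classify the overwintering range under
historical and warming scenarios, and a weighted meta-analysis linking
bioassay resistance ratios to overwintering type.

All stages run against synthetic data generators with known ground truth, so
every claim the package makes is testable offline. The generators emulate
the *designs* of the motivating study system (a diamondback-moth-like pest
of Brassicaceae crops); they do not reproduce any deposited dataset.

## Low-temperature degree-days

The exposure metric is the accumulated deficit of daily mean temperature
below a cold threshold $x_0$:

$$\mathrm{LTDD} = \sum_{j} \max(0,\; x_0 - x_j),$$

with $x_j$ the daily mean on day $j$ and $x_0 = 11.0\,^\circ$C, the
temperature below which larval and pupal survival of the focal pest is
reduced. Days at or above the threshold contribute nothing. Annual
accumulation windows are hemisphere-aware: July 1 through June 30 of the
following year in the northern hemisphere (so the window spans one winter),
and the calendar year in the southern hemisphere. The equator is assigned
the northern window as a deterministic tie-break.

Numerical choices:

* The sum runs over the actual calendar days of the window — 366 in leap
  years — because the physical quantity is a sum over days, not a
  fixed-length vector.
* Up to 2 % of a window's days may be missing from a station record; they
  are filled by linear interpolation between neighbouring observed days
  (nearest-value extension at window edges). More missingness raises a
  coverage error rather than silently extrapolating.
* A growing-season covariate, ETDD, accumulates
  $\max(0, \min(x_j, 33) - 7.4)$ over the calendar year at all latitudes
  (the developmental band of the focal pest). No hemisphere split is applied
  because the calendar year contains the whole growing season in either
  hemisphere.

The companion predictors for model comparison are the window's lowest daily
mean (MinDTmean) and its mean temperature paired with exposure duration
(DTmean + days). The mean is taken over *all* days of the exposure window,
not only sub-threshold days: laboratory winter regimes are almost entirely
sub-threshold, so the two readings differ negligibly there, and the
exposure-days covariate carries duration explicitly.

## The winter-survival model family

Nine candidate models cross the three predictors with three functional
forms (S is the survival proportion, X the predictor):

| form | single predictor | DTmean + days |
|---|---|---|
| linear | $S = a + bX$ | $S = a + b_1 T + b_2 D$ |
| exponential | $S = a e^{bX}$ | $S = a e^{b_1 T + b_2 D}$ |
| sigmoid | $S = a / (1 + e^{-(X-c)/d})$ | $S = a / (1 + e^{-(b_1 T + b_2 D - c)})$ |

For the two-covariate sigmoid the scale parameter is absorbed into
$b_1, b_2$, keeping the form identifiable. Fits minimise least squares on
raw survival proportions (matching the source software's behaviour);
binomial likelihood is deliberately not the selection criterion.
Linear forms are fitted by OLS; nonlinear forms by Levenberg–Marquardt with
five deterministic starts spread over a coarse grid of plausible
coefficients (convergence tolerance $10^{-10}$ on the relative RSS
reduction). The fitter never touches the global RNG, so simulations that
embed fits keep their own random streams.

The plateau parameter $a$ of the nonlinear forms is the asymptotic survival
*proportion* and is constrained to $(0, 1]$. This is not cosmetic: the
exponential is a boundary case of the sigmoid family, and unconstrained
sigmoid fits on exponential data drift to physically impossible plateaus
($a \approx 3$–$6$) purely to mimic the exponential's tail, corrupting AIC
selection. With the constraint in place, data generated from the
exponential-LTDD law select the exponential-LTDD model by AIC in 100 % of
replicates at the laboratory design. The linear form stays unconstrained;
all predictions are clipped to $[0, 1]$ at evaluation time.

Model ranking uses the least-squares AIC $n \ln(\mathrm{RSS}/n) + 2k$ with
$k$ the number of mean-function coefficients; the error-variance term is a
constant offset at fixed $n$ and is omitted because only differences rank
models. Ties break by higher $R^2$, then fewer coefficients. A perfect fit
(RSS = 0) yields a $-\infty$ sentinel.

Coefficient uncertainty is reported by a case bootstrap. Under binomial
noise the residual variance varies with the mean, and the homoscedastic
Wald covariance underestimates the slope's sampling standard deviation by
about 20 % at the laboratory design; resampling observations respects the
heteroscedasticity. For joint statements about $(a, b)$ the package
provides a bootstrap Mahalanobis confidence region
(`boot_confidence_region()`), whose measured joint coverage at the
laboratory design is 0.93 at the nominal 0.95 — two marginal intervals
cannot express a joint claim without overstating it.

Field validation regresses observed field survival on model predictions
computed from climate alone; the result reports slope, intercept, $R^2$ and
bias $|$slope $- 1|$. Field records whose exposure window accumulates no
cold (LTDD = 0) can be excluded — at such warm sites year-round breeding
makes "winter survival" unobservable in the field — mirroring the source
study's exclusion of its warmest sites.

## Range projection

The selected LTDD-driven model is composed with per-cell annual LTDD on a
regular latitude–longitude grid; yearly survival predictions are averaged
over five-year periods. Cells are classified by mean winter survival:
**permanent** ($\ge 5\%$), **marginal** ($[1\%, 5\%)$), **transient**
($< 1\%$); the marginal interval is left-closed so the three classes
partition $[0, 1]$. Cells whose host-plant presence probability falls below
0.3 are **masked**, overriding the climate class — the host grid is an
input product (e.g. a species-distribution-model output); a smooth random
field stands in for it in the synthetic pipeline.

Areas use spherical cos-latitude weighting at cell centres:
$(2\pi R/360)^2 \cos(\mathrm{lat})$ with $R = 6371$ km, i.e. $111.195^2
\cos(\mathrm{lat})$ km² for a 1° cell. This reproduces continental-scale
magnitudes without a projection-library dependency.

Expansion series difference each year's overwintering area (at both the 1 %
and 5 % cutoffs) against a baseline year, with non-overlapping five-year
block means anchored at the baseline. Warming scenarios add a constant
$\Delta T$ to every daily temperature; because every stage of the
composition is monotone, scenario areas are non-decreasing in $\Delta T$, a
property the tests assert. The marginal-belt trend selects the cells
classified marginal in the baseline year, averages their annual LTDD per
year, and fits an OLS line against year; the reported p-value is the
regression F-test, equivalent to the slope's two-sided t-test in this
single-predictor model.

## Resistance meta-analysis

Each bioassay record carries a resistance ratio
$\mathrm{RR} = \mathrm{LC50}_{\mathrm{field}} /
\mathrm{LC50}_{\mathrm{susceptible}}$. The effect size is
$\log \mathrm{RR}$ (natural log), weighted by $w = 1/\sqrt{V}$ where the
pooled variance combines both populations' LC50 uncertainty:

$$V = \frac{\mathrm{SE}_f^2}{n_f\,\mathrm{LC50}_f^2} +
      \frac{\mathrm{SE}_s^2}{n_s\,\mathrm{LC50}_s^2},
  \qquad \mathrm{SE} = \frac{\mathrm{CI_{hi}} - \mathrm{CI_{lo}}}{2 \times 1.96}.$$

Records missing a CI or LC50 receive the arithmetic mean of the complete
entries' variances (prognostic imputation) and are flagged. Zero variances
(zero-width CIs) would give infinite weight; they are floored at the 1st
percentile of the complete positive variances and flagged, keeping the
records without letting them dominate.

Resistance ratios are classified into five levels at the conventional
boundaries: susceptible (RR $\le 1$), low ($1 <$ RR $< 10$), moderate
($10 \le$ RR $< 100$), high ($100 \le$ RR $< 1000$), extreme (RR $\ge
1000$). Group summaries per overwintering type use the weighted mean of
$\log\mathrm{RR}$, exponentiated — a weighted geometric mean of RR, the
back-transform consistent with log-scale effect sizes.

Sites are annotated by the five annual windows labelled with the five years
preceding the sampling year; in the northern hemisphere the last window
ends June 30 of the sampling year, so all annotation climate strictly
precedes a growing-season sample.

The moderator analysis fits, via `lme4::lmer` (REML), the linear mixed
model with wlogRR as response, overwintering type and pesticide variety as
fixed factors, ETDD as covariate (standardised internally; Wald tests are
invariant to this), the two two-way interactions on request, and a random
intercept for the location-by-year combination. Each term is evaluated by a
Type-II Wald $\chi^2$ (`car::Anova`). The three-way interaction is never
fitted: its fixed-effect matrix is rank deficient in designs of this shape.
A fixed-effects-only reduction is available for degenerate designs and for
closed-form verification (a one-df term's Wald $\chi^2$ equals its squared
z).

Calibration, measured at the design scale ($n = 1806$, 200 replicates): the
ow-type Wald test holds its size (type-I error 0.06 at nominal 0.05) when
the generating process matches the model's assumptions, i.e. when weights
are homogeneous across records. Under the fully heterogeneous-weight
generator the same test is mildly anti-conservative (type-I error ~0.10),
because wlogRR $= w \times \log\mathrm{RR}$ makes the residual variance
proportional to $w^2$ while the model assumes a common variance. This is a
robustness limit of the weighted-response construction itself and applies
equally to analyses of real data with this model; users wanting exact size
under heterogeneous weights should treat the ow-type p-value as slightly
liberal. Power for the default injected contrast exceeds 0.9 at design
scale.

The high-resistance map comes from linear quantile regression of
$\log_{10}\mathrm{RR}$ on 5-year LTDD at $\tau = 0.85$ (the top-15 % level).
The fitter minimises the pinball loss directly: an iteratively reweighted
least-squares continuation with shrinking smoothing locates the optimum's
neighbourhood, and an exact vertex polish — enumeration of lines through
pairs of low-residual points, scored by the exact loss — returns the optimal
vertex line (an optimum of a linear quantile fit always passes through two
data points). Tests verify exact agreement with a brute-force all-pairs
oracle at small $n$. The slope's two-sided p-value uses a case-bootstrap
standard error with a $t_{n-2}$ reference. Predicted cell values
(intercept $+$ slope $\times$ LTDD) below-host-threshold cells are zeroed
and excluded from the output map.

Publication bias is checked by Kendall's rank correlation between
$\log\mathrm{RR}$ and the field bioassay sample size, with the funnel table
returned for plotting; the field population's $n$ is used as the study
size.

## The synthetic study design

The generators define the package's study conditions with known truth
(`truth_params()`):

* Survival law $S = 0.9\,e^{-0.005\,\mathrm{LTDD}}$ — a plateau near full
  survival in warm winters and a chronic-chill decay over the 0–1500
  °C·day range the regimes span. These magnitudes mimic the study system
  without claiming to be its fitted values.
* Laboratory design: 10 piecewise-linear 180-day regimes (linear decline,
  hold, linear rise; set points changed every 10 days) spanning winter
  minima from $-12$ to $+8\,^\circ$C; 11 sampling points every 10 days; 55
  larvae and 65 pupae per point; binomial survival; $10 \times 11 \times 2
  = 220$ observations. Field design: 12 sites, 1–4 month exposures, 30
  individuals per cage, two cages per condition, three stages.
* Climate grid: latitudinal gradient ($27 - 0.45|\mathrm{lat}|$ °C annual
  mean), hemisphere-phased seasonal cycle with amplitude growing with
  $|$lat$|$, a linear warming trend (default 0.03 °C/yr) and day noise
  (default 1.5 °C). The default 31 latitude rows over $\pm 45°$ give a
  3-degree spacing — fine enough that the few-degree-wide marginal survival
  belt is populated in both hemispheres. Days cover January 1 of the first
  label year through June 30 after the last, so every hemisphere-aware
  window is covered.
* Resistance records: $\ln \mathrm{RR} = \mu + \text{ow effect} +
  \text{pesticide effect} + \beta_{\mathrm{ETDD}}\,\mathrm{ETDD} +
  b_{\text{site-year}} + \varepsilon$, with overwintering-type log-effects
  $0 / \ln 31.6 / \ln 158$ (transient/marginal/permanent) mirroring the
  order of magnitude of contrasts such an analysis is designed to detect,
  15 pesticide varieties, and per-record sampling variances encoded
  *exactly* into the generated LC50 CIs (the target variance is split
  evenly between the field and susceptible terms, so the
  SE-from-CI/pooled-variance chain recovers it identically). A configurable
  fraction of CIs is blanked to exercise imputation.

What passing tests do and do not show: the generators share the model's
functional forms, have complete station records, no spatial autocorrelation
in the noise, no microhabitat buffering, no snow or precipitation effects,
and no dispersal. Success on them demonstrates the correctness and internal
calibration of the machinery at the stated designs — not that the model is
adequate for any particular real dataset.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full chain remains exercised end to end: grids of $31 \times 4$ or
$15 \times 2$ cells over 9–15 window years, 100 replicates for survival
parameter-recovery, 200 replicates for mixed-model calibration and power at
$n = 1806$ records, and 1000 random series for the degree-day oracle
comparison. These sizes are the package's simulation design; all scale
linearly for larger studies.

## Known limitations

* The LTDD metric ignores sub-daily variation, acute cold extremes
  (supercooling limits), and microhabitat buffering; it is a chronic-chill
  model by construction.
* Least-squares fitting of proportions is the source convention, not the
  most efficient estimator; a binomial GLM would weight observations
  differently (and is deliberately not the selection criterion here).
* The weighted-response mixed model is slightly anti-conservative under
  heterogeneous weights (see calibration above).
* The quantile fitter's polish is exact among vertex lines through its
  candidate set; pathological designs with many near-ties could in
  principle require a larger `n_polish`, and the brute-force oracle is
  available for verification at small n.
* Host masks and class thresholds are configurable but the defaults (0.3;
  5 % / 1 %) are the field's conventions and are treated as fixed by the
  classification contracts.
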