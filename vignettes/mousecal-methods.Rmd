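---
title: "Models and methods behind mousecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mousecal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousecal)
library(dplyr)
```

## The problem

Indirect calorimetry measures a mouse's metabolic rate from open-flow gas
exchange: oxygen consumption (VO~2~) and carbon dioxide production
(VCO~2~) are converted to energy expenditure (EE, kJ/hr). Large
phenotyping efforts run these assays at many institutions, and the
resulting EE values vary for reasons that have nothing to do with
genotype: body mass and composition, housing temperature, locomotor
activity, sex, season, and — after all of those — the institution itself.
`mousecal` implements the analysis chain needed to work with such
multi-site data: derive the standard metrics from raw hourly series,
screen for the data-handling anomalies that multi-site depositions
actually contain, fit wild-type reference regressions, attribute
explained variance to its sources, and express knockout-strain or
intervention phenotypes as residuals from the wild-type expectation in
units of the wild-type residual standard deviation.

Because the interesting properties of the pipeline are statistical
(calibration, power, recovery of known effects), the package ships a
seeded synthetic-cohort generator that plays the role of the consortium
datasets. Every stage is tested against cohorts whose generating
parameters are known.

## Derived quantities

EE is computed with the abbreviated Weir formula,

$$\mathrm{EE} \; [\mathrm{kJ/hr}]
  = 4.184 \cdot \frac{3.941\,\dot V_{O_2} + 1.106\,\dot V_{CO_2}}{1000},$$

with gas rates in mL/hr. The respiratory exchange ratio is
RER = VCO~2~/VO~2~ (about 0.7 for fat oxidation, 1.0 for carbohydrate).
The Lusk form — VO~2~ times an RER-dependent caloric equivalent of
oxygen, linearly interpolated between 4.686 kcal/L at RER 0.707 and
5.047 kcal/L at RER 1.0 — is implemented for formula classification
only. Both expressions are linear in RER and agree at RER 1.0 exactly
(both reduce to 5.047 kcal/L); their maximal relative difference, at
RER 0.707, is under 1%. That closeness is why `classify_ee_formula()`
assigns a site the candidate with the *smaller* median absolute relative
deviation from the reported EE (subject to a 1% ceiling) rather than
asking for a unique match: data generated by one formula match it to
machine precision while the other sits a few tenths of a percent away.
Whatever the classification, the pipeline replaces reported EE with the
Weir recomputation everywhere.

Energy intake is food mass times the diet's energy density
(15.69 kJ/g for the low-fat D12450B, 21.92 kJ/g for the high-fat
D12452); energy balance is intake minus expenditure over the same
period. Locomotor activity is normalised as a percentage of the site's
global maximum hourly beam-break count, because beam geometries differ
between calorimeter manufacturers and raw counts are not comparable
across sites.

### Acclimation and daily averages

Mice behave atypically when first placed in a calorimeter. The
acclimation window runs from the start of recording to the first
lights-on boundary at or after start + 18 h; this resolves the ambiguity
between "first 18 h" and "before the first full photoperiod" in favour
of whichever boundary makes the post-acclimation segment begin with a
complete photoperiod, and the choice is recorded per run. Daily EE (DEE)
and the other daily summaries are means over *complete* 24-h
post-acclimation blocks, with any partial trailing block discarded — a
partial block would overweight one photoperiod. Photoperiod labels use
half-open intervals with the dark start inclusive: lights-off at 18:00
means 18:00 itself is dark and 06:00 is light.

## The synthetic-cohort generator

`generate_cohort()` draws animals and hourly series under the linear
model the analysis assumes. Animal $i$ at site $s$ has true 24-h mean

$$\mu_i = \alpha_s + \beta_s m_i + \gamma_s (T_i - 22)
  + \delta_s a_i + \pi \cdot [\text{male}_i] + \Delta_{g(i)}
  + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2),$$

with $m_i$ body mass (g), $T_i$ ambient temperature (°C, centred at the
22 °C modal nominal housing temperature), $a_i$ activity (% of site
maximum), $\pi$ a male EE shift, and $\Delta_g$ an additive strain
effect. Site slopes $\beta_s$ are drawn uniformly within
1.18–5.32 × 10⁻² kJ/hr/g — the three-fold range observed across real
sites — and $\gamma_s \le 0$: warmer housing lowers EE below
thermoneutrality.

Choices worth knowing about:

* **Residual SD.** The default $\sigma$ = 0.161 kJ/hr adopts the
  reported 1-SD band of wild-type-unexplained strain EE directly as the
  per-animal residual SD. The source figure describes the spread of
  strain-level residuals, and the within-site per-animal SD is not
  published; taking the same number at the animal level is a documented
  convention, chosen because the scoring calibration (a null strain of
  n = 8 should almost never reach the 1-SD band, and a +0.322 kJ/hr
  shift should read as +2 SD) behaves consistently only on this
  interpretation. `wt_residual_sd(scope = "strain")` exposes the
  pseudo-strain alternative, which scales like $\sigma/\sqrt{n}$.
* **Circadian structure.** Hourly EE follows a 24-h-periodic profile —
  a ±30% dark-phase step plus a 5% cosine — whose mean over any complete
  24-h block equals $\mu_i$ *exactly*, so the daily average conserves
  the generating mean to machine precision. Food intake is
  dark-dominant (65% of daily intake) with multiplicative hourly noise;
  beam breaks are dark-dominant integer counts. RER follows a
  photoperiod step (0.95 dark / 0.80 light, a carbohydrate-diet
  pattern).
* **Gas back-solve.** Given hourly EE and RER, VO~2~ and VCO~2~ are
  solved from the two-equation Weir/RER system, so recomputing EE by
  Weir reproduces the generated series exactly — the round-trip closure
  every derivation test relies on.
* **Activity self-consistency.** Activity enters the truth as the same
  site-normalised percentage the analysis later derives: the generator
  simulates beam breaks first, normalises by the realised site maximum,
  and only then computes $\mu_i$. Refits therefore recover $\delta_s$
  without errors-in-covariates attenuation.
* **Energy balance coupling.** Each animal's daily intake is its
  expenditure plus a balance draw ($N(0, 2)$ kJ/day), and its weight
  change over the run is balance times duration over a 32 kJ/g tissue
  energy density, plus measurement noise — enough structure for the
  balance/weight-consistency QC check to have something real to detect.
* **Anomaly injection.** `inject_anomaly()` reproduces documented
  deposition errors at one site: `inverse_mass` reflects each animal's
  EE about the site's mean-mass OLS prediction, negating the *observed*
  marginal EE-vs-mass slope (including the sex–mass confound) while
  preserving the site mean and positivity; `constant_intake` keys every
  hourly food value to exactly 0.05 g; `lusk_ee` swaps reported EE to
  the Lusk computation; `short_run` truncates the site's runs below the
  18-h minimum.

What the generator does **not** emulate: growth over multi-week diet
studies, instrument drift or calibration error, seasonal physiology
(season labels exist but carry no generative effect, matching the null
seasonal result in the reference analyses), inter-animal correlation
within cages (all animals are singly housed), and non-Gaussian residual
tails. Tests passing on these cohorts therefore certify the statistical
machinery, not robustness to every pathology of real data.

## Reference models and variance attribution

`fit_reference()` is ordinary least squares on a declared covariate set,
fitted within a training scope (typically wild-type males, per site or
pooled with a site factor). Covariates a site never recorded are dropped
with a warning rather than imputed — real sites differ in what they
report — and constant factors (e.g. `site` inside a per-site scope) are
dropped the same way. Rank-deficient designs are an error naming the
collinear terms.

ANCOVA follows the standard two-model convention: slope heterogeneity is
the group-by-covariate interaction in the full model; the group effect is
tested in the common-slope model with the covariate entered first.
Per-group slopes, their SEs, and covariate-adjusted means at the grand
covariate mean are reported. Pairwise slope comparisons across sites use
per-site OLS slopes with a Welch-style statistic and Satterthwaite
degrees of freedom; unadjusted and Holm-adjusted p-values are both
emitted, with unadjusted values at α = 0.05 as the primary convention.
Mass-quartile ANCOVA bins animals at 14.00/20.75/27.50/34.25/41.00 g
with right-open intervals (last closed).

**LMG relative importance.** The R² of a fit is decomposed into
per-regressor shares by averaging, over all $p!$ orderings of regressor
entry, the R² increment when each regressor enters. This is computed
exactly via the closed-form subset weighting
$w_S = |S|!\,(p-|S|-1)!/p!$ over all $2^p$ subsets, feasible to
$p = 12$. Categorical covariates enter as single dummy blocks so one
share is reported per factor. Shares sum to the model R² identically
(telescoping), and the test suite checks them against brute-force
enumeration over all orderings to 10⁻¹⁰. Both raw shares (fractions of
response variance) and shares normalised to the explained variance are
emitted, since reported percentages in the field use either convention.

**Institutional share.** The site contribution is measured in two
stages: fit the biological model (no site term), then regress its
residuals on site indicators; the second-stage R² is the fraction of
biologically unexplained variation attributable to site. The alternative
(a site term's LMG share) is available by simply adding `site` to the
importance regressors; the two-stage form is the default because it
matches the "share of *residual* variation" phrasing.

**Sex variance Q-Q.** Each sex's EE SD is estimated as the OLS slope of
ordered sample quantiles on standard normal quantiles; the male/female
slope ratio summarises relative variability (1 = equally variable).

## Phenotype scoring

A strain's phenotype is the mean deviation of its animals' observed DEE
from the wild-type model prediction — the unexplained metabolic effect —
expressed in wild-type residual SD units. Bands are assigned at
inclusive integer thresholds (|SD units| ≥ 1, 2, 3; 3 caps the scale).
Two significance contracts coexist, both emitted because figure-level
practice differs: a one-sample t of per-animal residuals against zero
for cohort-wide scoring, and a Welch two-sample t of strain residuals
against local wild-type residuals for per-site panels
(`site_residual_comparison()`), which also classifies cross-site
concordance over the significant sites (none-significant /
unidirectional / bidirectional). The minimum testable strain size is 4,
the smallest group in the emulated per-site comparisons; smaller strains
are still scored but flagged. Males are scored by default, matching
consortium practice. `score_intervention()` applies the same residual
machinery to any labelled group of animal-periods, including sub-daily
windows such as a 3-h post-dose mean.

## Numerical and procedural choices

* Outlier removal (`remove_outliers()`): a point leaves when its
  deviation from a centred 5-point running median exceeds 4 robust SDs
  (1.4826 × MAD of the deviations over the run), capped at 5% of points
  per run. On smooth or constant runs the median filter reproduces most
  points exactly and that MAD collapses to 0; the rule then falls back
  to a relative threshold (deviation > 25% of the run's median level),
  so constant runs remove nothing while cage-opening spikes are still
  caught. The published pipelines do not print their exact criterion;
  this one is a declared stand-in with every constant exposed.
* Short-run exclusion retains exactly 18.0 h ("shorter than 18 h" is
  excluded; the boundary stays).
* Constant-intake flagging requires more than 50% of a site's animals to
  have zero within-animal intake variance: the documented anomaly was
  site-wide, and individual sensors may legitimately flatline.
* The `Fbxl19` strain is excluded before modelling by default,
  mirroring the emulated curation; the exclusion list is configuration.
* Season is derived from the run start month with the
  Northern-hemisphere meteorological mapping — every emulated site is in
  the Northern hemisphere.
* Timestamps are ISO 8601 with explicit offsets; sampling is assumed
  uniform within a run.
* All randomness flows from a single integer seed; identical
  configuration and seed reproduce every table byte for byte.

## Study conditions behind the quantitative checks

The acceptance-level checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) fix their own problem sizes as the package's
emulated study conditions:

* Parameter recovery uses a 2,000-animal cohort (4 sites × 250 per sex),
  fitting each site separately and comparing every coefficient with its
  generating value in SE units. With ~24 coefficients, the maximum |z|
  occasionally exceeds 3 by pure sampling, so the share of coefficients
  within 3 SE is reported alongside it.
* The institutional-share check injects site intercepts of
  0.55/0.65/0.75/0.85 kJ/hr on otherwise identical sites, implying a
  known site fraction of residual variance, and asks for recovery
  within ±0.05.
* Strain recovery scores 50 strains on a −3…+3 SD grid and 50 null
  strains, n = 8 males each, against a mass + temperature + site
  wild-type model fitted on 240 wild-type males.
* Anomaly round-trips run 20 replicate seeds of a 4-site cohort with the
  site mass slope pinned at 0.0325 kJ/hr/g — the midpoint of the
  observed 1.18–5.32 × 10⁻² range — because the inverse-mass OLS
  detector is genuinely underpowered at slopes near the low extreme
  with 50 animals per site; the fixed mid-range slope is the declared
  condition under which the ≥19/20 detection property is asserted.
* ANCOVA calibration uses a sex contrast at one site with no true sex
  effect (null) or a 0.2 kJ/hr effect (power), n = 8 per group,
  residual SD exactly 0.161 kJ/hr, and a 6 g between-group mass
  difference. The mass divergence is the point: it emulates the
  diet-contrast experiment in which the groups' masses had drifted far
  apart, inflating the SE of the covariate-adjusted group difference —
  a balanced design at these numbers would have ~60% power, while the
  emulated condition is genuinely underpowered (<50%).

## Limitations

The pipeline deliberately fits fixed-effects linear models — the
convention of the analyses it reproduces — rather than hierarchical or
mixed models; site is a fixed factor, and no shrinkage is applied to
strain effects. Basal or resting metabolic rate cannot be derived, since
none of the emulated experiments run at thermoneutrality. The QC layer
flags and recomputes but does not correct upstream data beyond the Weir
recomputation. Everything quantitative said here about performance
(recovery, calibration, detection rates) is computed by the test suite
and the acceptance script on the synthetic cohorts; no claim is made
about the pipeline's behaviour on any particular real deposition.
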