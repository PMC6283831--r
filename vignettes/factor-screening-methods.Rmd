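---
title: "Screening growth-condition factors: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening growth-condition factors: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mieo)
```

## The problem

Bench-scale growth of engineered microbes is notoriously hard to reproduce:
the same strain in nominally "the same" medium can differ several-fold in
biomass and product titer between laboratories, because growth conditions —
medium composition, container geometry and shaking, time, environment,
inoculum — are under-reported and under-controlled. `mieo` implements a
complete workflow for attacking this problem at bench scale (microtiter
plates and shake flasks, batch culture):

1. screen many candidate factors at two levels with orthogonal (fractional)
   factorial designs;
2. rank factor effects with a scale-free statistic, the *relative effect
   magnitude*;
3. check that effects reproduce under changed conditions of use by training
   a linear model on one group of experiments and testing it on another;
4. quantify repeatability and reproducibility over time with centerpoint
   replicates; and
5. report the growth condition of any run as a structured, validated
   minimum-information record (MIEO v0.1).

A seeded synthetic-response generator stands in for wet-lab data so that
every stage of the analysis is exercised and tested end to end.

## Factorial designs and aliasing

Factors are screened at a low (−1) and high (+1) coded level; quantitative
factors additionally carry a center level (coded 0) where one is defined.
`full_factorial()` builds all $2^k$ runs in standard order;
`fractional_factorial()` builds the regular $2^{k-p}$ fraction defined by
$p$ generator words (e.g. `F=ABC`), with design letters A, B, C, …
skipping I. The package ships standard minimum-aberration generators for
the common $(k, p)$ cases; the words actually used are recorded in all
output because the alias structure — which effects are confounded with
which — is part of the result, not an implementation detail. The shipped
$2^{8-3}$ and $2^{9-3}$ entries are resolution IV, so main effects are
unaliased with two-factor interactions.

Two oracles guard the construction in the test suite: the coded matrix $X$
of every factorial experiment must satisfy $X^\top X = nI$ exactly in
integer arithmetic, and for small designs the alias groups derived from
the word algebra must equal the groups found by brute-force comparison of
all column products.

Coded levels are −1/+1 rather than 0/1 so that balance, orthogonality and
the effect contrasts below are exact. One categorical factor needs a
special rule: inoculum age has levels 3 h, 16 h and "16 h + 96 h cold
storage"; the storage treatment is not a numeric midpoint, so the factor
is ordered-categorical with 16 h as the centerpoint reference.

The default campaign plan reconstructs a 256-run, three-group layout:
Group 1 (112 runs) screens factor effects and within-category interactions
in four experiments split by category — media $2^{8-3}$, microwell
containers $2^5$, shake flasks $2^4$, other $2^5$; Group 2 (96 runs)
re-screens the factors split by observed effect size ($2^{9-3}$ large,
$2^{8-3}$ small) to test reproducibility under changed conditions of use
and screen between-category interactions; Group 3 (48 runs) replicates
the centerpoint condition four times on each of 12 days, 7 days in one
month and 5 in another. Which factors belong to the "large" experiment is
stated explicitly in the plan rather than inherited implicitly, so a user
can audit or change the split. Run order is randomized per experiment
under the campaign seed; plate-position randomization is not modelled, as
no positional analysis is attached to it.

```{r}
camp <- build_campaign(seed = 1)
table(camp$group)
```

## Relative effect magnitude

For factor $X_i$ with response $Y$, the relative effect magnitude is

$$\mathrm{REM}_{X_i} =
  \left|\frac{\bar Y_{X_{i+}} - \bar Y_{X_{i-}}}{\bar Y}\right|,$$

and for a factor pair

$$\mathrm{REM}_{X_iX_j} =
  \left|\frac{\bar Y_{X_{i+}X_{j+}} + \bar Y_{X_{i-}X_{j-}}
            - \bar Y_{X_{i+}X_{j-}} - \bar Y_{X_{i-}X_{j+}}}{\bar Y}\right|.$$

Both are dimensionless, invariant to positive rescaling of the response
and to run reordering. Two conventions deserve attention:

* **The interaction contrast is not halved.** The classical interaction
  *effect* divides this four-cell contrast by 2; `rem_interaction()`
  implements the sum-of-cell-means form exactly as defined above, so its
  value is twice the classical effect over the mean. The tests document
  this relation explicitly so users comparing conventions are not
  surprised.
* **Centerpoint runs are excluded** from both the cell means and the
  denominator $\bar Y$: the statistic is a two-level contrast, and
  centerpoints feed the repeatability analysis and curvature diagnostics
  instead.

On an orthogonal design the main-effect REM equals $|2\hat\beta|/\bar Y$
where $\hat\beta$ is the least-squares coefficient on the coded level —
the package computes both routes and the tests require agreement to
1e−10, which pins down sign, scaling and denominator conventions at once.
REMs are computed on raw responses by default; `normalize_responses()`
provides the min–max 0–1 normalization used for visual comparison across
responses.

Effect screening uses normal (or half-normal) probability plots with Blom
plotting positions $(i - 0.375)/(n + 0.25)$; sorting ties are broken by
effect label so coordinates are deterministic.

## The train/test linear model

`fit_response_model()` fits a response on the coded main effects by least
squares; interactions are opt-in, since the screening design's purpose is
to justify a main-effects description (the default term set is declared,
not asserted, to match any particular published fit). Model transfer is
scored with `score_response_model()`, whose default $r^2$ on test data is
$1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the test-set mean. This
form penalizes both miscalibrated spread and bias; the squared-correlation
alternative, which does not, is available via `method = "cor"`. Runs
whose coded cell is `NA` (a factor inapplicable to that container type)
enter the model at the held reference level 0.

## Repeatability and reproducibility

The dispersion statistics follow the metrological definitions:
repeatability is agreement under unchanged conditions, reproducibility is
agreement under changed conditions (here: time). Published dispersion
values in this field are percentages, so both statistics are implemented
as relative SDs:

* `repeatability_cv()` — each day's sample SD over that day's mean,
  averaged across days, ×100. Note that the sample SD at $n = 4$
  replicates is biased low by the normal-theory factor
  $c_4(4) \approx 0.921$; the package reports the plain estimator and the
  tests account for $c_4$ when checking parameter recovery.
* `reproducibility_cv()` — by default the SD of all observations pooled
  across months over the grand mean, ×100. Whether a published
  "reproducibility SD" pools all runs or contrasts month summaries is
  ambiguous in general, so the gauge-style between-month
  variance-component alternative is also computed and the choice is
  logged in `rr_report()`.
* `month_variance_fraction()` — one-way ANOVA $\eta^2$ (between-month sum
  of squares over total), ×100.

### Variance homogeneity

Day-to-day homogeneity of spread is tested with the Brown–Forsythe
statistic: the one-way ANOVA F on absolute deviations from day medians,
chosen for robustness to non-normality. At the centerpoint replicate
structure — 12 days of only 4 replicates — the classical F reference for
this statistic is measurably anticonservative (about 6% type-I error at
$\alpha = 0.05$ in the package's own null simulations), so the default
p-value is a permutation null: observations are centred at their day
medians (removing day location shifts), reassigned to days at random
`B = 999` times, and the statistic recomputed each time. This reference
is exact under exchangeability, and the test suite verifies its type-I
error at $\alpha = 0.05$ over 1000 null simulations. The classical F
p-value remains available (`p_method = "F"`) and is cross-checked against
an independent implementation in the tests. Detecting a genuinely
inhomogeneous day at these small replicate counts has limited power: a
10× spread inflation on one day is flagged at $p < 0.01$ in only about
two-thirds of simulated campaigns at 4 replicates/day, rising above 95%
by 8 replicates/day — worth knowing when sizing a replication study.

## Media formulation

Phosphate buffers are composed by simultaneously solving the
Henderson–Hasselbalch equation
$\mathrm{pH} = \mathrm{p}K_a + \log_{10}([A^-]/[HA])$ and the capacity
equation $C = [A^-] + [HA]$ for the conjugate base and acid, with
$\mathrm{p}K_a = 6.86$ for the second phosphate proton. The
Terrific-Broth centerpoint masses (2.28 g/L KH₂PO₄, 12.7 g/L K₂HPO₄) give
pH 7.50 and 90 mM capacity; note that the 0.17/0.72 mol L⁻¹ phosphate
amounts sometimes quoted for TB are tenfold larger than these masses
imply and are inconsistent with a 90 mM capacity — the package treats the
gram values as canonical. The computed pH is the buffer-only pH; adding
the remaining components is known to depress measured pH by 0.3–0.5
units, which is not modelled because no quantitative relation is
available.

Osmolality sums per-component contributions assuming complete
dissociation of defined salts (KH₂PO₄ → 2 particles, K₂HPO₄ → 3, NaCl
→ 2, MgSO₄ → 2, glycerol → 1) plus an empirical coefficient of 6 mmol/kg
per g/L for the undefined mixtures yeast extract and tryptone. Dilute
aqueous solutions are assumed throughout, so mmol/L and mmol/kg are used
interchangeably. Sodium chloride additions to hit an osmolality target
are solved in closed form.

```{r}
osmolality(tb_centerpoint_recipe())
buffer_from_masses(2.28, 12.7)
```

## Assay calibration

Raw plate signals become responses through linear calibration curves.
Curves are fitted through the origin by default — blank subtraction
removes the offset, and replicate calibrations performed months apart are
combined by averaging slopes — with an intercept fit available for
diagnostics. Lycopene titer is the mean of the two single-wavelength
estimates (475 and 507 nm) scaled by the dilution factor; dry cell mass
is OD700 × slope × dilution. The standard dilution chain (250 µL + 1 mL;
then 40 µL into 160 µL) multiplies to a factor of 25, but the factor is a
per-assay configurable, not a constant, because extraction protocols
change it. Negative blank-subtracted signals are clamped to zero with a
warning (physical non-negativity). Absorbance at 600 nm, where lycopene
does not absorb, flags contamination; the threshold defaults to 3× the
blank-well SD, the standard limit-of-detection convention, and flagged
runs are marked, never dropped. Yield is titer over dry cell mass and is
reported missing where dry cell mass is zero. Fluorescent-protein titers
stay in arbitrary units; no absolute calibration is attempted.

The generator's `simulate_raw_plate()` inverts this chain exactly in the
noise-free case, and the tests require the round trip
responses → raw plate → responses to be the identity to 1e−9.

## The synthetic-response generator

`simulate_responses()` generates, for each run,

$$Y = \Bigl(\mu + \textstyle\sum_i \beta_i x_i
      + \sum_{ij} \beta_{ij} x_i x_j + d + m\Bigr)(1 + \varepsilon),$$

with coded levels $x$, day and month random effects $d, m \sim N(0,
\sigma^2)$ drawn once per label, and $\varepsilon \sim N(0, CV)$. Noise
is multiplicative because dispersion in this setting is reported and
observed as percentages; day/month effects are additive on the response
scale; responses are floored at 0.1 units to keep biomass positive; and
yield is always derived as titer / dry cell mass, never generated.

The defaults are fixed study conditions, not tuning knobs: baselines of
8 g/L dry cell mass and 8.5 mg/L titer with coefficient sets that span
roughly 4–12 g/L and 1–16 mg/L over the screening campaign; the largest
coefficients on container factors and glycerol, with a well-volume ×
shake-speed interaction as the largest single interaction (the
qualitative pattern this generator emulates, not a quantitative claim);
within-day CVs of 3.5% (dry cell mass) and 7.2% (titer); and day/month
effect SDs (0.27/0.06 g/L and 0.72/0.21 mg/L) sized so that centerpoint
replicates show pooled two-month CVs near 5% and 11% with a small
percentage of variance attributable to month.

What the generator deliberately does not emulate: mechanistic growth
kinetics (no Monod/logistic saturation), oxygen-transfer physics behind
the container effects, plate-position spatial effects, non-Gaussian
outliers, and contamination events. Passing parameter-recovery tests
therefore shows that the estimators are correct for data with this
covariance structure — it does not validate the biological model of any
real campaign.

## MIEO v0.1 records

A record holds up to nine category blocks — Media components, Media
properties, Container geometry, Container shaking, Time, Environment,
Selective agents, Inoculum, Inducers — of factor/value/units/detail
levels. Six categories are required; Media properties, Selective agents
and Inducers are optional (derivable or not always applicable).
`validate_record()` reports problems rather than raising: missing
required categories and malformed levels are errors, absent optional
categories and empty level lists are warnings (a category with an empty
level list is treated as present-but-unreported, which seems closer to
author intent than an error). An Inducers block may carry the single
literal level "None".

Two serializations cover the standard's two intended modalities: a
human-oriented tabular dialect (CSV with header
`category,factor,value,units,detail`) and a machine-oriented
hierarchical dialect (XML, one element per category, one child per
factor with `value`/`units`/`detail` attributes). Output ordering is
canonical (categories in standard order, factors in insertion order) so
serialization is deterministic, and both dialects round-trip losslessly.
Values and units are free text compared by string equality — a unit
ontology is out of scope, since real records mix units, percentages and
lot numbers. The shipped reference record (`centerpoint_mieo_record()`)
reports the full centerpoint growth condition in 29 levels across all
nine categories. `record_from_design_row()` re-expresses any design run
as a record, merging the run's natural levels with the static context
levels a design does not vary.

## Problem sizes in the test suite

The package's statistical checks run at sizes chosen to give stable
Monte-Carlo verdicts while keeping the default suite quick: REM/least-
squares equivalence on five fixture designs (16–32 runs) × 3 seeds;
parameter recovery of main-effect REMs over 200 seeds of the 32-run
microwell experiment; repeatability/reproducibility recovery over 200
simulated centerpoint campaigns (plus a 10× replicate-count convergence
check); homogeneity-test calibration over 1000 null draws with B = 199
permutations; and the effect screen over 200 seeds. These sizes are the
package's declared verification conditions; rerunning with more seeds
tightens the Monte-Carlo tolerances but does not change any default.

## Known limitations

* Only two-level (plus centerpoint) regular fractions are constructed:
  no response-surface designs, blocking, Plackett–Burman or
  optimal-design search.
* Buffer chemistry ignores activity coefficients, temperature dependence
  of pKa and multi-pKa treatment; osmolality assumes ideal complete
  dissociation.
* The reproducibility analysis uses fixed month labels, not a full
  crossed gauge study; no REML variance components or control charting.
* Validation of MIEO records is structural, not semantic: it cannot know
  whether a reported value is plausible.
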