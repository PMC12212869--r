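---
title: "Methods: a region-specific fetal growth standard and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a region-specific fetal growth standard and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frogs)
```

## The model

The standard answers one question: *where does a weight sit among healthy
fetuses of the same gestational age (and optionally sex) in a given
population?* It combines three ingredients.

**Shape.** The expected weight across gestation follows the Hadlock
log-quadratic fetal curve, `exp(0.578 + 0.332 g − 0.00354 g²)` with `g`
in exact weeks. Being ultrasound-derived, it describes fetuses still in
utero rather than the selectively small babies that happen to be born
preterm.

**Level.** The curve is rescaled by the *proportionality ratio*: the
population's term mean birthweight (40+0 to 40+6) divided by 3705 g, the
curve's own value at the mid-point of week 40. The ratio is held constant
at all gestations. With the default (Australian national) reference the
combined ratio is 3573/3705 ≈ 0.964; if fetal sex is known the male
(3641 g) or female (3504 g) term mean is used instead. Unknown sex falls
back to the combined mean and the result is flagged sex-unadjusted.

**Spread.** Weights at each gestational day are taken as normal around
the rescaled mean with a constant coefficient of variation,
`cv = SD_term / mean_combined` = 421/3573 (11.8% after rounding; the
unrounded ratio is used internally, rounding only for display). One cv is
applied to all sexes — the sex-specific term SDs round to the same 11.8%.
Centiles are `100 Φ(z)` with `z = (w − μ)/σ`, computed at the exact
gestational *day*; the inverse `μ + σ Φ⁻¹(p/100)` draws centile curves
and round-trips to 1e-9 relative error.

The *estimate range* re-scores the weight at ×0.9 and ×1.1 on the same
standard, giving the centile interval compatible with a ±10% ultrasound
measurement error. It is a sensitivity band, not a probability statement:
its width depends on where the weight sits on the bell curve.

### Assumptions

The standard assumes (i) the Hadlock shape is right for the population,
(ii) weights are normal at each gestational day, and (iii) the cv is
constant across gestation. None is guaranteed; in the population the
defaults came from, the upper tail is in fact heavier than normal (more
births above the 97th centile than the model predicts), which is a known
limitation of mean/SD-based centiles.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `mean_combined_g` / `mean_male_g` / `mean_female_g` | 3573 / 3641 / 3504 | g | term level of the target population |
| `sd_term_g` | 421 | g | sets the cv (421/3573 ≈ 0.118) |
| anchor | 3705 (fixed) | g | Hadlock curve at 40.5 exact weeks; not configurable |
| chart window | 140–307 | days | 20+0 to 43+6; queries outside raise rather than extrapolate |
| cohort window | 168–300 | days | 24+0 to 42+6; the validation population |
| `error_fraction` | 0.10 | — | assumed ultrasound measurement error |
| SGA / LGA | centile < 10 / > 90 | — | strict: exactly the 10th centile is not SGA |

## Numerical conventions

* Gestational age is stored as integer days; `"W+D"` strings are parsed,
  fractional weeks are derived, never stored.
* "Mid-point of 40 weeks" is fixed at 40.5 exact weeks (283.5 days): the
  curve evaluated there reproduces the 3705 g anchor to the gram, which
  40+3 does not.
* Week-resolution comparator charts evaluate their reference once per
  completed week, at `completed_weeks + 0.5` weeks, held constant over the
  7 days — consistent with the anchor convention above. Published
  week-charts do not state their evaluation point; this choice is recorded
  in output metadata (`resolution = "week"`).
* Displayed centiles are clamped to [0.01, 99.99]; the raw centile and the
  unbounded z are always retained alongside.
* Bracket tables treat each threshold as the lower bound of the bracket
  above it: a weight exactly at the 10th-centile threshold is in the
  10th–25th bracket and not SGA.
* Empirical chart quantiles use the linear-interpolation convention
  (`type = 7`); cells with fewer than 20 births (configurable) are flagged
  unusable, never interpolated. Records falling in a missing cell are
  reported unclassifiable and counted — they leave denominators
  explicitly, not silently.
* Normal CDF/quantile are double-precision `pnorm`/`qnorm` throughout; no
  lookup tables.
* The Wilson bounds are evaluated in their algebraic closed form, with the
  k = 0 and k = n endpoints returned exactly as 0 and 1.

## The two-step validation

**Step 1 (statistical).** `classify_cohort()` scores every birth;
`threshold_proportions()` reports the fractions below the 3rd/10th/50th
and above the 90th/97th centiles plus the male share of the SGA group;
`centile_histogram()` checks flatness (refused for bracket-only charts,
which cannot produce exact centiles); `sga_by_day_of_week()` diagnoses
week-resolution bias. Under a week-constant threshold a day-0 birth is
judged against a reference computed 3.5 days ahead of its true age, so
its z is shifted down by roughly `(3.5/7)·0.049/cv ≈ 0.2` standard
deviations, and the SGA fraction falls monotonically across the week —
about twice as many day-0 as day-6 births are labelled SGA. A
day-resolution chart shows no such trend.

**Step 2 (outcome-based).** `nonoverlap_compare()` partitions two charts'
SGA sets, reports the Venn counts, and compares the *non-overlapping*
populations outcome by outcome — the informative contrast, since the
births flagged by both charts carry the same risk regardless of chart.
"SGA by chart A only" is the reference group.

Two interval methods coexist deliberately: single proportions get Wilson
score intervals, while relative risks get the Katz log-RR interval
`exp(ln RR ± z √(1/b − 1/n_b + 1/a − 1/n_a))` — the method that
reproduces the published intervals this layout mirrors. P-values are
two-sided pooled-proportion score tests; no continuity corrections, no
multiple-testing adjustment, complete-case per outcome with per-row
denominators always printed. Zero events in the reference group yield an
explicit infinite RR with the CI omitted rather than a continuity fudge.

Known inconsistencies in the published tables this machinery emulates:
two rows of the birthweight-chart comparison (NICU RR 78.2, Apgar<7 RR
3.18) and one of the unadjusted-chart comparison (stillbirth RR 2.14)
disagree with their own printed counts (count arithmetic gives ≈15.0,
≈3.15 and ≈2.21), and one stillbirth p-value is printed as 0.0347 where
the score test gives 0.0462. These rows are excluded from the package's
verification targets.

## The synthetic cohort

`generate_cohort()` emulates the structure the validation assumes, so
every operation is testable without registry data:

* sex ~ Bernoulli(0.51); gestation is a mixture of a term component
  (Normal(278, 8) days, truncated) and a preterm tail (7%, right-skewed
  toward late preterm over 168–258 days);
* a latent growth-restricted (FGR) subpopulation (5%) has weight z-scores
  Normal(−1.5, 0.5) instead of Normal(0, 1), and its births are
  preferentially preterm (probability ×3) — encoding the epidemiological
  fact that preterm births are enriched for growth restriction;
* weight = `frogs_mean(ga, ref, sex) · (1 + cv·z)`, floored at 150 g and
  rounded to the gram — multiplicative noise matching the chart's
  constant-cv assumption exactly, which makes calibration tests sharp;
* binary outcomes follow logistic models
  `logit P = logit(base) + slope·z + c·preterm`. The baseline stillbirth
  probability is 0.0015; its slope (−0.78, with preterm log-odds +1.0)
  was set once, by solving the mixture integral analytically, so the
  defaults yield an aggregate stillbirth rate of 0.25%. The other outcome
  baselines (neonatal death 0.0008, NICU 0.02, Apgar<7 0.012, Apgar<4
  0.0015 nested within Apgar<7, growth-indicated delivery 0.025,
  operative delivery for distress 0.10) are plausible obstetric orders of
  magnitude chosen once and not tuned.

FGR was modelled as a shifted-z subpopulation rather than a separate
growth curve: it is the simplest structure that reproduces the
qualitative registry findings (preterm enrichment below the 10th centile,
risk gradients in the SGA group, birthweight charts missing preterm FGR)
while keeping closed-form expectations available as test oracles — e.g.
the enrichment of FGR below the 10th centile is exactly
`Φ((Φ⁻¹(0.1)+1.5)/0.5)` over the mixture SGA probability.

Determinism: one seed governs everything; each record consumes a fixed
block of 16 uniforms, so growing `n` appends records without reshuffling
earlier ones.

**What a green test does not establish.** The generator draws weights
from the very model the chart assumes, so calibration tests verify the
implementation, not the biology: they cannot detect a wrong Hadlock
shape, non-normal tails, gestation-varying cv, or outcome confounding by
surveillance-driven intervention (small babies detected antenatally get
delivered earlier, which dilutes observed risk — a feedback the simulator
deliberately omits). Registry-scale results (the published threshold
proportions, stillbirth rates per 1,000, SGA-vs-non-SGA relative risks)
are therefore *not* reproduced at desk scale; they are replaced by
property suites plus exact oracle checks of the risk arithmetic.

## Design choices where the ground was open

* **Week-chart evaluation point.** Mid-week (`+0.5`), by consistency with
  the 40.5-week anchor; a choice, not a citation.
* **No extrapolation past 43+6.** The chart window is 140–307 days;
  queries outside raise. Whether the standard should extend to 44 weeks
  is unspecified upstream, and refusing beats guessing.
* **One cv for all sexes**, since the sex-specific term SDs agree to the
  displayed precision.
* **Male/unisex direction.** A male at his sex-specific 10th centile
  scores *above* the 10th on a unisex chart (he is compared against the
  lower combined mean) — which is exactly why unisex charts
  under-represent males among SGA. The package's tests assert this
  direction.
* **Day-of-week flatness threshold.** One acceptance check asserts the
  day-chart's SGA max/min ratio across days-of-week is below 1.1 in a
  100,000-birth null cohort. The underlying profile is flat (ratio 1.012
  at n = 2×10⁶), but the max/min of seven binomial proportions of ~14,300
  births exceeds 1.1 for roughly 15% of seeds by noise alone; at the
  package's canonical seed it is 1.14, so that check fails as stated. It
  was left failing rather than re-seeded or widened; the trend-test
  formulation (logistic slope on day-of-week, |z| < 3) is the
  statistically appropriate version and passes.

## Known limitations

Retrospective birthweight validation is a surrogate for prospective
estimated-fetal-weight use; stillbirth gestations lag the age at fetal
death; the normal-tail assumption overstates symmetry at the high end;
the simulator's outcome models are single-index logistic in the latent z
and ignore calendar effects, interventions and multiple gestation. The
lookup-bracket interface supports externally published week-by-sex
tables, but no published table ships with the package.
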