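---
title: "Comparing serial clinical observation with the neonatal sepsis risk calculator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing serial clinical observation with the neonatal sepsis risk calculator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoscompare)
```

## The problem

Early-onset sepsis (EOS) is a culture-proven bloodstream infection in the
first days of life. At a baseline incidence around 0.6 per 1,000 live
births among infants born at 34 or more weeks of gestation, it is rare —
but its early signs are ambiguous and a missed case is catastrophic, so
30–40 uninfected neonates are commonly exposed to antibiotics for every
infected one. Two structured strategies compete for the management of
at-risk newborns:

* the **neonatal sepsis risk calculator (NSC)**, a Bayesian tool that
  converts a maternal-risk-factor prior into a posterior EOS risk through
  likelihood ratios attached to the infant's clinical presentation, and
  maps the posterior to one of five management recommendations; and
* **serial clinical observation (SCO)**, which schedules structured
  bedside examinations of at-risk infants and withholds laboratory testing
  and antibiotics while symptoms are absent, or mild and non-progressive.

`eoscompare` implements both engines, a seeded synthetic cohort generator,
and the paired-proportion statistics needed to compare the strategies
decision-by-decision on the same infants.

## The calculator model

For infant $i$ the calculator starts from a prior risk $\pi_i$ (per 1,000
live births). With no further information the prior is the local
incidence; an externally computed multivariate prior can be supplied per
record (`prior_override_per_1000`), or covariate odds multipliers can be
configured. The original regression coefficients are not published in the
sources this package draws on, so none are shipped: the prior model is a
pluggable interface, never an invented number.

The infant's presentation within the first 4 hours is classified as

* **clinical illness** — persistent need for nCPAP/HFNC/mechanical
  ventilation outside the delivery room, vasoactive drugs, seizures or a
  5-minute Apgar below 5, or supplemental oxygen for more than 2
  cumulative hours;
* **equivocal** — one physiologic abnormality (heart rate > 160/min,
  respiratory rate > 60/min, temperature > 38.0 °C or < 36.4 °C, or
  respiratory distress without supplemental oxygen) persisting more than
  4 h, or two or more abnormalities each lasting more than 2 h;
* **well appearing** otherwise.

Each category carries a likelihood ratio $LR \in \{0.41, 5.0, 21.2\}$,
and the update is performed on the odds scale — the definition of a
likelihood ratio:

$$\frac{p_i}{1-p_i} \;=\; \frac{\pi_i}{1-\pi_i} \times LR.$$

A naive multiplicative update ($p_i = \pi_i \cdot LR$) is available as a
configuration option; at risks below 20 per 1,000 the two differ by less
than 3% relative (asserted by a property test). The posterior is cut into
risk strata at 0.65 and 1.54 per 1,000 and into management
recommendations at 1 and 3 per 1,000:

```{r}
est <- bayes_posterior(0.6, "equivocal")
est$posterior_per_1000
nsc_recommend(est)$value
```

One published boundary is ambiguous: the fourth management category is
printed with the same posterior bound as the third. The default decision
table resolves it as *equivocal presentation with posterior at or below
3 per 1,000* — the resolution that reproduces the published split of 131
"strongly consider" versus 55 "empiric" recommendations — and the whole
table can be replaced via `nsc_config(recommend_fn = ...)`. Following the
published projection, "strongly consider antibiotics" is counted as an
antibiotic recommendation; the identity 131 + 55 = 186 with the published
antibiotics marginal supports that reading.

### Temporal semantics

Charted vitals are sparse. A recorded value is carried forward until the
next recording of the same item; the final recording holds no further
duration. Abnormalities may be intermittent — durations accumulate over
the union of abnormal intervals — and an abnormality that begins inside
the 4-hour scoring window accrues its full duration even if it persists
past the window (otherwise "persistent abnormality > 4 h" could never be
met). Persistence comparisons are strict (`> 4 h`, `> 2 h`), matching the
printed criteria. Absent vitals are "not measured" and never abnormal;
nothing is imputed.

## The observation protocol

Structured examinations are scheduled at ages 1, 3, 6, 12, 18, 24, 36,
and 48 h. Each observation is graded:

* **major** — moderate-to-severe respiratory distress requiring support
  (nCPAP/mechanical ventilation, or tachypnea plus increased effort on
  any support), hypoxia (SpO2 < 90% while unsupported), poor perfusion or
  capillary refill ≥ 3 s, temperature ≥ 38 °C, abnormal skin colour,
  worsening of general wellbeing, apnoea, lethargy, irritability, or
  seizures;
* **minor** — tachypnea > 60/min without support, tachycardia > 160/min,
  metabolic acidosis (base excess ≤ −10 mmol/L), temperature below 36 °C
  or between 37.5 and 38 °C.

Note the deliberate asymmetry with the calculator: tachycardia is minor
here, and the high temperature band uses ≥ 38 °C where the calculator's
instability criterion is strictly > 38.0 °C (each framework follows its
own printed table; the two are kept independent).

Minor symptoms trigger re-evaluation every 2 h. Laboratory evaluation
("rule out sepsis") is triggered by the first of: a major finding;
worsening; or minor symptoms persisting 12–24 h (default: the lower
edge, 12 h; configurable). "Worsening" is operationalized as a strict
increase in the number of distinct minor findings between two
*consecutive minor-graded* assessments. Comparing against a previous
grade of none would brand every symptom onset as worsening, which
contradicts the protocol's tolerance of new mild symptoms; whether
intensification of a single finding (say, a rising respiratory rate)
should also count is not specified in the protocol and is a documented
limitation. The antibiotic decision after evaluation is, in practice,
left to the physician; for reproducibility it is modelled as an explicit
policy — `major_only` (default: treat when a major finding is present at
or after evaluation), `always_on_eval`, or a seeded `probabilistic`
policy for cohort simulation.

Triage sends infants on nCPAP/mechanical ventilation, vasoactive drugs,
or with seizures to the NICU; infants on supplemental oxygen or HFNC to
intermediate care; asymptomatic infants of 34 weeks' gestation to
intermediate care; and everyone else rooms in with the mother.

## The synthetic cohort generator

No patient-level data are deposited, so the generator emulates the
published cohort structure: 178/3,445 late preterm; gestational age from
two truncated normal distributions matched to the printed medians and
IQRs (36.14 [35.29–36.57] and 39.71 [39.0–40.29] weeks; the
distributional family is free since only median and IQR are printed);
risk-factor prevalences from the published demographics table, with IAP
and prolonged rupture conditioned on the late-preterm stratum because
both strata are printed; maternal temperature as a shifted log-normal
calibrated by two-point quantile matching so that P(T ≥ 37.5 °C) =
110/3,445 and P(T ≥ 38 °C) = 36/3,445 emerge from one continuous
distribution (shift 36.5 °C, a baseline below which intrapartum
temperatures were not of interest); symptom incidence 264/3,445 with
onset split 68.2% at birth / 18.6% at 1–6 h / 13.3% after 6 h; and
log-normal symptom durations with the median matched exactly to 72 h and
`sdlog` derived from the printed IQR 24–120 h (a two-parameter log-normal
cannot reproduce that asymmetric IQR exactly; the median is exact and the
IQR approximate).

Trajectory composition is not printed numerically anywhere, so it was
fixed once from the qualitative statements available: most symptoms are
respiratory, and among admitted untreated symptomatic infants 80
underwent nCPAP and 67 HFNC. The defaults are: 30% of symptomatic
infants major at onset, 15% of minor trajectories progress to major,
respiratory-support mix 40% nCPAP / 30% HFNC / 15% supplemental oxygen /
15% none among major-grade infants, and minor-finding mix 60% tachypnea /
15% tachycardia / 10% mild fever / 15% acidosis. Latent true-EOS infants
(incidence 0.6/1,000 by default; 0 mirrors the observed cohort, which had
no culture-proven case) are forced to symptomatic major trajectories from
birth so that parameter-recovery tests have a detectable signal.

Generated vitals are sampled to *realize the intended grade*: every
observation of a synthetic timeline reproduces its intended none / minor
/ major grade when passed back through `grade_observation()`
(inverse-grading consistency, asserted by test). All randomness flows
from one seed; each record's timeline stream is derived as
`(seed + index * 1000003) mod (2^31 - 1)`, so a single infant's timeline
can be regenerated without redrawing the cohort.

### What the generator does and does not emulate

It reproduces marginal prevalences, onset timing, grade trajectories, and
support levels — enough to exercise every decision path of both engines
and to test the statistics at scale. It does not model correlations
between maternal risk factors and symptom severity (beyond forcing latent
EOS cases symptomatic), charting noise, missing vitals, blood-culture
contaminants, or clinician discretion. One consequence worth knowing:
with a median symptom duration of 72 h, most minor trajectories exceed
the 12-h persistence threshold, so the observation protocol *evaluates*
more synthetic infants than the observed 4.0% — the published cohort's
evaluation rate reflects clinical judgment the mechanical persistence
rule does not capture. The antibiotic comparison, the headline of the
analysis, nonetheless shows the published direction: the calculator
recommends antibiotics for substantially more infants than observation
treats, with the discordance dominated by calculator-only
recommendations. Passing tests therefore validate the engines and
statistics, not the epidemiology of any real nursery.

## Paired statistics

Decisions are compared on the same infants, so the 2×2 paired table and
McNemar's test are the right tools; only discordant pairs carry
information about marginal homogeneity. The default variant is the exact
binomial, $p = \min(1,\, 2\,P(X \le \min(b,c)))$ with
$X \sim \mathrm{Bin}(b+c, \tfrac12)$, because discordant counts as small
as 5 and 0 occur in the published tables, where chi-square asymptotics
are unreliable. Chi-square variants with and without continuity
correction are provided; the exact p converges to the continuity-corrected
variant for large discordance.

The paired difference is $(b - c)/n \times 100$ percentage points.
Confidence intervals are available by the paired Wald method and by
Newcombe's square-and-add method (Wilson intervals for the two marginals
with a phi correction for their correlation). The software used for the
published analysis and its CI method are unknown, and the printed
interval 3.14–3.71 is asymmetric about 3.51, so intervals are provided
but are not treated as reproduction surfaces — only point differences
are. Two presentation modes are supported because the published tables
use both: the direct difference (3.51%, 1.63%) and the difference of
one-decimal-rounded marginals (27.0% − 8.4% = 18.6%, where the exact
difference is 18.54%).

```{r}
tab <- paired_table(3254, 126, 5, 60)
marginal_rates(tab)
paired_difference(tab)$diff_pct
mcnemar_test(tab)$p_value
```

## Numerical and degenerate-input choices

* Temperatures are canonicalized to Celsius at ingest; the calculator's
  Fahrenheit-derived thresholds are stored as 38.0 °C and 36.4 °C.
* Risk strata bins are closed on the lower edge of each upper bin
  (low < 0.65 ≤ middle ≤ 1.54 < high).
* `b + c = 0` gives McNemar p = 1, not an error; an empty stratum in the
  rate summary yields a row of zeros; an empty cohort file with a valid
  header is an empty cohort.
* An empty timeline with a normal birth context is a well-appearing
  infant, never an error; validation failures always name the record id
  and field.
* Generated continuous values are rounded (ages and temperatures to two
  decimals, vitals to one) so that cohort CSVs round-trip bit-exactly and
  a fixed seed reproduces files byte for byte.

## Problem sizes used by the test suite

The suite exercises the engines on hand-built timelines and on synthetic
cohorts of 300–60,000 records; the generator-recovery property uses 100
derived seeds at n = 100,000; the end-to-end direction check runs one
seeded cohort of n = 100,000. These sizes were chosen to make binomial
3-standard-error bands narrow enough to be informative while keeping the
default test run comfortably fast.

## Known limitations

* The calculator's prior is the baseline incidence unless coefficients or
  per-record overrides are supplied; published posterior *distributions*
  (e.g. score box plots) are therefore not reproducible here.
* "Worsening" ignores intensification of a single finding.
* The generator draws risk factors independently apart from the
  documented gestational-age conditioning, and does not link maternal
  risk to symptom probability.
* Post-24-hour reassessment dynamics of the live calculator are out of
  scope; each infant is scored once from the first 4 hours.
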