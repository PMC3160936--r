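---
title: "Standardized hierarchical cause-of-death assignment from verbal autopsy data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized hierarchical cause-of-death assignment from verbal autopsy data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hierva)
```

## The problem

In settings without routine medical certification of deaths, verbal autopsy
(VA) — a structured interview with the caregiver about the signs and
symptoms that preceded a child's death — is the main source of
cause-of-death information. Expert-algorithm VA interpretation encodes each
candidate cause as a boolean *case definition* over the reported symptoms,
and resolves competing diagnoses with a *hierarchy*: causes are checked in
tiers, and the first tier in which a definition fires determines the
assigned cause. When several survey waves are analyzed together — for
example, repeated Demographic and Health Survey (DHS) VA modules spanning a
decade — comparability requires one standardized algorithm applied to the
symptom set collected in *every* wave, rather than each wave's original
algorithm applied to its own richer questionnaire.

hierva implements that pipeline end to end: record I/O and multi-wave
harmonization, a declarative rule engine, the tiered assignment hierarchy
with a simultaneous measles/ARI/diarrhea tier, comorbidity redistribution,
survey-weighted cause-specific mortality fractions (CSMFs) and rates
(CSMRs), a stratified clustered bootstrap for uncertainty, and a synthetic
DHS-style population generator with known cause structure.

## The model and its assumptions

**Records.** One row per deceased child under 5: age at death in completed
days (0–1825), a sampling weight, design stratum and primary sampling unit
(PSU) identifiers, a survey-wave label, and yes/no/missing symptom
indicators named by codebook codes. Neonates are deaths at 0–27 completed
days; 28–1825 days is the 1–59-month group. This day-boundary convention is
the standard demographic one; inputs recorded in months should be converted
at 1 month = 30.44 days before import.

**Missing answers are negative evidence.** A case definition can only fire
on an explicit "yes". "Don't know" and absent answers behave as "no"
everywhere, including inside at-least-*k* counts and under negation
(`va_not(va_sym(x))` is satisfied when x is "no" *or* missing). The
rationale: a hierarchical expert algorithm requires positive evidence, and
records too incomplete to fire any rule fall through to the `unspecified`
residual rather than being guessed at. This is a documented design choice;
algorithms that model missingness probabilistically (InterVA-style) are out
of scope.

**Harmonization.** `harmonize_waves()` drops every symptom column whose
codebook entry is not available in all waves present in the data. The
codebook guarantees that exactly five serious-infection signs (stopped
suckling, difficult breathing, chest indrawing, convulsions, fever) survive
for any combination of the default waves; signs asked in later waves only —
stiff neck, rapid breathing, lethargy and the like — are discarded so that a
wave with a richer instrument cannot systematically absorb more deaths into
the possible-serious-infection category. The operation is idempotent.

**Case definitions.** Each definition is an age gate (age group, optionally
a narrower day window) plus a boolean expression tree with AND/OR/NOT and
at-least-*k*-of-a-set nodes over symptom codes. Two rules are fixed by the
standardized algorithm itself:

* *neonatal tetanus*: death at 4–14 days with convulsions, where the baby
  cried normally after birth but stopped crying, or suckled normally but
  stopped suckling (or both). A stricter later-wave variant additionally
  requiring the stopping to begin at least one day before the final illness
  is available (`default_definitions(tetanus_2004 = TRUE)`) but off by
  default, because only the laxer rule can be applied to every wave.
* *other possible serious infection*: two or more of the five common
  serious-infection signs.

The remaining shipped rules (measles as ≥3-day generalized rash with fever
at 120+ days; pneumonia as cough with chest indrawing or difficult
breathing, with a neonatal variant; diarrhea as frequent loose stools;
birth asphyxia as no cry/no breath at birth with death in the first week;
prematurity/LBW as born early or very small; malnutrition as visible
wasting or limb/face swelling; the weaker "possible" pneumonia/diarrhea
patterns) are editable defaults drawn from common VA practice. They are
*not* a reproduction of any particular study's exact wording — the engine's
correctness is independent of rule content, and every rule can be replaced
through a YAML definitions file without touching code.

**Hierarchy.** The shipped standardized order is: (1) neonatal tetanus,
(2) injury, (3) measles/ARI/diarrhea assigned *simultaneously*, (4)
congenital abnormality, (5) birth asphyxia/birth injury, (6) possible
pneumonia / possible diarrhea, (7) prematurity/LBW, (8) other possible
serious infections, (9) malnutrition, (10) unspecified. Prematurity/LBW is
deliberately ranked above the residual serious-infection category; tier
placement is the single most influential analytic choice in this class of
algorithm, and the package treats the order as versioned, editable config.
Age gating lives inside the definitions, so one hierarchy serves both age
groups. In the simultaneous tier any two or all three of measles, ARI and
diarrhea may fire together, producing the intermediate categories
`measles_with_ari_or_diarrhea` and `ari_and_diarrhea`; a co-firing
possible-pneumonia/possible-diarrhea pair is held as
`possible_ari_and_diarrhea`. Tie-breaks inside an exclusive tier use a
fixed canonical cause order, so assignment is invariant to how causes are
listed within a tier.

**Multi-cause sensitivity mode.** `assign_multicause()` returns every
firing cause with no hierarchy; `resolve_multicause()` reapplies the tier
order to such a set. Composing the two reproduces `assign_causes()`
exactly — a property asserted in the test suite over simulated populations.
The weighted share of deaths whose multi-cause set has at most one member
(`fraction_hierarchy_insensitive()`) bounds how much any hierarchy
reordering can matter.

**Redistribution.** Reporting uses final causes only. Within each wave ×
age-group cell, `finalize_causes()` merges measles-with-ARI/diarrhea into
measles, splits comorbid ARI-and-diarrhea mass between pneumonia and
diarrhea in proportion to their single-cause weighted masses
(`split_comorbid()`), applies the same split to the comorbid possible pair,
and folds possible pneumonia/diarrhea into the confirmed causes. Total
weighted mass is conserved to floating tolerance. Two degenerate-input
choices are deliberate: when both single-cause masses are zero the comorbid
mass splits equally (conservation must hold and the proportional rule is
undefined), and redistribution operates per age group within wave (the
pooled alternative is a one-line change on the mass table). The
"treat ARI+diarrhea as pneumonia" alternative sometimes argued for on
clinical grounds is not the default and can be had by editing the mass
table before finalization. The share of finalized pneumonia/diarrhea mass
that arrived via the possible categories is retained as provenance
(`possible_share()`), since among neonates that share is known to be large
and affects interpretation.

**Estimation.** CSMF: weighted share of deaths in the denominator group
(`under5`, `neonatal`, `1-59m`); fractions over all under-5 deaths sum to 1
per wave after finalization. CSMR = CSMF × U5MR per 1,000 live births, with
the external U5MR/NMR series supplied as a small table; survey-period rates
are the arithmetic midpoint of the two calendar years
(`interpolate_u5mr()`). Presentation rounding is half-away-from-zero to
integers at ≥1 per 1,000 and to one decimal below 1.

## Uncertainty

Deaths cluster within PSUs, so the bootstrap resamples PSUs with
replacement within design strata, keeping stratum PSU counts and original
weights (no weight rescaling — the plain within-stratum cluster bootstrap).
Strata contributing only one PSU of deaths cannot be resampled alone and
are pooled into a single interchangeable stratum. Every replicate reruns
the nonlinear part of the pipeline — mass aggregation, comorbidity
redistribution, fraction estimation; per-record assignment is a pure
function of the record, so computing it once before the loop is exactly
equivalent to recomputing it per replicate. Replicate `b` depends only on
`seed + b`. Uncertainty ranges are plain 2.5–97.5 empirical percentiles
(linear interpolation, no BCa), reported around the full-sample point
estimate.

For CSMR uncertainty, each fraction replicate is multiplied by an
independent U5MR draw. The draw is normal with mean at the point rate and
SD `(hi − lo)/3.92`, truncated at zero — the minimal assumption that
matches a symmetric 95% interval; when bounds are unavailable the rate is
held fixed with a warning. The between-survey two-sample test uses
replicate differences from independently resampled surveys, two-sided
`p = 2·min(P(Δ ≤ 0), P(Δ ≥ 0))` with the add-one correction
`(r+1)/(B+1)`, so the attainable minimum is `2/(B+1)` and p is never 0.
The default B is 1,000.

## The synthetic generator

`synthetic_config()` describes a survey the pipeline can be validated
against: strata of PSUs with Poisson death counts, an oversampled stratum
carrying reduced weights, a neonatal share, age-specific true cause mixes,
and conditionally independent symptom emission given the cause (per-profile
sensitivity, global false-positive rate on age-applicable symptoms) with
three deliberate departures from independence — an ARI×diarrhea comorbidity
mechanism, a "possible-pattern" fraction of pneumonia/diarrhea deaths that
emit only the weaker symptom profile, and a prematurity×serious-infection
comorbidity that gives hierarchy-reordering experiments signal.

Defaults were chosen once to mirror the 2004 Bangladesh DHS VA study and
are not tuned thereafter: 10 strata, 66 PSUs (two single-PSU strata so the
pooling rule is always exercised), Poisson(8.9) deaths per PSU (~590 deaths
≈ the 587 collected in 2004), neonatal share 0.56, cause mixes whose
implied under-5 fractions echo the 2004 pattern, sensitivity 0.9 and
false-positive rate 0.02 as a realistic VA misclassification level,
comorbidity 0.25, possible-pattern shares 0.65 (neonates) and 0.20
(postneonates) matching the observation that most neonatal pneumonia enters
through the less-specific definition, and prematurity–serious-infection
comorbidity 0.30, the level at which demoting prematurity below the
serious-infection residual cuts its fraction by about 30%.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: free-text narratives, interview nonresponse,
recall-quality differences between waves, symptom correlation beyond the
three mechanisms above, and any cause missing from the final category list
(e.g. meningitis or neonatal sepsis as separate entities). Recovery results
on synthetic data validate the *machinery*, not the clinical validity of
any particular rule set.

## Numerical choices

* Percentiles: type-7 (linear interpolation) quantiles.
* Conservation tolerance: redistribution asserts relative 1e-9.
* Rounding: half away from zero (base `round()` rounds half to even, which
  does not match how published rate tables are typically rounded).
* Ties among co-firing causes in one exclusive tier: combination categories
  first, then a fixed canonical cause order — never listing order.
* Degenerate proportional splits fall back to equal halves, with a message.
* Bootstrap replicates with an empty denominator are recorded as missing,
  counted, and excluded from percentiles (they cannot arise when every PSU
  in the plan contributes deaths, which `plan_bootstrap()` guarantees).

## Problem sizes used in validation

The shipped test-suite and acceptance-script runs use: rule-engine oracle
equivalence on 1,000 random record×rule evaluations against an independent
R-expression evaluator; 100 random mass tables for conservation; ~590-death
populations for engine cross-mode identity; a ~5,000-death population for
the pinned CSMF-accuracy regression; ~50,000 deaths for generator
convergence; and null two-wave calibration with B = 500 replicates over 200
simulated survey pairs (B = 400 over 100 pairs in the acceptance script),
sizes at which Monte-Carlo error on a 5% rejection rate is about ±1.5–2
percentage points. Percentile intervals for very rare causes (true
fraction below ~2%, e.g. measles at the 2004 mix) are known to undercover
at these sample sizes; calibration checks therefore read coverage over the
causes with fractions above ~4%.

## Known limitations

* Case-definition content outside the tetanus and serious-infection rules
  is a package default, not a validated clinical standard; users analyzing
  real data should review every rule in the YAML definitions file.
* The exact standardized tier order beyond its documented anchors (tetanus
  first; prematurity above the serious-infection residual; possible
  pneumonia/diarrhea retained as tiers; unspecified last) — in particular
  malnutrition's position — is a flagged, versioned default.
* Uncertainty ranges reflect sampling design and U5MR uncertainty only;
  they do not include misclassification error in the cause-assignment
  rules themselves.
* The two-sample test compares two waves; it is not a trend test across
  three or more.

## A worked synthetic example

```{r example}
cfg <- synthetic_config()
pop <- generate_population(cfg, seed = 42)
rec <- harmonize_waves(pop$records)

fr <- cause_fractions(rec)
head(fr[order(-fr$fraction), ], 4)

boot <- bootstrap_fractions(rec, B = 500, seed = 1)
fraction_ur_table(boot)[1:3, ]

recovery_report(pop$truth, fr)
```
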