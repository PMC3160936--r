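# hierva

Standardized hierarchical cause-of-death assignment from under-5 verbal
autopsy (VA) data, with survey-weighted estimation and clustered-bootstrap
uncertainty.

## What it is for

Where deaths are not medically certified, the cause-of-death evidence for
children under 5 comes from verbal autopsies: structured caregiver
interviews about the signs and symptoms preceding the death. Expert
algorithms interpret these interviews by encoding each candidate cause as
a boolean *case definition* over symptom indicators and resolving
competing diagnoses with a tiered *hierarchy* — the first tier whose
definition fires assigns the cause. Comparing causes of death across
repeated surveys (e.g. DHS VA modules a decade apart) requires one
standardized algorithm restricted to the symptoms collected in *every*
wave.

hierva is for epidemiologists and biostatisticians doing exactly that. It
provides:

* validated delimited-text I/O for VA death records and a YAML symptom
  codebook; multi-wave **harmonization** to the common symptom set
  (`read_va_table()`, `harmonize_waves()`);
* a declarative **rule engine** (AND/OR/NOT, at-least-*k*-of-a-set) with
  shipped, editable standardized definitions, including neonatal tetanus
  (death at 4–14 days with convulsions after initially normal crying or
  suckling that later stopped) and "two or more of the five
  serious-infection signs" (`default_definitions()`, `evaluate()`);
* the tiered **hierarchy engine** with a simultaneous measles/ARI/diarrhea
  tier and a no-hierarchy multi-cause sensitivity mode
  (`assign_causes()`, `assign_multicause()`, `resolve_multicause()`);
* comorbidity **redistribution**: comorbid ARI-and-diarrhea mass split
  between pneumonia and diarrhea proportionally to their single-cause
  masses, possible pneumonia/diarrhea folded into the confirmed causes,
  total weighted mass conserved (`split_comorbid()`, `finalize_causes()`);
* survey-weighted **estimation**: cause-specific mortality fractions
  f_c = Σ w_i·1[cause_i = c] / Σ w_i and rates CSMR_c = f_c × U5MR per
  1,000 live births (`cause_fractions()`, `csmr()`);
* **uncertainty** from a stratified clustered bootstrap that resamples
  PSUs within strata (single-PSU strata pooled), reruns the nonlinear
  pipeline per replicate, and reports 2.5–97.5 percentile ranges;
  U5MR uncertainty propagates into CSMR ranges, and a two-sample
  bootstrap test compares waves (`bootstrap_fractions()`, `csmr_ur()`,
  `two_sample_test()`);
* a **synthetic DHS-style generator** with known cause structure so the
  whole pipeline is testable without restricted microdata
  (`synthetic_config()`, `generate_population()`, `recovery_report()`).

A thin CLI over these functions ships at
`system.file("cli", "hierva-cli.R", package = "hierva")` with
`simulate` / `assign` / `finalize` / `estimate` / `bootstrap` subcommands.

## Worked example

```r
library(hierva)

cfg <- synthetic_config()                      # 2004-style survey, ~590 deaths
pop <- generate_population(cfg, seed = 42)
rec <- harmonize_waves(pop$records)

fr <- cause_fractions(rec)                     # assignment + redistribution
head(fr[order(-fr$fraction), ], 4)
#>    wave denominator                       cause fraction
#> 1  2004      under5                   pneumonia    0.261
#> 11 2004      under5                 unspecified    0.186
#> 7  2004      under5 birth_asphyxia_birth_injury    0.147
#> 8  2004      under5             prematurity_lbw    0.102

boot <- bootstrap_fractions(rec, B = 500, seed = 1)
fraction_ur_table(boot)[1:3, ]
#>       cause  point    lo     hi   B
#> 1 pneumonia 0.2613 0.227 0.2982 500
#> 2  diarrhea 0.0665 0.047 0.0872 500
#> 3   measles 0.0000 0.000 0.0000 500

recovery_report(pop$truth, fr)
#> ...
#> CSMF total-variation error: 0.0923
```

Reading the output: pneumonia is assigned to 26.1% of (weighted) under-5
deaths with a 95% uncertainty range of 22.7–29.8% from 500 PSU-resampling
replicates; the generator's true pneumonia share in this draw is 31.0%,
and the pipeline recovers the full 11-cause fraction vector to a total
variation distance of 0.092 under the default misclassification noise
(sensitivity 0.9, false-positive rate 0.02). With a noiseless emission
model the recovery is exact — that invariant is part of the test suite.

Multiplying fractions by an external under-5 mortality rate series gives
mortality rates per 1,000 live births:

```r
rates <- read_u5mr_series(system.file("extdata", "igme_u5mr.csv",
                                      package = "hierva"))
f <- data.frame(wave = "2004", cause = "pneumonia", fraction = 0.33)
csmr(f, rates)
#>   wave     cause rate rate_reported
#> 1 2004 pneumonia 23.1            23
```

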