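# doacaudit

Medication-safety audit pipeline for direct-acting oral anticoagulant
(DOAC) prescribing in primary care. From event-level records — patients,
coded observations, prescriptions, diagnoses — it builds monthly cohorts of
adults on a DOAC, extracts weight and renal-function parameters within a
12-month lookback, classifies each prescribed regimen against the
creatinine-clearance (CrCl)–banded recommended dose for atrial fibrillation
(AF), and reports monthly proportion measures and between-month change
summaries. A seeded synthetic-EHR generator makes the whole pipeline
testable without access to real records.

It is aimed at prescribing-safety and medicines-optimisation analysts:
DOACs are renally excreted fixed-dose drugs, so the prescribed dose must
track the patient's CrCl (Cockcroft–Gault), *not* the routinely reported
eGFR. The audit quantifies, per month: how many DOAC patients have a recent
weight / creatinine / eGFR / CrCl on record, and — among AF patients with a
recorded CrCl — how many receive the recommended dose, a higher dose
(overdose) or a lower dose (underdose).

## The core pieces

* **Dose rules** (`doac_dose_rules()`, `classify_dose()`): the CrCl-banded
  recommended regimens — apixaban 5 mg BID ≥30 / 2.5 mg BID 15–29;
  dabigatran 110 or 150 mg BID in 30–50 and >50; edoxaban 60 mg OD >50 /
  30 mg OD 15–50; rivaroxaban 20 mg OD ≥50 / 15 mg OD 15–49. All DOACs are
  contraindicated below 15 ml/min. Classification compares daily dose
  (strength × frequency) to the recommended envelope; wrong-frequency
  regimens, CrCl < 15 and dabigatran below 30 are flagged separately and
  kept out of the match/over/under denominators.
* **Cockcroft–Gault** (`cockcroft_gault()`):
  `(140 − age) × weight / (72 × SCr[mg/dL])`, ×0.85 if female, with
  µmol/L conversion (÷88.4) and actual / ideal (Devine) / adjusted weight
  policies.
* **Cohort + measures** (`build_cohort()`, `measure_series()`,
  `characteristics_table()`, `change_summary()`): monthly inclusion,
  365-day lookback extraction, ever-recorded AF flag, and reports in which
  every percentage carries its numerator and denominator.
* **Synthetic data** (`synthetic_config()`, `generate_synthetic_ehr()`):
  deterministic, with configurable age/sex structure, recording
  probabilities, AF prevalence and match/overdose/underdose mix — sampled
  category-first so the classifier's expected output equals the configured
  mix.

## Worked example

```r
library(doacaudit)

# classify three prescriptions against the recorded CrCl
classify_dose(drug  = c("edoxaban", "apixaban", "rivaroxaban"),
              strength_mg = c(60, 2.5, 20), frequency_per_day = c(1, 2, 1),
              crcl = c(40, 80, 75))
#> [1] "overdose"  "underdose" "match"

# Cockcroft-Gault: 80-year-old, 70 kg, serum creatinine 1.0 mg/dL
cockcroft_gault(80, 70, c("male", "female"), 1.0)
#> [1] 58.33333 49.58333

# end to end on synthetic data
cfg <- synthetic_config(seed = 42, n_patients = 5000, study_start = "2022-03",
                        study_end = "2023-02", doac_prevalence = 1)
d  <- generate_synthetic_ehr(cfg)
co <- build_monthly_cohort(d, "2023-02")
dose_outcome_summary(co)
#> # A tibble: 7 x 4
#>   category      n denominator percent
#>   <chr>     <int>       <int>   <dbl>
#> 1 match      2319        2675    86.7
#> 2 overdose     73        2675     2.7
#> 3 underdose   283        2675    10.6
#> # i 4 more rows
```

The denominator (2675) is the number of cohort patients with AF, a CrCl
recorded in the past 12 months, and a classifiable regimen; the percentages
are the recommended / overdose / underdose split over exactly that group.
Contraindicated (CrCl < 15) and non-standard regimens are counted in the
remaining rows without diluting the split. `characteristics_table(co,
"2023-02")` gives the full monthly block (sex, age bands, weight bands,
recording rates, AF∧CrCl under both denominator conventions), and
`audit_report()` compares two months.

A thin command-line wrapper is installed at `inst/cli/doacaudit.R`
(`generate` / `run` / `report` subcommands over the same functions).

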