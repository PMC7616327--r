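---
title: "Auditing DOAC dose appropriateness against renal function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DOAC dose appropriateness against renal function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doacaudit)
```

## The problem

Direct-acting oral anticoagulants (DOACs) — apixaban, dabigatran, edoxaban
and rivaroxaban — are fixed-dose drugs whose dose must be reduced when renal
function declines, because they are substantially renally excreted and
overdosing raises bleeding risk while underdosing leaves patients
under-anticoagulated. The renal measure mandated for DOAC dose selection is
creatinine clearance (CrCl, ml/min) estimated by Cockcroft–Gault, not the
eGFR that laboratories report routinely (eGFR can overestimate renal
function for dosing purposes). A prescribing-safety audit therefore asks,
month by month across a primary-care population: who is on a DOAC, do they
have a recent weight / creatinine / eGFR / CrCl on record, and — for
patients anticoagulated for atrial fibrillation (AF) with a recorded CrCl —
does the prescribed regimen match the recommended regimen for their CrCl
band?

`doacaudit` implements that audit as a tested pipeline over event-level
records in four delimited tables (patients, observations, prescriptions,
diagnoses), with a seeded synthetic-data generator standing in for real
records, which are inaccessible by design.

## The dose rules and the classifier

The rule table (`doac_dose_rules()`) has one row per drug × CrCl band ×
recommended regimen. The source table prints integer band edges
("15–49", "≥50", ">50") without continuous-value semantics; we fix the
inclusivities so every drug's band union is gapless:

* apixaban: 2.5 mg BID on [15, 30), 5 mg BID on [30, ∞)
* dabigatran: 110 mg and 150 mg BID, each on [30, 50] and (50, ∞)
* edoxaban: 30 mg OD on [15, 50], 60 mg OD on (50, ∞)
* rivaroxaban: 15 mg OD on [15, 50), 20 mg OD on [50, ∞)

No DOAC has a recommended dose below 15 ml/min, and dabigatran has none
below 30 ml/min. The table as published lists both dabigatran strengths in
both bands, so both count as a match in either band; product licensing is
more nuanced, but the audit follows the rule table it encodes. Alternative
tables can be swapped in as CSV (`read_dose_rules()`), and
`validate_dose_rules()` refuses tables whose bands leave coverage gaps.

`classify_dose()` compares the prescribed regimen to the recommended set at
the recorded CrCl. Membership in the set is a `match`; otherwise the
*daily* dose (strength × frequency) is compared with the recommended
daily-dose envelope, so a wrong-frequency regimen can never be mistaken for
a match — non-standard frequencies get their own category and are excluded
from the match/over/under denominators, as are CrCl < 15
(`contraindicated_crcl_below_15`, surfaced as a safety count) and
dabigatran below 30 (`no_recommended_dose`). One corner is unreachable with
catalogue strengths but still defined: a standard-frequency regimen whose
daily dose falls strictly between recommended daily doses without matching
any (e.g. a hypothetical dabigatran 130 mg BID) is `unclassifiable`.

The classifier is verified against an independent brute-force scan of a
hand-copied rule table on a grid of every drug × catalogue regimen × CrCl
values 1–200 plus the band edges and their neighbourhoods.

## Cockcroft–Gault and the weight-policy question

$$\mathrm{CrCl} = \frac{(140 - \text{age}) \times \text{weight}}
{72 \times \mathrm{SCr}_{\text{mg/dL}}} \times (0.85 \text{ if female})$$

Serum creatinine in µmol/L is divided by 88.4. National guidance is
unresolved on whether actual, ideal or adjusted body weight belongs in the
formula, and GP-system calculators are inconsistent — this is precisely the
safety concern the audit design responds to. The package therefore treats a
*recorded* CrCl as opaque (it audits what the EHR says, not what the
formula would give) and exposes the calculator separately with all three
policies: `actual` (the default — it is what EHRs record), `ideal` (Devine:
50 kg male / 45.5 kg female + 2.3 kg per inch over 5 ft, floored at the
base weight below 152.4 cm), and `adjusted` (ideal + 0.4 × excess over
ideal, applied only when actual exceeds ideal). `crcl_batch()` records the
policy used in its output so downstream tables are self-describing.

## Cohort construction

A patient is in the cohort for month *m* iff a registration interval covers
day 1 of *m*, their age at day 1 (whole years, floored) is in [18, 120],
they have not died on or before day 1 (death on day 1 excludes —
conservative reading of "not died before the start of the month"), and at
least one DOAC prescription is dated inside *m*. When several prescriptions
fall in one month the latest wins; same-day ties resolve to the last in
file order.

Parameters use a 12-month lookback: the most recent observation dated in
`[month_end − 365 days, month_end]`, both ends inclusive ("past 12 months"
carries no day semantics in audit guidance; we fix one and test the
boundary). AF is an **ever-recorded** flag — AF is a chronic indication, so
a diagnosis any time up to month end counts — while the monitoring
parameters are window-limited. A dose assessment is computed exactly when
AF, a CrCl record and a regimen are all present. Patients with unknown sex
are retained but flagged non-calculable, which reproduces the
non-calculable bucket audit tables report.

## Measures and denominators

Published audit tables mix denominators between adjacent rows (weight-band
rows divide by the weight-recorded count, the CrCl < 15 row by the
CrCl-recorded count, sex rows by the total), and one published AF∧CrCl
percentage reproduces only from the calculable denominator while the other
month's reproduces from the total. `doacaudit` defuses this two ways: every
percentage in every report is accompanied by its numerator and denominator
columns, and the AF∧CrCl row is emitted twice, once per denominator
convention. Change summaries emit the count difference, the
percentage-point difference and the relative count change as three
separately named columns, never a single ambiguous "(%)".

All report percentages are rounded half away from zero at one decimal
(3.7706 → 3.8; base `round()`'s half-even rule would disagree on exact
halves), and only at report time — intermediate values stay at full
precision.

## What the synthetic generator emulates

`generate_synthetic_ehr()` is deterministic given its seed and emulates:

* the age structure of a DOAC population (74% of mass in the 70+ bands by
  default), a 44.5% female split, and a 0.2% unknown-sex fraction;
* per-parameter 12-month recording probabilities (defaults 0.728 weight,
  0.943 creatinine, 0.924 eGFR, 0.735 CrCl). Each patient is, per
  parameter, a "recorder" with the configured probability; a recorder emits
  one observation every 365 days at a random phase anchored to the final
  study month. Because the lookback window spans 366 days and the spacing
  is 365, **every** monthly window contains a record iff the patient is a
  recorder, so the per-window recording probability equals the configured
  value exactly, for every month — which makes recovery tests sharp and
  makes `recording_prob = 1` give fully observed cohorts;
* AF in 74% of DOAC users (diagnosis coded before the study window);
* monthly DOAC prevalence (default ramp 1.15% → 2.10% across the window),
  drawn independently per patient-month;
* recorded CrCl as a lognormal (median 70 ml/min, sdlog 0.66, putting about
  1% of mass below the 15 ml/min contraindication threshold), weight as a
  truncated normal with configurable tail masses below 50 kg and above
  120 kg, and creatinine/eGFR as negatively associated draws;
* the dose mix, category-first: for each AF patient with CrCl ≥ 15 a
  category is drawn from `dose_mix`, then a catalogue regimen the
  classifier maps to that category at the patient's CrCl. Under the rule
  table an overdose is only constructible at CrCl ≤ 50 (no higher strength
  exists above the top band) and an underdose only at CrCl ≥ 30, so
  patients assigned those categories have their CrCl redrawn from the same
  lognormal truncated to the feasible band. That mirrors clinical reality —
  failure to dose-reduce happens in renal impairment — and keeps the
  classifier's expected output exactly equal to `dose_mix` among classified
  patients.

It does **not** emulate: longitudinal disease progression or treatment
switching (drug, regimen and parameter values are constant per patient);
any joint distribution of weight × renal function (parameters are
independent, so the creatinine-but-no-CrCl share is the product of the
marginals rather than a calibrated value); registration churn;
polypharmacy; or an eGFR estimating equation (eGFR is a recorded value
only, by design). Passing recovery tests therefore show the pipeline is
correct and unbiased under these conditions, not that real EHR data would
behave this way.

## Problem sizes and numerical choices

Recovery checks use a 20 000-patient population over a 12-month window with
prevalence 1, so the full population flows through classification and
every configured probability *p* can be tested against the pipeline
estimate at 3 binomial standard errors, `3·sqrt(p(1−p)/n)`; smaller
property tests use 5 000–6 000 patients. The full-window prevalence
trajectory is checked at 20 000 patients over the 62-month default window.
Generation-time labels are kept in a ground-truth table
(`summarize_truth()`); because classification is deterministic in (regimen,
CrCl), pipeline dose-category counts equal the truth counts exactly, not
just in expectation. End-to-end determinism is asserted byte-for-byte on
the written reports.

## Known limitations

* Dual AF+VTE indication dosing is out of scope; such patients would be
  assessed against AF rules only.
* Edoxaban's weight (≤ 60 kg) and interacting-medicine dose criteria are
  not applied; regimens are classified on CrCl alone.
* The recorded-CrCl-is-opaque stance means the audit cannot detect a CrCl
  that was itself computed with an inappropriate weight; the
  `crcl_batch()` policy comparison exists for exactly that sensitivity
  analysis.
* Real SNOMED CT / dm+d codelists are replaced by identity stub codelists;
  mapping real product codes to structured regimens needs a layer this
  package does not provide.
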