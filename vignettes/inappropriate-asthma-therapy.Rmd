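---
title: "Detecting inappropriate asthma therapy in claims data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inappropriate asthma therapy in claims data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Overuse of short-acting β₂-agonist (SABA) relievers and use of long-acting
β₂-agonists (LABA) without inhaled corticosteroid (ICS) cover are
well-documented, potentially dangerous patterns of asthma management.
Claims and primary-care databases record every prescribed or dispensed
pack, so these patterns can be measured at population scale without
clinical chart review. `asthmaclaims` implements a complete pipeline for
doing so: cohort construction from longitudinal medication events,
classification of three inappropriate-use patterns over a 12-month
follow-up, stratified comparisons, and extrapolation of cohort prevalences
to national burden counts.

Real databases of this kind (UK primary-care prescribing records, French
national claims samples) are access-restricted. The package therefore
ships a synthetic claims generator that emulates both database dialects
with known planted truth, so every stage of the pipeline is testable
end-to-end without any data access.

## Data model and terminology

Three tables drive the pipeline:

* `patients` — `patient_id, birth_date, sex` (one row per person);
* `med_events` — `patient_id, date, drug_code, packs` (one row per
  prescribed/dispensed pack-event);
* `dx_events` — `patient_id, date, condition_code, source_kind`
  (diagnoses, long-term-condition flags, hospital-discharge codes).

Drug and condition codes are opaque strings. A miniature terminology maps
them to the therapeutic classes and condition labels the rules operate on;
the pipeline never parses code internals, so any coding system can be
plugged in by supplying a `code, dialect, class_label, human_name` CSV.
The two dialects differ in what they record:

* `PRESCRIPTION_UK_LIKE` — prescription events plus physician diagnosis
  codes (asthma diagnoses are available and required for inclusion);
* `DISPENSATION_FR_LIKE` — dispensation events with no diagnoses; chronic
  conditions appear as long-term-condition flags or hospital-discharge
  codes, and asthma status is inferred from the medication algorithm
  alone.

## Cohort algorithm

**Entry.** A patient enters the cohort at the third distinct calendar date
within the cohort year bearing at least one qualifying respiratory-drug
event (SABA, single-agent LABA, single-agent ICS, fixed-dose ICS+LABA,
leukotriene receptor antagonist, or xanthine). Several qualifying events
on one day count as one date. Requiring three separate dates filters out
one-off prescriptions and makes persistent airway therapy — hence probable
asthma — likely.

**Age.** 6–40 completed years at entry. The lower bound avoids
preschool-wheeze misclassification; the upper bound avoids contamination
by chronic obstructive pulmonary disease (COPD). Strata are children
(6–13) and adults (14–40).

**Exclusions**, evaluated over the 12-month lookback window and in a fixed
order so that each excluded patient gets exactly one reproducible reason:

1. age outside 6–40 at entry;
2. any omalizumab event (marker of severe asthma under specialist care);
3. chronic oral corticosteroid (OCS) use — prescription dialect: ≥ 5
   prescriptions on ≥ 4 distinct dates; dispensation dialect: ≥ 4
   distinct dispensation dates spanning ≥ 2 civil calendar quarters;
4. COPD: a COPD condition code, or any tiotropium/indacaterol event with
   no ICS-containing event in the lookback ("COPD drug alone");
5. cystic fibrosis; 6. lung cancer; 7. bronchiectasis; 8. tuberculosis;
9. sarcoidosis — each via condition codes;
10. less than 12 months of data coverage after entry.

In the prescription dialect an asthma diagnosis code on or before the
entry date is additionally required (checked right after entry-date
finding); the dispensation dialect has no diagnoses, so its inclusion
rests on the medication algorithm.

### Calendar conventions

These conventions are applied uniformly and are worth stating precisely
because several rules live on window boundaries:

* *Month arithmetic.* "12 months after d" is the same day-of-month one
  year later, clamped to month end when that day does not exist
  (`add_months()`).
* *Windows.* Lookback is half-open, `[entry − 12 m, entry)`; follow-up is
  half-open, `[entry, entry + 12 m)`. The entry date itself belongs to
  follow-up: the third qualifying event is exposure, and an exclusion
  drug event on the entry date does not exclude.
* *Age.* Completed years at entry (whole birthdays elapsed); a patient
  whose 6th birthday is the entry date is included, one whose 41st
  birthday is the entry date is not.
* *Quarters.* Civil calendar quarters (Jan–Mar, …, Oct–Dec), the French
  claims convention.
* *Chronic OCS count.* The prescription-dialect threshold "more than 4
  prescriptions" is read strictly as ≥ 5; the inclusive reading (≥ 4) is
  available via `cohort_config(ocs_min_prescriptions_uk = 4)` because the
  printed rule wording is ambiguous between the two.

## The three patterns

Treatment units are prescribed/dispensed *packs*, summed by class over the
follow-up window:

* **SABA overuse** — ≥ 12 SABA packs over the 12-month follow-up
  (roughly one reliever inhaler a month, the canonical overuse
  threshold).
* **LABA without ICS** — ≥ 1 single-agent LABA pack and zero ICS of any
  form (neither single-agent ICS nor fixed-dose combination, FDC).
* **Unbalanced LABA/ICS** — ≥ 1 single-agent ICS pack and a
  LABA-to-single-ICS pack ratio ≥ 2. FDC packs enter neither side of the
  ratio: a combination inhaler cannot deliver LABA without ICS, so it is
  counted as ICS co-therapy, never as LABA exposure.

A design decision was needed for the zero-ICS corner of the ratio rule
(division by zero): a patient with single-agent LABA, no single-agent ICS
and no FDC is assigned to *LABA without ICS*; with FDC present, to
*neither* LABA pattern (ICS co-therapy exists and the ratio is
undefined). This keeps the two LABA patterns mutually exclusive, matching
their separate reporting, and is verified exhaustively over a count grid
in the test suite. ICS *underuse* is deliberately out of scope: without
clinical context it cannot be distinguished from appropriately
intermittent therapy in mild seasonal asthma.

## Statistics

Percentages are compared with Pearson's χ² on the 2×2 flagged/not-flagged
table (df = 1). Continuity correction is off by default — the intended
cohorts have thousands of members, where the correction is immaterial —
but switchable (`correct = TRUE`). The test refuses tables with a zero
margin instead of returning `NaN`. Continuous variables are compared with
the Mann–Whitney U test: midranks, exact p by exhaustive enumeration of
all group labelings when `n₁·n₂ ≤ 64` (ties handled exactly), otherwise
the normal approximation with tie-corrected variance and continuity
correction — the correction keeps the approximation within about 0.01 of
the exact p even at n = 8 per group, which the test suite checks. Tests
are two-sided; no multiple-testing adjustment is applied, matching
standard descriptive drug-utilization reporting, and the significance
threshold used in examples is 0.05. Standard deviations use the n − 1
denominator; the s.d. of a single value is reported missing, never zero.
Report percentages are rounded half-up to one decimal
(`round_half_up()`), the convention of published cohort tables, rather
than R's round-half-to-even.

## Extrapolation

Direct standardisation scales a cohort prevalence to a national burden:

```
count = pattern_prevalence × asthma_prevalence_6_40 × population_6_40
```

National population and asthma prevalence are configuration inputs
(`national_inputs()`) — census and registry figures that must be supplied,
never fetched or hard-coded. Each per-pattern count is rounded to a
configurable granularity (default 10); the total is the exact sum of the
per-pattern counts with no further rounding, which is the only arithmetic
verifiable against published burden tables. When stratum prevalences must
be pooled before extrapolation, `weighted_cohort_prevalence()` takes the
convex combination with the cohort's stratum shares; a single pooled
asthma prevalence is used by default (stratum-specific prevalences can be
extrapolated separately and summed).

## The synthetic generator

`generate_claims()` plants truth *constructively*: instead of sampling
events and hoping rules fire, it decides each patient's fate first (one
exclusion channel or eligible, then a pattern assignment) and writes
events that realise exactly that fate.

* Qualifying events use the leukotriene-antagonist class — respiratory,
  so they qualify for entry, but invisible to all three pattern rules.
* Background noise uses class `OTHER`, invisible to every rule.
* Pattern events are written into the follow-up window to meet (or stay
  below) each threshold; exclusion triggers are written into the lookback
  window of an otherwise-eligible patient, so the planted channel is the
  first rule that fires.

Consequently `build_cohort()` must recover the planted
inclusion/exclusion outcome for *every* patient — an exact identity, not
a statistical one — and the test suite asserts exactly that at n = 2,000,
alongside a binomial-CI check that measured pattern prevalences recover
their planted values. Generation consumes a single seeded RNG stream in a
fixed per-patient order, so one seed gives byte-identical CSV output;
reproducibility is per-seed within this implementation.

Default study conditions: cohort year 2013, 2,000 patients, sex ratio
0.52, age weights giving roughly 27% children among the 6–40 band,
planted prevalences 8.5% SABA overuse, 0.3% LABA-without-ICS, 0.4%
unbalanced LABA/ICS (pooled magnitudes typical of published 2013
figures), per-channel exclusion rates summing to ≈ 0.13, and a data
horizon of 30 June of the following year so a late-entry
insufficient-follow-up channel exists. These sizes keep the full
generate–build–classify cycle at a few seconds while leaving every
exclusion channel populated.

What the generator does *not* emulate: seasonality, adherence dynamics,
prescriber effects, regional coding variation, or calibration to real
database marginals. Green tests therefore demonstrate that the *rules*
are implemented exactly as stated and recover planted truth — they do not
validate the rules' clinical sensitivity/specificity on real data, which
requires the restricted databases themselves.

## Worked example

```{r}
library(asthmaclaims)

cfg <- sim_config(seed = 1, n_patients = 2000)
db <- generate_claims(cfg)

cc <- cohort_config(cfg$dialect, cfg$cohort_year,
                    data_end_date = cfg$data_end_date)
built <- build_cohort(db$patients, db$med_events, db$dx_events, cc)
built$baseline

cl <- classify_cohort(built$cohort, db$med_events,
                      default_terminology(cfg$dialect))
subset(cl$prevalence, stratum == "ALL")

ni <- national_inputs("UK", 2013, population_6_40 = 2.9e7,
                      asthma_prevalence_6_40 = 0.068)
prev <- with(subset(cl$prevalence, stratum == "ALL"),
             setNames(as.list(percent / 100), pattern))
extrapolate_burden(prev, ni)
```

## Known limitations

* Exclusion criteria are scanned in the lookback window only; a COPD
  diagnosis arriving *during* follow-up does not retroactively exclude
  (the rules are defined on the 12 months before entry).
* The unit of exposure is the pack; pack size, dose strength and defined
  daily doses are not modelled, so "12 packs" is a proxy for "12
  canisters" only insofar as one pack holds one canister.
* The terminology shipped is a miniature registry for testing and
  demonstration; real analyses must supply their full coding dictionaries.
* Unfilled prescriptions are invisible in dispensation data and
  unfillable in prescription data; cross-dialect comparisons inherit that
  asymmetry from the sources, not from the pipeline.
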