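---
title: "Estimating avoidable trauma mortality under TXA strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating avoidable trauma mortality under TXA strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txavert)
```

## The model and its assumptions

`txavert` implements a two-source avoidable-mortality calculation. A
TXA-naive cohort of U.S. blunt/penetrating trauma deaths (2007–2012, chosen
because tranexamic acid was essentially unused for trauma in that era) is
identified from aggregated death-certificate strata; the fraction of those
deaths attributable to hemorrhage is taken as a fixed literature-derived
parameter; and counterfactual deaths averted under a TXA strategy are the
product

\[
\text{averted} = \frac{D}{n_\text{years}} \times p_\text{bleed} \times
  f_\text{subgroup} \times \text{RRR},
\]

with the RRR confidence-interval endpoints carried through the same product
to give a range (interval-bound propagation). The core assumptions are
inherited from the study design this emulates: trial RRRs from an
international trauma population transfer to U.S. decedents; every EMS-
transported decedent was potentially salvageable and could have received the
drug under a liberal protocol; and the hemorrhage fraction is constant
across states and strategies. None of these are tested by the package — they
are the stated world the arithmetic lives in.

A second, patient-level source supplies the subgroup fractions for
vitals-gated strategies: among registry decedents (EMS-transported,
blunt/penetrating, age ≥ 16, died in the ED or after admission), the
complete-case fractions with any EMS systolic blood pressure < 90 mmHg
(hypotensive) or additionally any EMS heart rate > 110 bpm
(tachycardic-or-hypotensive). Records with no documented EMS vitals —
roughly half — are assumed missing at random and excluded from the
denominator.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `p_bleed` | 0.25 | fraction | hemorrhage share of blunt/penetrating trauma deaths; literature range 23–39%, low end chosen deliberately so averted-death estimates are conservative |
| `rrr_point/low/high` (within 1 h) | 0.32 / 0.18 / 0.43 | fraction | trial RRR for death due to bleeding, treatment within one hour |
| `rrr_point/low/high` (1–3 h) | 0.21 / 0.03 / 0.36 | fraction | trial RRR for treatment between hours one and three; a surrogate for deferring TXA to the hospital |
| `sbp_threshold` | 90 | mmHg | hypotension cut; strict `<`, any single reading qualifies |
| `hr_threshold` | 110 | bpm | tachycardia cut; strict `>`, any single reading qualifies |
| `n_years` | 6 | years | 2007–2012 study window |
| `denominator` | `"any_vital"` | — | complete-case convention, see below |

Scenario constants live in `inst/extdata/scenarios.json`, not in code, so a
user can re-run the pipeline under different effect sizes without touching
the package.

## Design choices where the design was open

**Mechanism taxonomy.** The source criteria name only the four excluded
mechanisms (drowning, fire/flame, poisoning, suffocation). Which remaining
mechanism categories count as blunt versus penetrating is a taxonomy
decision, so it ships as an editable data file
(`inst/extdata/mechanism_map.csv`) modeled on the CDC external-cause
mechanism categories: cut/pierce and firearm are penetrating; falls,
transport, struck-by and machinery are blunt. An unmapped mechanism is an
error, never a silent drop.

**Age boundary.** "Age > 15" is enforced as "age band entirely ≥ 16". A band
straddling the boundary (e.g. "15–19") raises an error: no proration rule is
stated, and silently prorating would fabricate data. The synthetic exports
therefore use bands that respect the boundary.

**Place of death.** "In a medical facility but not dead on arrival" keeps
the inpatient/ED category only. Facility deaths with unknown status are
excluded by default (the conservative reading) behind a
`include_unknown_facility` flag.

**Suppressed cells.** WONDER-style exports suppress small counts. Suppressed
cells are read as zero with a warning; any other treatment would be a guess.

**Complete-case denominator.** The source text does not say whether the
hypotension and tachycardia proportions share a denominator. The default
(`"any_vital"`) uses one shared denominator — every record with at least one
documented reading of either channel — so the two proportions describe the
same set of visits; a pressure-only record can still classify as hypotensive
and a rate-only record as tachycardic. The stricter `"both_vitals"`
convention is a config switch. The exact denominator behind the published
proportions (11,571 = 18.1%; 26,644 = 40.2%) is not recoverable from the
text, and the package documents rather than resolves that: the two implied
denominators (≈63,900 and ≈66,300) even disagree with each other.

**Death definition.** ED deaths are `ed_disposition == "expired"`; hospital
deaths require `hospital_disposition == "expired"` *and* an ED disposition
of inpatient admission or observation. A patient transferred out of the ED
who later died elsewhere is not a death here — the transfer breaks the
admission chain the definition describes.

**Rounding.** All arithmetic is full precision; only report columns round,
half away from zero (42,609.5 → 42,610). Strategy comparisons difference the
exact points by default; a `use_rounded` mode differences the printed
(rounded) values instead, because published differences of published
rounded numbers (e.g. 2793 = 3409 − 616) are not reachable any other way.

**Uncertainty.** Interval-bound propagation only. A resampling mode is *not*
offered: the emulated analysis used CI endpoints, and pretending a
Monte-Carlo band is "the" method would misrepresent it.

## Numerical notes and known divergences

* The 1–3 h point at full precision is 2236.99875; half-away-from-zero
  reporting gives 2237 (an abstract rounding elsewhere gives 2236 — the
  package reports 2237).
* The within-1 h lower bound computes to 10,652.375 × 0.18 = 1917.43,
  reported 1917; published tables print 1918. The computed value is
  reported and the divergence is listed in `run_metadata.json`'s notes.
* Restricted-scenario points published as 616 and 1371 are not exactly
  recoverable from the one-decimal percentages 18.1%/40.2% (which give
  617.0 and 1370.3). When a `vitals_summary` is supplied, the estimator uses
  exact count/denominator fractions; the rounded percentages are only a
  fallback, and reports flag the distinction.

## What the synthetic generators emulate — and what they don't

`gen_wonder_export()` draws raw certificate records field-by-field from
declared mixtures (jurisdiction by population weight, year, mechanism,
intent, place, age band) and aggregates them into strata, so the export has
the multinomial cell-count structure of a real aggregated query, including
disallowed intents/places, under-16 bands, and a 24% excluded-mechanism
share (the emulated cohort excluded 24.4%). `gen_ntdb_cases()` draws death
records with latent shock classes (18.1% hypotensive, 40.2%
hypotensive-or-tachycardic by default), class-conditional vitals that respect
the 90/110 thresholds with probability 1, and whole-block MAR dropout of EMS
vitals at 50%. One seed drives each generator through per-field sub-seeded
streams, so adding a field never perturbs earlier fields' draws and byte
reproducibility is exact.

Deliberately not modeled: injury-severity correlation (no ISS/AIS), temporal
trends within the window, geographic heterogeneity in case mix or bleeding
fraction, partial per-channel vitals missingness, and any linkage between
the two sources (the emulated analysis uses them independently). A green
test therefore establishes that the *pipeline arithmetic and filters* are
correct under the stated world — not that the stated world is epidemiologically
complete.

An MNAR stressor (`mnar_delta > 0` makes dropout more likely for truly
hypotensive cases) exists to *demonstrate* the complete-case estimator's
bias when missingness is informative — the acknowledged limitation of the
MAR assumption — not to correct it; the test suite shows the estimate falls
many standard errors below truth under MNAR while remaining unbiased under
MAR.

## Degenerate inputs and tie-breaks

Zero complete-case denominators raise an error rather than returning NaN;
`total_deaths = 0` produces a header-only export; empty strata filter to
all-zero totals; boundary vitals readings (exactly 90 mmHg / 110 bpm)
qualify for neither threshold because both inequalities are strict; state
estimates require known jurisdiction codes (50 states + DC) and error on
anything else.

## Limitations

The package reproduces a fixed-ratio counterfactual; it performs no causal
inference, no age standardization, and no trend modeling. Its state
estimates inherit every national-level assumption uniformly (shared
`p_bleed`, shared subgroup fractions), which is what makes the per-state
rows sum exactly to the national row — and also what makes them
illustrative rather than state-specific epidemiology. The per-state EMS
protocol classification is manual review work outside the package; it enters
only as a user-supplied three-category table joined onto the estimates.
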