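---
title: "Methods: costing, triage thresholds and cost-effectiveness for mpMRI in suspected MASLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: costing, triage thresholds and cost-effectiveness for mpMRI in suspected MASLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masldcea)
```

## The problem the package models

Suspected metabolic dysfunction-associated steatotic liver disease (MASLD)
is common, and its progressive form — MASH, especially MASH with fibrosis —
is the state clinicians most need to find. The reference standard, liver
biopsy, is invasive and costly, so non-invasive multiparametric MRI (mpMRI)
metrics are attractive for triage: cT1 (iron-corrected T1 relaxation time,
ms, a marker of fibro-inflammatory disease activity) and PDFF (proton
density fat fraction, %, liver fat).

The package implements the analysis pipeline of a two-arm multi-national
randomised design: standard of care (SoC) versus SoC plus mpMRI (the
imaging arm, IA). It covers four recruiting regions (Ulm, Leiden, Coimbra
and a pooled UK region), healthcare resource-use (HCRU) questionnaires at
2, 6 and 12 months, multi-country unit costing, diagnosis-rate comparison,
biopsy-avoidance evaluation, and an incremental cost-effectiveness analysis
(ICER per diagnosis and per QALY) with willingness-to-pay (WTP) price
inversion for the mpMRI tariff.

Patient-level trial data are not publicly deposited, so the package is
organised around two complementary data sources:

* **packaged published aggregates** — the per-site expenditure components,
  diagnosis counts and the biopsy subgroup, which are sufficient to
  reproduce every self-contained published figure exactly; and
* **a synthetic cohort generator** — patient-level data with the same
  statistical structure, so every stage of the pipeline is exercised
  end-to-end in tests.

## Liver-relatedness mapping

The HCRU questionnaires do not restrict recall to liver-related care. Three
blinded clinicians rate each event on a five-level scale; the inclusive
binary mapping sends *definitely*, *probably* and *possibly liver-related*
to A (liver-related) and the two negative levels to B. The published
methodology states the scale and the mapping but no aggregation rule across
the three raters; the package uses majority vote — the standard
adjudication convention — with a 1–1 split of two raters declared
indeterminate. Unrated events default to A (consistent with the inclusive
philosophy; configurable). Indeterminate events count toward all-cause
totals but are excluded from the liver-related subtotal, and both subtotals
are reported.

## Costing

Unit costs are national tariffs (Germany, Portugal, UK) or local hospital
prices (Leiden), in local currency. Costing proceeds as:

1. **inflate** the nominal tariff to the analysis year in local currency
   (`value * idx_to / idx_from`, ONS health index for the UK, OECD health
   CPI elsewhere);
2. **convert** GBP to EUR at a single rate;
3. **multiply** by each patient's event frequency; no discounting (the
   follow-up is at most 12 months).

Inflation and conversion commute for constant rates; the order is fixed
(inflate first) purely for reproducibility. Full precision is kept
internally; rounding is half-up to 2 dp and only at report rendering.

Two numerical facts about the packaged tables are worth recording:

* The published analysis names "the 2020 exchange rate" without printing
  it. The rate is recoverable from the published aggregate table itself:
  (cohort total − EU site totals) / UK site total equals 1.16700 in *both*
  arms, so the packaged default is `fx_gbp_to_eur = 1.167`.
* Some published cost cells are not exactly nominal-tariff × printed count
  (site-year CPI adjustments are not published). The package therefore
  treats the published *component totals* as the reproduction surface — the
  packaged fixture stores those components and the engine reproduces the
  grand totals (523,968.98 / 331,393.85 EUR) and per-patient means
  (1,300.17 / 830.56 EUR) from them — while nominal×count costing is used
  for synthetic cohorts. Two cells of the Portuguese tariff row could not
  be transcribed unambiguously from the published table; they are assigned
  plausible values and are not load-bearing for any reproduced figure.

Per-patient means always use **all randomised patients** in the group as
denominator, not only resource users (523,968.98 / 403 = 1,300.17
confirms this convention).

## Threshold triage

* **MASH risk**: high if PDFF ≥ 10% *or* cT1 ≥ 800 ms (inclusive), low if
  both present and both below, otherwise unclassified. A missing cT1 with
  PDFF below threshold is unclassified — the decisive value is missing —
  while PDFF at or above threshold is decisive alone. The published
  analysis reports only the count of missing-cT1 patients, so this
  missing-value policy is the package's documented choice.
* **Histological MASH with fibrosis**: MAS ≥ 4 *and* fibrosis stage ≥ 2.
* **Avoidable biopsy**: no MASH with fibrosis *and* cT1 below the 875 ms
  avoidance threshold. The published methods write the rule with a strict
  `<` while the results arithmetic (9 of 10 spared) requires `≤`; the
  package defaults to the inclusive comparison that matches the published
  arithmetic, with `strict = TRUE` available.

The biopsy subgroup fixture encodes the published counts: of 21 biopsied
imaging-arm patients, 2 are excluded for missing data and 1 for autoimmune
hepatitis; of the 18 analyzable, 10 lack MASH with fibrosis (9 with cT1 ≤
875 ms) and 8 have it. The 3-below / 5-above split of the 8
condition-positives is the *unique* split reproducing all four published
operating characteristics (0.9 / 0.63 / 0.75 / 0.83, half-up rounding),
verified by enumerating all nine splits in the tests. Note the published
condition polarity: the test identifies patients *without* MASH with
fibrosis, inverted relative to the usual disease-positive convention; the
package follows that polarity. Percentages are quoted against the
convention denominator 20 (analyzable plus missing-data exclusions) while
the 2×2 uses 18; both denominators are exposed.

## Cost-effectiveness

QALYs are generated through diagnoses: each missed diagnosis costs 0.03
QALY, so the QALY gain is (Δ diagnoses) × 0.03. WTP thresholds default to
EUR 11,200 (conservative, ≈ GBP 10,000) and EUR 22,400 per QALY.

Two per-QALY conventions coexist in `icer()`:

* `icer_per_qaly` — the standard Δcost / ΔQALY;
* `icer_per_qaly_reported` — (Δcost / Δdx) / ΔQALY, the convention under
  which the published headline figure (5067.77 / 1.02 = 4968.40) was
  evidently computed.

The published headline pair is **not derivable from the published counts**:
230 − 193 = 37 additional diagnoses give an ICER per diagnosis of 5,204.73
EUR and 1.11 QALYs, not the published 5,067.77 EUR per 1.02 QALYs (which
imply a denominator of 38). The package never bakes unexplained constants
in silently: the first-principles values are the default, the published
pair is reproduced only under explicit `incremental_dx_override = 38` and
`qalys_gained_override = 1.02`, every result carries its override ledger,
and the replication report prints both with a discrepancy flag. The same
applies to the published mpMRI price ranges (301–1204 and 301–2709 EUR):
no inversion convention reproduces them from published inputs, so
`price_threshold_inversion()` reports the package's own bound — the exact
solution of ICER(price) = WTP, with a 1e-9 round-trip identity tested —
alongside an explicit not-reproducible flag.

Dominance quadrants (negative incremental cost, or no QALY gain with
positive cost) are labelled `dominant` / `dominated` rather than reported
as misleading ratios.

## Between-arm comparisons

Utilisation counts are compared with two-sided Wilcoxon rank-sum tests:
exact enumeration when both samples are ≤ 20 and untied, otherwise the
tie-corrected normal approximation with continuity correction (the two
branches agree within 0.01 in p for mid-sized samples; tested). Diagnosis
rates are compared with a two-sample t-test on the binary indicator
(Welch), with the pooled two-proportion z reported as a cross-check —
degenerate zero-variance inputs are handled explicitly. On the published
counts (230/403 vs 193/399) this gives z ≈ 2.47, p ≈ 0.014; the published
p = 0.0012 is not reproduced by any standard two-sample test on those
counts and is flagged, not corrected. No multiplicity adjustment is applied
(none was specified).

## The synthetic generator: what it emulates, and what it does not

Defaults are the trial's published conditions, chosen once:

* arm/site sizes 107/109, 89/88, 79/75, 128/127 (403 vs 399 total);
* per-site biomarker means/SDs from the published baseline table, modelled
  as independent normals truncated to physiologic ranges (age 18–75, BMI
  16–60, ALT/AST 5–400, cT1 600–1250 ms, PDFF 0.5–45%); the published
  table gives only marginal moments, so independence is the simplest model
  matching them — parameter-recovery tests compare against the
  truncated-normal population mean;
* cT1/PDFF realised only in the imaging arm; cT1 missing at rate 21/403,
  independently of value by default (`fat_dependent` switches to a
  PDFF-proportional mechanism, since the published attribution — artefacts
  or fat outside the quantifiable range — suggests but does not quantify
  one);
* diagnosis rates 0.57 / 0.48; biopsy referral 21/403 and 23/399;
* event counts Poisson per patient-category at the published count / arm
  size, split across the 2/6/12-month windows in proportion to window
  length (non-overlapping reporting intervals, summed, never
  deduplicated); biopsy events follow the referral flag rather than a
  Poisson rate, so biopsy costs and histology always refer to the same
  patients;
* histology of biopsied imaging patients drawn so the joint distribution
  of (MASH-with-fibrosis × cT1 side of 875 ms) matches the published
  subgroup (9/18, 1/18, 3/18, 5/18), conditioning on the patient's own
  simulated cT1; SoC biopsies use the published marginal 11/23;
* three-rater five-level ratings driven by a per-category probability that
  care is truly liver-related and a rater accuracy of 0.9 (the published
  analysis reports no rater-agreement statistics; these are the package's
  own calibration of a plausible panel).

The generator does **not** emulate: correlation between biomarkers,
longitudinal biomarker change, site-level care heterogeneity beyond rates,
MR physics or image artefacts, dropout, or recall bias. Passing tests
therefore demonstrate that the pipeline's arithmetic, rules and interfaces
behave correctly under realistic marginal structure — not that the
generator reproduces real patient-level joint distributions.

## Numerical and testing choices

Determinism: one integer seed fully determines cohort and events (the
event stream uses a fixed offset of the seed so each is reproducible on
its own). Rounding in reports is half-up (base R `round()` is half-even,
which would turn 0.625 into 0.62 and break the published 0.63).
Problem sizes in the test suite were chosen to keep the full suite in a
few seconds while leaving the statistical checks well-powered: parameter
recovery uses 10,000 patients per arm with 3-standard-error bands, the
rank-sum type-I-error check uses 1,000 null simulations at n = 50 per arm,
and exhaustive enumerations (rating multisets, contingency recounts on
cohorts of ≤ 12, the biopsy-split brute force) are complete rather than
sampled.

## Known limitations

* Biopsy-complication and out-of-pocket costs are excluded (as in the
  published analysis); MRI costs cover scan time only.
* CPI indices in the packaged table are identity: the published analysis's
  country-year health indices are not public, so reproduction targets the
  published component totals rather than re-inflated tariffs. Supply a
  unit-cost YAML with real indices to inflate.
* The QALY model is a constant per-diagnosis loss; no Markov disease
  progression, no probabilistic sensitivity analysis beyond price
  inversion, no discounting.
* Percentages involving the biopsy subgroup intentionally expose two
  denominators (18 and 20), mirroring the published convention rather than
  resolving it.
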