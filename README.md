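# masldcea

Trial-based cost-effectiveness and diagnostic-triage analysis for
multiparametric MRI (mpMRI) in suspected metabolic dysfunction-associated
steatotic liver disease (MASLD).

## What it is for

Health economists and hepatology researchers evaluating whether adding
mpMRI (cT1 disease-activity and PDFF liver-fat maps) to standard of care
pays for itself in a two-arm randomised design. The package takes
per-patient healthcare resource-use records through the full analysis
chain:

1. **liver-relatedness mapping** — three blinded clinicians' five-level
   ratings collapsed to a binary A/B classification by majority vote;
2. **multi-country costing** — nominal unit tariffs inflated by health-CPI
   indices, converted GBP→EUR, multiplied by per-patient frequencies, no
   discounting;
3. **threshold triage** — high/low MASH risk (PDFF ≥ 10% or cT1 ≥ 800 ms),
   histological MASH with fibrosis (MAS ≥ 4 and fibrosis ≥ 2), and the
   biopsy-avoidance rule (no MASH with fibrosis and cT1 ≤ 875 ms), with
   2×2 operating characteristics
   (sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), PPV, NPV);
4. **between-arm statistics** — Wilcoxon rank-sum tests for utilisation,
   a two-sample test on the binary diagnosis indicator;
5. **cost-effectiveness** — incremental cost ΔC, QALY gain
   ΔQ = Δdiagnoses × 0.03, ICER = ΔC/ΔQ against willingness-to-pay
   thresholds, and inversion of a WTP threshold into the maximum
   admissible mpMRI price from ICER(p) = (ΔC + n·(p − p₀))/ΔQ.

Because patient-level trial data are not deposited, the package ships (a)
the published aggregate tables as plain-text fixtures, sufficient to
reproduce every self-contained published figure, and (b) a synthetic
cohort generator with the trial's published structure (arm/site sizes,
biomarker moments, event rates, missingness, histology joint
distribution), so the whole pipeline is testable end to end.

## Worked example

```r
library(masldcea)
rep <- replicate_trial_analysis()
print(rep)
```

```
<masld_replication>
                                         imaging        soc
Visits with health care practitioners 272,941.15 270,658.62
Patient assessment                     52,822.70  60,735.23
MRI                                    97,057.07       0.00
mpMRI                                 101,148.06       0.00
Total cost                            523,968.98 331,393.85
Per patient                             1,300.17     830.56
  diagnosis rates: imaging 230/403 (57%), soc 193/399 (48%)
  cT1<=875 rule: sens 0.900 spec 0.625 ppv 0.750 npv 0.833
  avoidable biopsies: 9 (45% of 20)
  first-principles ICER:
<icer_result>
  delta cost: 192575.13 EUR; delta dx: 37; QALYs gained: 1.11
  ICER per diagnosis: 5204.73 EUR
  ...
  published-override ICER:
<icer_result>
  delta cost: 192575.13 EUR; delta dx: 38; QALYs gained: 1.02
  ICER per diagnosis: 5067.77 EUR
  ICER per QALY: 188799.15 EUR (reported convention: 4968.40)
  overrides: incremental_dx_override = 38; qalys_gained_override = 1.02
```

Reading the output: the imaging arm costs 523,968.98 EUR in total
(1,300.17 EUR per randomised patient) against 331,393.85 EUR (830.56 EUR)
under standard of care — the entire excess is the MRI/mpMRI tariff, not
additional liver-related care. The imaging arm diagnoses 57% of patients
vs 48%. In the biopsied subgroup, the cT1 ≤ 875 ms rule identifies
patients without MASH with fibrosis with sensitivity 0.90 and specificity
0.63, and 9 of 20 biopsies were avoidable. The ICER report shows both the
first-principles computation from the published counts (37 extra
diagnoses → 5,204.73 EUR per diagnosis, 1.11 QALYs) and, under explicit
logged overrides, the published headline pair (38 → 5,067.77 EUR; 4,968.40
EUR/QALY under the reported convention); the `flags` field spells out each
discrepancy rather than hiding it.

A fully synthetic run of the same pipeline:

```r
report <- run_pipeline(pipeline_config(seed = 11))
print(report)
report$cost_by_arm          # Table-2-style summary, all-cause + liver-related
report$diagnostic_metrics   # 2x2 metrics on the simulated biopsy subgroup
report$icer                 # first-principles ICER on simulated data
```

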