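# Minimal follow-up (validation) arm of the Pietra surveillance trial.
# Relative to the calibration arm: recurrence probability adjusted to 40.4%,
# metastatic-site distribution (liver/lung/other) to 14.2/4.8/81.0, and the
# background five-year cumulative mortality raised by 14.0 percentage points
# (1.6% + 14.0pp = 15.6%). Disease-progression parameters are unchanged.
# The local-only share of recurrences uses the same 50% assumption as the
# intensive fixture (see that file and the package vignette).
name: pietra_minimal
n_patients: 10000
p_recur: 0.404
horizon_cycles: 20
eligibility: cycle_start
p_lung_operable: 0.5
site_distribution:
- local_status: locoregional
  met_status: none
  prob: 0.35
- local_status: anastomotic_only
  met_status: none
  prob: 0.15
- local_status: none
  met_status: liver
  prob: 0.071
- local_status: none
  met_status: lung
  prob: 0.024
- local_status: none
  met_status: multiple_other
  prob: 0.405
progression:
  r_d: 0.092
  x_du_weeks: 6.0
  r_u: 0.11
  x_ds_weeks: 17.0
  r_s: 0.07
  sigma_ds_weeks: 11.0
  m: 0.156
tests:
  cea: {sensitivity: 0.64, specificity: 0.90}
  chest_xray: {sensitivity: 0.76, specificity: 0.95}
  ct_hepatic: {sensitivity: 0.83, specificity: 0.93}
  ct_other_abdominal: {sensitivity: 0.46, specificity: 0.98}
  hepatic_ultrasound: {sensitivity: 0.62, specificity: 0.85}
  colonoscopy: {sensitivity: 0.95, specificity: 1.00}
  clinical_exam: {sensitivity: 0.42, specificity: 0.95}
# "Every 6 months for 1 year; every 12 months thereafter" for clinical
# interview/exam, CEA and hepatic ultrasound; no CT; chest x-ray and
# colonoscopy every 12 months.
schedule_rules:
  clinical_exam:
  - {interval_months: 6, from_month: 6, to_month: 12}
  - {interval_months: 12, from_month: 24, to_month: 60}
  cea:
  - {interval_months: 6, from_month: 6, to_month: 12}
  - {interval_months: 12, from_month: 24, to_month: 60}
  hepatic_ultrasound:
  - {interval_months: 6, from_month: 6, to_month: 12}
  - {interval_months: 12, from_month: 24, to_month: 60}
  chest_xray:
  - {interval_months: 12, from_month: 12, to_month: 60}
  colonoscopy:
  - {interval_months: 12, from_month: 12, to_month: 60}
life_expectancies:
  no_recurrence_years: 20.7
  post_salvage_months: 21
  post_unresectable_months: 8
targets:
  dfs5: 53
  os1: 98
  os2: 89
  os3: 74
  os4: 65
  os5: 58
  salvage: 6
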