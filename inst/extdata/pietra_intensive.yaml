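# Intensive follow-up (calibration) arm of the Pietra surveillance trial.
# Trial-reported inputs: recurrence rate 39.4%; metastatic-site distribution
# (liver/lung/other, if metastases present) 26.7/0.0/73.3; calibrated
# background five-year mortality 1.6%; disease-progression parameters at
# their final calibrated values.
# The trial's local-only vs metastatic split of recurrences was not
# published. This fixture assumes 50% local-only (35% locoregional, 15%
# anastomotic-only) and 50% metastatic, subdivided by the reported
# metastatic-site distribution; see the package vignette for how this share
# was reconstructed. It is an explicit scenario input and can be changed.
name: pietra_intensive
n_patients: 10000
p_recur: 0.394
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
  prob: 0.1335
- local_status: none
  met_status: lung
  prob: 0.0
- local_status: none
  met_status: multiple_other
  prob: 0.3665
progression:
  r_d: 0.092
  x_du_weeks: 6.0
  r_u: 0.11
  x_ds_weeks: 17.0
  r_s: 0.07
  sigma_ds_weeks: 11.0
  m: 0.016
tests:
  cea: {sensitivity: 0.64, specificity: 0.90}
  chest_xray: {sensitivity: 0.76, specificity: 0.95}
  ct_hepatic: {sensitivity: 0.83, specificity: 0.93}
  ct_other_abdominal: {sensitivity: 0.46, specificity: 0.98}
  hepatic_ultrasound: {sensitivity: 0.62, specificity: 0.85}
  colonoscopy: {sensitivity: 0.95, specificity: 1.00}
  clinical_exam: {sensitivity: 0.42, specificity: 0.95}
# "Every 3 months for 2 years; every 6 months thereafter" for clinical
# interview/exam, CEA and hepatic ultrasound; CT of abdomen/pelvis (both
# performance components), chest x-ray and colonoscopy every 12 months.
schedule_rules:
  clinical_exam:
  - {interval_months: 3, from_month: 3, to_month: 24}
  - {interval_months: 6, from_month: 30, to_month: 60}
  cea:
  - {interval_months: 3, from_month: 3, to_month: 24}
  - {interval_months: 6, from_month: 30, to_month: 60}
  hepatic_ultrasound:
  - {interval_months: 3, from_month: 3, to_month: 24}
  - {interval_months: 6, from_month: 30, to_month: 60}
  ct_hepatic:
  - {interval_months: 12, from_month: 12, to_month: 60}
  ct_other_abdominal:
  - {interval_months: 12, from_month: 12, to_month: 60}
  chest_xray:
  - {interval_months: 12, from_month: 12, to_month: 60}
  colonoscopy:
  - {interval_months: 12, from_month: 12, to_month: 60}
life_expectancies:
  no_recurrence_years: 20.7
  post_salvage_months: 21
  post_unresectable_months: 8
targets:
  dfs5: 68
  os1: 97
  os2: 90
  os3: 84
  os4: 76
  os5: 73
  salvage: 20
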