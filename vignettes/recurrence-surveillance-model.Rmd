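---
title: "A microsimulation of colorectal-cancer recurrence and surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A microsimulation of colorectal-cancer recurrence and surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcrecur)
```

## The model

About a third of patients curatively resected for colorectal cancer (CRC)
later recur, and follow-up programs try to catch those recurrences while
curative salvage surgery is still possible. `crcrecur` simulates this
process with two interacting submodels.

**Disease progression (continuous time).** Each patient is assigned a
future recurrence status with probability `p_recur` and, if recurring, an
anatomic site: a local component (locoregional, anastomotic-only, or
intraluminal) and/or a metastatic component (liver, lung, or
multiple/other organs). Recurrences "begin" at initial treatment; the time
$D_i$ at which patient $i$'s recurrence first becomes detectable by testing
is exponential with per-cycle hazard $r_d$, which produces the familiar
declining incidence of recurrence with time since surgery. Two milestones
follow deterministically and stochastically from $D_i$ (all in 3-month
cycles; window parameters are quoted in weeks, 13 weeks per cycle):

$$U_i = D_i + x_{du}\,(1 + r_u D_i), \qquad
  S_i = D_i + x_{ds}\,(1 + r_s D_i) + \epsilon_{ds},\quad
  \epsilon_{ds} \sim N(0, \sigma_{ds}^2).$$

$U_i$ is the point of unresectability — beyond it only palliation is
possible — and $S_i$ the point of symptom onset, at which the patient
seeks care between scheduled visits. Positive $r_u$ and $r_s$ encode the
clinical observation that late-recurring disease runs a more indolent
course. The error term guarantees that some patients become symptomatic
while still resectable and others only afterwards.

**Surveillance and re-treatment (discrete time).** A five-state
individual-based Markov submodel (no known recurrence; recurrence
curatively treated; recurrence palliatively treated; dead of cancer; dead
of other causes) advances in 3-month cycles over a 5-year horizon (20
cycles). A binary schedule matrix — one row per cycle, one column per
modality (CEA assay, chest X-ray, the hepatic and other-abdominal
components of CT, hepatic ultrasound, colonoscopy, clinical
interview/exam) — dictates which tests are administered at each cycle
boundary. Each administered test fires with probability `sensitivity` when
the patient harbors a detectable ($t \ge D_i$) recurrence at a site that
modality targets, and with probability `1 - specificity` otherwise. Any
positive triggers a single full workup within the cycle whose combined
sensitivity and specificity are 100%: recurrence is diagnosed if and only
if something is actually detectable. A consequence worth noting is that a
false positive can serendipitously diagnose a true recurrence at a
different site — lowering the specificity of a site-specific test can
therefore *increase* curative salvage, a paradox the sensitivity analysis
reproduces.

At diagnosis (by surveillance at a boundary, or symptomatically at the
continuous time $S_i$), resectability and site operability decide the
path: local-only disease and liver metastases are operable, lung
metastases half as often as liver, multiple/other metastases never.
Salvaged patients are assigned a 21-month life expectancy, unresectable
ones 8 months; cancer death then occurs deterministically at diagnosis
time plus life expectancy, competing with a per-cycle background
mortality derived from the five-year cumulative probability $m$ via
$(1-p)^{20} = 1-m$.

## Design choices in the gaps

Several details are not pinned down by the modeling approach itself; the
package makes these choices explicit and, where sensible, configurable.

**Resectability is assessed at the start of the diagnosis cycle**
(`eligibility = "cycle_start"`, the default). The discrete submodel
evaluates disease state cycle by cycle, so a recurrence diagnosed during
cycle $c$ is classified by whether that cycle began before $U_i$. The
strictly continuous alternative (`"exact"`, comparing the diagnosis time
itself with $U_i$) is also implemented. The choice matters: with the
calibrated 6-week baseline resectability window, the exact rule classifies
roughly half as many diagnoses as salvageable, and cannot reproduce the
~20% salvage proportion observed in the intensive arm of the calibration
trial for any site mix — the operable fraction required would exceed
100%. The cycle-start rule reproduces it naturally, and the package's
fixtures use it.

**The local/metastatic split of recurrences.** The calibration data source
(a classic Italian randomized follow-up trial by Pietra and colleagues)
reported the distribution of metastatic disease *when present*
(liver/lung/other 26.7/0.0/73.3 in the intensive arm, 14.2/4.8/81.0 in the
minimal arm) but not the share of recurrences that were local-only. That
share is a required scenario input here. The packaged fixtures assume 50%
local-only (35% locoregional, 15% anastomotic-only), for two reasons:
the trial focused on — and re-operated — local recurrences, and simple
algebra bounds the salvage proportion above by
$p_{recur}\,P(D \le 20)\,[L + (1-L) \cdot 0.267]$, which reaches the
observed 20% only for a local share $L$ near one half or more. Shares of
30% or below are arithmetically incompatible with the trial's salvage
outcome. The assumption is stated in the fixture files and is an ordinary
config knob.

**Within-cycle event order.** Symptom onset is a continuous-time event
inside the cycle, so it resolves first; scheduled testing happens at the
boundary; mortality last, with an assigned cancer death (a continuous
time) taking precedence over the background draw at the boundary. Ties at
a boundary ($S_i$ exactly at a visit) resolve symptomatically — the
diagnosis time is the same either way.

**Clipping of symptom onset.** A large negative $\epsilon_{ds}$ can push
$S_i$ below $D_i$, a symptomatic but undetectable recurrence the model
does not admit. $S_i$ is clipped to $D_i$ (not resampled, preserving the
error distribution above the boundary) and the event is flagged per
patient in the `s_clipped` output column.

**Visit anchoring.** Rules like "every 3 months for 2 years, every 6
months thereafter" anchor to months since surgery with no visit at time
zero: cycles 1–8 then 10, 12, …, 20. Yearly tests fall at cycles 4, 8, 12,
16, 20; the minimal arm's "every 6 months for 1 year, then yearly" gives
cycles 2, 4, 8, 12, 16, 20. Intervals must be multiples of the 3-month
cycle.

## Random numbers and reproducibility

The cohort engine (C++) draws every variate as a pure hash of
`(seed, patient index, draw identity)`, where the identity encodes what the
draw decides — recurrence status, site, $D_i$, $\epsilon_{ds}$, lung
operability, each (cycle, modality) test result, each cycle's mortality.
Three contracts follow by construction: runs are bitwise reproducible;
growing the cohort leaves earlier patients' histories untouched; and two
scenario variants run under the same seed share every draw whose identity
they have in common (common random numbers), so a sensitivity sweep
isolates the parameter's effect and a schedule that adds visits can only
advance diagnoses. The single-patient R functions (`assign_recurrence()`,
`simulate_patient()`, …) mirror the engine's logic using R's own RNG and
are cross-checked against it in the test suite.

## Calibration

Seven parameters ($r_d, x_{du}, r_u, x_{ds}, r_s, \sigma_{ds}, m$) are
estimated by iterative grid search against seven observed targets (DFS5,
OS1–OS5, salvage proportion), expressed in percentage points. Each round
builds the Cartesian grid over the current ranges, simulates a cohort per
combination, then filters candidates target by target in priority order
(DFS5, OS5, OS4, OS3, salvage, OS2, OS1 — the last two are most exposed to
small-number noise in the source trial): deviations beyond ±1 point are
dropped, with a ±2-point fallback when a step would otherwise eliminate
everyone, and a flagged skip if even the fallback would. Ranges then
narrow to the survivors' span, padded by one grid step each side and
clipped to the starting ranges. Rounds stop when the minimum unweighted
sum-of-squared-deviations fit stops improving; the final set is the
terminal survivor closest to the final ranges' midpoints (summed
normalized distance, ties broken in parameter order).

The default profile is deliberately desk-scale — 3-point grids (2,187
combinations per round), 2,000 patients per run, at most 3 rounds — sized
so that a full parameter-recovery exercise completes in well under a
minute while still locating the generating values within the terminal
ranges; the original nine-round, ~277,000-combination search is reachable
via configuration (`points_per_param`, `n_patients`, `max_rounds`) but is
machinery, not a requirement. Each combination runs under a sub-seed
derived from the master seed and its index, so calibrations are exactly
repeatable.

## Sensitivity analysis

`one_way_sweep()` perturbs one non-calibrated scalar (a test's sensitivity
or specificity, or a life expectancy) to its published low and high
values, re-running under the identical seed, and reports the change in the
salvage proportion and OS5 as *percent of baseline* — the relative reading
of statements like "a 7.9% increase"; the absolute-percentage-point
reading would imply implausibly large effects. `sweep_all()` ranks the
default 16-parameter table tornado-style. The implementation reproduces
the qualitative structure reported for this model — CEA sensitivity most
influential, clinical exam next, the specificity paradox for hepatic
ultrasound, every other parameter within 5% relative — but the CEA effect
magnitude here is about ±3% rather than the reported ±7–8%. Under the
cycle-start eligibility rule that the salvage totals require, per-visit
combined detection probability in the intensive arm is high (~0.8–0.9) and
the effective resectability window spans one or two visits, so detection
before $U_i$ is close to saturated and a ±0.15 change in one test's
sensitivity moves few patients; the exact-eligibility variant roughly
doubles the effect but understates salvage overall. We report the computed
values as they are.

## What the synthetic generator does and does not emulate

`generate_synthetic_scenario()` draws structurally valid random scenarios
— site mixes over all five site types, progression parameters across wide
ranges, random test panels and visit matrices — for property-based
testing: survival orderings, detectability invariants, schedule-coupling
monotonicity, round-trip I/O. It emulates the model's *structure*, not
clinical realism: real cohorts have correlated test schedules, adherence
patterns, stage mix, and site-specific survival that the generator (and
the model) do not represent. Green property tests therefore certify the
simulator's internal contracts, not predictive validity on real data —
that is what the packaged trial fixtures and their validation-arm
comparison are for.

## Numerical notes

* Problem sizes: packaged fixtures simulate 10,000 patients (Monte-Carlo
  SE on a proportion ≈ 0.5 points); the recovery exercise uses 2,000 per
  combination; distributional unit tests use 10^5 draws with 3-SE bands.
* Uniforms are generated strictly inside (0, 1) (53-bit, half-offset), so
  inverse-CDF transforms never hit infinities.
* `sigma_ds = 0` short-circuits the normal draw; degenerate (zero-width)
  calibration ranges collapse to a single grid value.
* Site distributions must sum to 1 within 1e-6; schedules must be 0/1
  matrices with one row per cycle.

## Limitations

Second primary (metachronous) tumors are not modeled as a separate
process; there is no re-recurrence after salvage, no cost or
quality-of-life tracking, and no test adherence model. Calibration targets
are aggregate trial outcomes, so the parameters are identified only up to
the usual aggregate-calibration uncertainty — the grid search returns
ranges, not confidence intervals. Life expectancies after diagnosis are
fixed assignments rather than survival draws; within a 5-year horizon with
competing background mortality this is a minor simplification, but it
makes post-diagnosis survival curves step-shaped.
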