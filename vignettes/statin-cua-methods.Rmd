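---
title: "Methods: a lifetime Markov cost-utility model of statin intensity after ACS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime Markov cost-utility model of statin intensity after ACS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acscua)
```

## The decision problem

After hospitalization for an acute coronary syndrome (ACS), patients take a
statin for life as secondary prevention. High-intensity statin therapy (HIS:
atorvastatin 40 mg or rosuvastatin 20 mg daily) lowers the rate of recurrent
myocardial infarction and revascularization relative to low-to-moderate
intensity therapy (LMIS), at a higher annual drug cost. `acscua` implements a
cost-utility analysis of that trade-off from the Indonesian payer
perspective: a Markov cohort model accrues discounted lifetime costs (in
Indonesian rupiah, IDR) and quality-adjusted life years (QALYs) under each
strategy and reports the incremental cost-effectiveness ratio (ICER),

$$\mathrm{ICER} = \frac{C_{HIS} - C_{LMIS}}{Q_{HIS} - Q_{LMIS}},$$

judged against two Indonesian willingness-to-pay thresholds: the empirical
willingness to pay for life-saving disease (192,514,839 IDR/QALY) and three
times GDP per capita (206,319,831.79 IDR/QALY).

## Model structure

Five health states: Resolved ACS (RA), Myocardial Infarction (MI), Cardiac
Arrest (CAr), Revascularization (Rv), and Death (D, absorbing). The whole
cohort enters at age 30 in RA and moves in one-year cycles. Annual
transition probabilities out of RA (to MI, CAr, Rv) and between event states
(MI→MI, MI→Rv, Rv→Rv, Rv→MI) are age-constant; event-state mortality
(MI→D, CAr→D, Rv→D) is tabulated in eleven 5-year age bands from 30–34 to
80–84. The packaged reference table (`acs_parameters()`) carries every mean
and standard error; RA's outgoing row sums to exactly 1 and lists no direct
death exit, so the base model has no background mortality from RA — death
is reached only through event states.

Three aspects of the structure are genuine conventions rather than data,
and are explicit switches in `model_config()`:

* **Residual rule.** The tabulated outgoing probabilities of MI, CAr and Rv
  rows do not sum to 1; the survivor residual must go somewhere. The default
  `to_RA` returns event-year survivors to the resolved state, reading RA as
  the hub of the state diagram; `stay` leaves them in the event state
  (making CAr nearly absorbing, which sits poorly with its moderate utility
  weight); `to_D` sends the residual to death, an exploratory high-mortality
  reading discussed below.
* **Hazard-ratio application.** The HIS effect sizes are hazard ratios for
  MI, CAr and Rv events. By default they multiply the annual probability of
  every transition *into* the event state (`all_inbound`,
  `multiplicative`, capped at 1); alternatives restrict them to first
  events from RA (`from_RA_only`) or act on the log-survival scale
  (`rate_based`, $1-(1-p)^{hr}$). The residual of each row is recomputed
  after transformation; any row pushed past total mass 1 is rescaled
  proportionally and the event is counted and reported.
* **Horizon tail.** "Lifetime" is age 100 by default, holding the 80–84
  mortality band for older ages (`hold_last_band`); `truncate` stops the
  simulation at age 85 instead.

Cycle length is fixed at one year. Discounting is end-of-cycle at 3% per
year for both costs and outcomes (cycle 0 undiscounted); a half-cycle
correction (half weight on the first and last cycle) is off by default and
switchable. The cohort is tracked as exact proportions; the conventional
reporting cohort of 1000 patients is only a display scale.

## Economic accrual

Per cycle, each alive state accrues its per-state direct medical cost
(INA-CBGs tariffs: RA 19.73M, MI 12.12M, CAr 7.04M, Rv 40.02M IDR) every
cycle of occupancy, every alive patient accrues the strategy's annual drug
cost (HIS 3,908,568; LMIS 1,474,656 IDR) — statins are taken for life — and
utility weights (RA 0.78, MI 0.65, CAr 0.68, Rv 0.78; death 0) accrue
QALYs. Death costs nothing.

## Base case and the reproducibility gap

Under the default conventions the deterministic model gives (per patient,
discounted): HIS 690.6M IDR and 22.35 QALYs, LMIS 612.5M IDR and 21.87
QALYs — an ICER of 163,030,422 IDR/QALY, below both thresholds. These are
the numbers `acs_cua()` prints and the test suite recomputes.

The source analysis from which the parameter table is taken reports a much
lower base-case ICER (31,843,492.98 IDR/QALY deterministic; 31,742,536.88
probabilistic). `convention_sweep()` enumerates all 32 combinations of the
convention switches above; across them the ICER ranges from about 90M to
266M IDR/QALY and never approaches 31.8M. The gap appears structural rather
than conventional: the source's reported incremental *drug* cost range
(27.4M–34.1M IDR) equals the annual drug-cost difference (2,433,912 IDR)
times roughly 11–14 discounted life-years, whereas this parameter table —
with no death exit from RA and survivors returning to RA — implies about
29 discounted life-years from age 30. A model whose survivors do not return
to the resolved state (the exploratory `to_D` residual rule reaches ICERs
near 50M) is closer but still not reconcilable with the published figure.
We therefore report the model's own results as computed and expose the
sweep so users can quantify the convention sensitivity themselves. The
tornado ordering shows the same signature: with a small incremental QALY
gain (~0.48), the utility of the resolved state and the HIS drug price are
among the *most* influential parameters here, while the resolved-state
medical cost ranks mid-field — not the ordering the source reports.

## Probabilistic sensitivity analysis

`run_psa()` (or `simulate()` on a fitted analysis) draws each parameter
independently from a distribution matched to its tabulated mean and
standard error by method of moments: beta for probabilities and utilities
(feasibility $se^2 < m(1-m)$ is validated), gamma for costs, lognormal
(moment-matched on the natural scale) for hazard ratios. Discount rates are
fixed in PSA — they are policy choices, not sampling quantities — and are
varied in the one-way analysis instead. The RA stay probability is never
sampled: it is the row residual $1 - (tpRA\_MI + tpRA\_CAr + tpRA\_Rv)$, as
sampling all four row entries independently would break row-stochasticity
(its tabulated standard error is informational only). Within an iteration
the same sampled table drives both strategies, so the hazard ratios are the
only between-arm difference. A sampled row whose listed mass exceeds 1 is
proportionally rescaled; a draw that still fails validation is redrawn (at
most 100 attempts); both events are counted and surfaced in summaries and
manifests. Iteration *i*'s draws depend only on (seed, *i*), so runs are
exactly reproducible and restartable.

With 1000 iterations the ratio-of-means probabilistic ICER lands within a
fraction of a percent of the deterministic value (~163M IDR/QALY), every
iteration gains QALYs under HIS, and the probability of cost-effectiveness
is about 0.72 at the 192.5M threshold and 0.80 at the 206.3M threshold
(seed-dependent within a couple of points) — again far from the 0.99 the
source reports, for the structural reason above. The median-of-ratios ICER
is also exported, since which convention a published probabilistic ICER
uses is rarely stated.

## One-way sensitivity analysis

`owsa()` varies one parameter at a time. The default range rule is `ci95`
(mean ± 1.96·SE, clipped to the parameter's domain), with `pct20`
(mean ± 20%) available for tables without standard errors; the published
ranges are not stated, and ±1.96·SE is the standard reading of a tabulated
SE. Discount rates are always varied over [0, 0.05], the common guideline
interval. Entries are sorted by ICER spread for tornado display. The
analysis is deterministic and reproducible bit-for-bit.

## Synthetic parameter tables

`random_parameters(seed, difficulty)` generates valid tables for testing:
event probabilities drawn so every row keeps positive residual mass in
every age band, mortality growing geometrically in age (growth factor
1.2–1.5 per band, typical; up to 1.75, extreme), costs positive, utilities
inside (0,1) with event states no better than RA, hazard ratios in
(0.3, 1.5), and standard errors drawn as a feasible fraction of each
distribution's moment bound. `"extreme"` pushes probabilities toward 0,
hazard ratios toward 1, and utilities toward their bounds. The generator
emulates the *structure* of a secondary-prevention parameter table — it
makes no claim of clinical realism in the joint distribution (e.g. costs
are independent of severity), so passing tests on synthetic tables
demonstrates engine correctness and validation coverage, not calibration to
any real population.

## Numerical choices and limitations

* Row-stochasticity is enforced to 1e-10 and checked in tests; occupancy
  vectors stay within 1e-9 of total mass 1 over a 70-cycle horizon.
* ICERs with $|\Delta Q| < 10^{-12}$ are flagged `undefined` rather than
  divided; strict dominance flags follow the cost-effectiveness-plane
  quadrants.
* A degenerate single-cycle run (`max_age = start_age`) is allowed and
  accrues exactly one undiscounted cycle in RA — useful as a closed-form
  check.
* Validation is data-first: `validate_parameters()` returns a violation
  table instead of throwing, so samplers and file loaders can react; the
  constructors raise the same information as errors.
* Model-validation problem sizes: the cohort trace is checked against a
  200,000-patient individual-level microsimulation using the same
  transition matrices (agreement within 0.5 percentage points per state per
  cycle over the full horizon); matrix properties are swept over the
  reference table plus 100 synthetic tables; the generator is swept over
  1000 consecutive seeds; sampler moment recovery uses 10,000 draws per
  family.
* Not modelled: individual covariates, time-in-state (tunnel) effects,
  treatment discontinuation or adherence, background non-cardiac mortality
  from RA, cost inflation, currency conversion (a user-supplied IDR/USD
  rate is accepted for display only), and budget impact.
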