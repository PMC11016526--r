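# acscua

A lifetime Markov cohort cost–utility model comparing **high-intensity
statin therapy (HIS)** with **low-to-moderate-intensity statin therapy
(LMIS)** for secondary prevention in post-hospitalized acute coronary
syndrome (ACS) patients, from the Indonesian payer perspective. It is aimed
at health-economics practitioners who want a reproducible, scriptable,
fully tested implementation of this model family: cohort trace, discounted
cost/QALY accrual, incremental cost-effectiveness ratio (ICER),
probabilistic sensitivity analysis (PSA), cost-effectiveness acceptability
curves (CEAC), one-way (tornado) sensitivity analysis, and a sweep over the
structural conventions that published models often leave unstated.

## The model

Five health states — Resolved ACS (RA), Myocardial Infarction (MI),
Cardiac Arrest (CAr), Revascularization (Rv), Death (D) — with one-year
cycles from age 30 to 100. Transition probabilities, age-banded event
mortality (5-year bands, 30–84), per-state direct medical costs (IDR),
annual drug costs, HIS hazard ratios, utilities, and 3% discount rates ship
as a validated parameter table (`acs_parameters()`), each with a standard
error. Strategy comparison:

- cohort trace: `x_{t+1} = x_t P(a_t)`, with `P` rebuilt per age band and
  strategy (hazard ratios applied to transitions into MI/CAr/Rv under HIS);
- per cycle: state costs + drug cost for the alive, utilities for QALYs,
  discounted at `1/(1+r)^t`;
- `ICER = (C_HIS − C_LMIS) / (Q_HIS − Q_LMIS)`, judged against the
  Indonesian willingness-to-pay thresholds 192,514,839 IDR/QALY
  (life-saving disease) and 206,319,831.79 IDR/QALY (3× GDP per capita);
- PSA: beta/gamma/lognormal method-of-moments sampling from the tabulated
  means/SEs, 1000 Monte Carlo iterations, CEAC and CE-plane outputs.

See the methods vignette (`vignettes/statin-cua-methods.Rmd`) for the
conventions, their defaults, and a discussion of how the results relate to
the published analysis this parameter table comes from.

## Worked example

```r
library(acscua)

fit <- acs_cua()          # reference table, default conventions
summary(fit)
```

```
Per-patient discounted totals:
 strategy  total_cost   drug_cost total_qaly life_years
      HIS 690,602,618 112,317,419   22.34793   28.73621
     LMIS 612,483,054  41,532,516   21.86876   28.16421
HIS vs LMIS: dCost = 78,119,564 IDR, dQALY = 0.479172
  ICER = 163,030,422 IDR per QALY (quadrant NE)
  at WTP 192,514,839 IDR/QALY: incremental NMB 14,128,098 IDR (cost-effective)
  at WTP 206,319,832 IDR/QALY: incremental NMB 20,743,060 IDR (cost-effective)
```

Lifetime HIS therapy costs 78.1M IDR more per patient and gains 0.48
QALYs; at 163M IDR per QALY it is under both national thresholds, i.e.
cost-effective, though with little headroom. Uncertainty and structural
sensitivity:

```r
psa <- simulate(fit, nsim = 1000, seed = 1)   # probabilistic SA
summary(psa)                                  # prob. ICER, CEAC, quadrants
tor <- owsa(acs_parameters())                 # tornado table
sw  <- convention_sweep(acs_parameters(),     # 32 structural conventions
                        reference = 31843492.98)
```

`summary(psa)` reports a ratio-of-means probabilistic ICER of ~162.9M
IDR/QALY with all 1000 iterations gaining QALYs, and cost-effectiveness
probabilities of ~0.72 / ~0.80 at the two thresholds. Plot methods draw the
occupancy traces (`plot(fit)`), CE plane (`plot(psa)`), and tornado
(`plot(tor)`).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/acscua.R base-case --out-dir out/
Rscript inst/cli/acscua.R psa --n 1000 --seed 1 --out-dir out/
Rscript inst/cli/acscua.R owsa --range-rule ci95 --out-dir out/
Rscript inst/cli/acscua.R sweep --reference 31843492.98 --out-dir out/
```

Each run writes plain CSV/JSON tables plus a manifest (config, seed,
version, feasibility warnings) that makes stochastic outputs replayable
bit-for-bit.

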