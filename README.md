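# capnovent

An in-silico crossover study of **variable ventilation (VV) versus
pressure-controlled ventilation (PCV) during and after capnoperitoneum**,
built as a fully testable R pipeline. Laparoscopic surgery inflates the
abdomen with CO2; the diaphragm shifts cranially, lung volume falls, tissue
mechanics stiffen, shunt rises and CO2 is retained. VV — breath-by-breath
variation of tidal volume and rate around the conventional targets — is a
candidate countermeasure. `capnovent` simulates every computational layer
of such an experiment and analyzes it the way the physiology literature
does, so that each layer can be verified against closed forms, brute-force
oracles and reference implementations.

The package is aimed at respiratory physiologists and methodologists who
want a reproducible sandbox for crossover ventilation studies: power/design
exploration, estimator validation (oscillometry fitting), or teaching.

## What it computes

* **Breath plans and delivery** — PCV and VV plans (VV: truncated-Gaussian
  multipliers on driving pressure and rate, exactly rescaled so every
  disjoint 30-breath window reproduces the PCV mean VT and RR), delivered
  on a single-compartment lung `Pao = R·V' + E·V + PEEP` with exact
  exponential stepping and a PIP calibrated by bisection to a 7 mL/kg
  target.
* **Forced oscillometry** — a pseudorandom pressure signal with 23
  mutually non-integer-multiple components on 0.5–20.75 Hz (doubled
  primes on the 0.125 Hz grid of an 8-s window), input impedance
  `Zrs = Pao/V'` by cross/auto-spectra, tracheal-tube subtraction,
  ensemble averaging, and the constant-phase tissue model

  `Z(w) = Raw + jw·Iaw + (G − jH)/w^a`, `a = (2/pi)·atan(H/G)`,

  fitted by multi-start log-parameter least squares; hysteresivity
  `eta = G/H` is derived, never fitted.
* **Gas exchange** — alveolar gas equation, oxygen contents
  (`CaO2 = 1.34·Hb·SaO2 + PaO2·0.0031`, capillary content at full
  saturation) and the modified Berggren shunt
  `Qs/Qt = (CcO2 − CaO2)/(CcO2 − CvO2)`.
* **A synthetic cohort** — 11 subjects × 2 modes × 3 stages (START, CP,
  post-CP) with subject random intercepts, stage-dependent cell moments
  taken from reported stage summaries, and a blood-gas panel from which the
  shunt is *derived*, never drawn.
* **The statistics** — two-way repeated-measures ANOVA with Mauchly /
  Greenhouse–Geisser / Huynh–Feldt handling of sphericity, Holm–Šidák
  post-hoc contrasts, per-subject relative changes with t-based 95% CIs,
  and Pearson correlation of elastance vs oxygenation changes.

## Worked example

```r
library(capnovent)

mech     <- baseline_mechanics()              # Raw 20, Iaw 0.15, G 40, H 200
settings <- ventilator_settings("VV")         # 7 mL/kg, 22/min, PEEP 5, CV 0.2
calibrate_pip_for_vt(mech, settings)
#> [1] 10.51        # cmH2O: driving pressure ~5.5 for a 27.3 mL breath

plan <- make_vv_plan(settings, 60, seed = 1, mech = mech)
simulate_breaths(plan, mech)
#> <simulated_breathing> 60 breaths, 169 s @ dt = 5e-04 s, mean VT 27.2 mL

fit_constant_phase(cpm_impedance(mech, forcing_spec()$frequencies))
#> <cpm_fit> converged (cost 4.638e-27, 23 freqs)
#> <mechanical_state>
#>   Raw = 20 cmH2O.s/L   Iaw = 0.15 cmH2O.s2/L
#>   G   = 40 cmH2O/L     H   = 200 cmH2O/L
#>   eta = 0.2             alpha = 0.8743

st <- run_study(study_config(n_subjects = 11, seed = 1))
st
#> <capno_study> 11 subjects, seed 1
#> Stage-effect ANOVA p-values (uncorrected):
#>   pao2_fio2  mode p = 0.105, stage p = 0.000144, interaction p = 0.00337
#>   paco2      mode p = 0.0597, stage p = 1.35e-11, interaction p = 0.00278
#>   qs_qt      mode p = 0.734, stage p = 9.78e-05, interaction p = 0.0606
#>   ...
#>   eta        mode p = 0.221, stage p = 0.928, interaction p = 0.0103
#>   vt         mode p = 0.508, stage p = 0.897, interaction p = 0.989
```

The simulated study shows the expected physiology: strong stage effects on
gas exchange and tissue mechanics (capnoperitoneum worsens them, deflation
restores them), stable VT/RR (the ventilator holds its windowed targets),
and an eta (= G/H) untouched by stage — damping and elastance rise
proportionally. Per-subject relative changes mirror the reported pattern,
e.g. for Paco2:

```r
relative_changes(st$cohort, "paco2")
#>   outcome mode         contrast mean_pct ci_lo ci_hi  n
#> 1   paco2  PCV      CP vs START     36.9  23.9  50.0 11
#> 2   paco2  PCV post-CP vs START     25.4  15.8  35.1 11
#> 3   paco2   VV      CP vs START     51.9  42.7  61.2 11
#> 4   paco2   VV post-CP vs START     17.7  11.6  23.9 11
```

CO2 retention is larger under VV during capnoperitoneum, but CO2 clearance
is better under VV after deflation — the study's direction-of-effect
finding, which the acceptance suite verifies across 100 seeded replicates.

## Command line

```sh
capnovent simulate --n 11 --seed 1 --out cohort.csv
capnovent plan --mode vv --seed 1 --out plan.csv
capnovent fit-impedance spectra.csv --weights uniform --out fit.json
capnovent gases panels.csv --out panels_computed.csv
capnovent analyze cohort.csv --out results.json
capnovent run-study --n 11 --seed 1 --out study_out
```

(The launcher lives in `inst/exec/capnovent`; equivalently call
`capnovent::capnovent_main(c("simulate", ...))`.)

## Layout

* `R/` — ventilation, oscillometry, fitting, gas exchange, cohort
  generator, statistics, study orchestration, CLI.
* `tests/testthat/` — unit and property tests per module plus
  `test-acceptance.R` (one test per acceptance criterion); oracles include
  closed forms, a brute-force 15^4 grid search, and base R's `aov` /
  `mauchly.test`.
* `vignettes/capnovent-methods.Rmd` — models, assumptions, parameter
  provenance, numerical choices, limitations.
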