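---
title: "Models and methods behind capnovent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind capnovent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnovent)
```

# Scope

`capnovent` is an in-silico counterpart of a crossover animal experiment on
ventilation during capnoperitoneum: eleven anaesthetized rabbits, each
ventilated in two modes — conventional pressure-controlled ventilation (PCV)
and variable ventilation (VV) — through three protocol stages: baseline
(START), 15 minutes of capnoperitoneum at 6 cmH2O intra-abdominal pressure
(CP), and 15 minutes after abdominal deflation plus a recruitment maneuver
(post-CP). The package simulates every computational layer of such a study
(breath plans, forced-oscillation mechanics, blood-gas chemistry, cohort
statistics) and analyzes the result the way the physiology literature does.
Nothing here touches animals: the cohort is synthetic, parameterized from
reported stage summaries, and the point of the package is that the whole
chain — generation, measurement, fitting, statistics — is testable end to
end.

# Ventilation: breath plans on a single-compartment lung

## Equation of motion and its discretization

Breaths are delivered against the linear single-compartment equation of
motion

$$P_{ao}(t) = R \dot V(t) + E V(t) + \mathrm{PEEP},$$

driven by an ideal square pressure wave between PEEP and the per-breath
peak inspiratory pressure (PIP) with a 1:2 inspiratory:expiratory split.
The compartment parameters are reduced from the constant-phase mechanics:
$E = H$ and $R = R_{aw} + G/\omega_b^\alpha$ with $\omega_b$ the breathing
angular frequency — the minimal time-domain model consistent with
frequency-domain tissue parameters. Within each constant-drive segment the
state is advanced by the exact exponential update
$V_{k+1} = V_\infty + (V_k - V_\infty)e^{-\Delta t/\tau}$, $\tau = R/E$,
so there is no integrator-order ambiguity; the default step is
$\Delta t = 0.5$ ms.

Three recording conventions matter because the square drive makes flow
discontinuous at phase transitions:

* the recorded **volume trace is the trapezoidal antiderivative of the
  recorded flow trace**, so the pair is exactly conservative under the
  trapezoid rule (the internal state stays exponential-exact);
* a sample at a drive transition records the **mean of the left and right
  flow limits**, halving the discretization bias of the jump;
* a sample at a breath boundary is attributed to the **incoming** breath,
  so the outgoing breath's end-expiratory volume is not contaminated by the
  next inspiration.

Without these choices the jump bias is about
$\Delta t \cdot \Delta\dot V/2 \approx 3\times10^{-5}$ L per transition —
enough to push end-expiratory volume negative and to fail a 0.1%
grid-convergence check. With them, halving $\Delta t$ moves delivered VT by
$\sim 2\times10^{-5}$ relative. If $\tau < \Delta t/10$ the lung is treated
as resistance-free (volume steps instantly to $\Delta P/E$).

## PIP calibration and the variable-ventilation pattern

`calibrate_pip_for_vt()` finds by monotone bisection the PIP whose single
steady-state simulated breath delivers the tidal-volume target (7 mL/kg by
default) to 0.1%. On the default rabbit mechanics this lands near
PIP ≈ 10.5 cmH2O, i.e. a driving pressure of ≈ 5.5 cmH2O — the scale
reported for healthy rabbits at this VT.

VV perturbs the calibrated plan breath by breath. The original experimental
pattern came from a pre-recorded physiological signal that is not
available, so the package states its own distribution: i.i.d. multipliers
on driving pressure and on breath rate, Gaussian truncated at ±2 SD, with
default coefficient of variation 0.2 each. Two deliberate choices:

* **The stated CV is the CV of the truncated distribution.** Truncation at
  ±2 SD shrinks the SD by ≈ 12%; the pre-truncation SD is inflated to
  compensate. Under the naive reading the realized CV would sit exactly on
  the package's own "within 15% of nominal" contract boundary.
* **Exact windowed rescaling.** Within every disjoint 30-breath window the
  multipliers are divided by their window mean, so the window-mean rate
  equals the PCV rate and the window-mean driving pressure equals the PCV
  driving pressure *exactly* (hence the window-mean model-predicted VT is
  exact too). Disjoint rather than running windows were chosen because the
  averaging contract is stated per 30-cycle block; a running-window
  constraint would couple every breath to every other.

Zero CVs make VV bit-identical to PCV. CVs at or above ≈ 0.44 would let
the ±2 SD truncation floor reach PIP ≤ PEEP and are rejected as a
configuration error. Whether PIP and RR fluctuations should be correlated
is unknown; they are independent here.

# Oscillometry: forcing signal, impedance, constant-phase fit

## The frequency grid

Respiratory input impedance is probed with a small-amplitude multifrequency
pressure signal during 8-s apneic windows. The component frequencies must
be mutually non-integer multiples (so harmonic distortion of one component
never lands on another) and, for leakage-free estimation, should sit on the
FFT bins of the window (0.125 Hz at 8 s). Both are achieved at once by
doubling the first 23 primes: $f_k = 2p_k/8$ Hz gives 0.5, 0.75, 1.25, …,
20.75 Hz — exactly 23 components spanning 0.5–20.75 Hz, with all pairwise
ratios equal to ratios of distinct primes. Default sampling is 256 Hz
(≥ 10× the top component), phases are drawn uniformly from a seed, and the
composite amplitude defaults to 1 cmH2O RMS split equally.

## Estimation and correction

`estimate_impedance()` computes $Z_{rs}(f) = S_{PV'}(f)/S_{V'V'}(f)$ at the
component bins over the full window (an FFT ratio when bins align, a direct
DFT otherwise). A component with no flow energy raises an error naming the
frequency rather than returning a garbage point. The tracheal tube is
modeled as a series resistance–inertance (defaults 2 cmH2O·s/L,
0.01 cmH2O·s²/L — measured in such setups but not reported, so
configurable) and removed by complex subtraction before fitting; repeated
recordings are ensemble-averaged as complex means.

## The constant-phase model and its fit

$$Z(\omega) = R_{aw} + j\omega I_{aw} + \frac{G - jH}{\omega^\alpha},
\qquad \alpha = \frac{2}{\pi}\arctan(H/G),$$

with $\omega$ in rad/s (so $G$ and $H$ carry units cmH2O/L at 1 rad/s —
stated explicitly because the convention is often left implicit).
Hysteresivity $\eta = G/H$ and $\alpha$ are always derived from the fitted
$G, H$, never fitted independently.

`fit_constant_phase()` minimizes
$\sum_f w_f\,|Z_{meas}(f) - Z(f)|^2$ over the log of the four parameters
(positivity by construction) with BFGS and an analytic gradient, from five
deterministic starts spanning 0.1–10× a data-driven guess ($R_{aw}$ from
the high-frequency real part, $H$ from the low-frequency reactance). No
randomness enters the optimizer. Weights default to uniform; a
`weights = "relative"` flag applies $1/|Z|^2$, which is the
likelihood-matched choice when measurement noise is proportional to $|Z|$
— under 5% proportional noise it roughly halves the error on $G$, the
weakest-identified parameter, because uniform weighting lets the large
low-frequency magnitudes dominate the cost. Standard errors come from the
Gauss–Newton covariance with $2m - 4$ residual degrees of freedom. The
convergence flag requires a log-space gradient norm below
$10^{-4}(1 + \mathrm{cost})$ — scale-free, and as tight as BFGS's own
stopping rule reliably delivers on noisy spectra.

# Gas exchange

Oxygen contents use the Hüfner constant 1.34 mL/g and solubility
0.0031 mL·dL⁻¹·mmHg⁻¹:
$C_aO_2 = 1.34\,Hb_{art}\,S_aO_2 + P_aO_2\cdot 0.0031$ (and analogously for
venous blood), with the end-capillary content assuming full saturation at
alveolar oxygen tension,
$C_cO_2 = 1.34\,Hb_{art} + P_AO_2\cdot 0.0031$ — this full-saturation
assumption is what "modified" refers to in the modified Berggren shunt
equation

$$Q_s/Q_t = \frac{C_cO_2 - C_aO_2}{C_cO_2 - C_vO_2}.$$

The alveolar gas equation is
$P_AO_2 = F_iO_2(P_{atmos} - P_{H_2O}) - P_aCO_2/RQ$ with RQ = 0.8.
Barometric pressure 760 mmHg and water-vapor pressure 47 mmHg are
conventional defaults (they are not part of the printed equations) and are
configurable. Saturations are inputs: no dissociation-curve model is fitted.

# The synthetic cohort

## Generative model

Each of the 12 outcomes (oxygenation index, Paco2, shunt, Raw, G, H, MAP,
HR, CO, driving pressure, VT, RR) follows

$$y_{ics} = \mu_{cs} + b_{i} + \varepsilon_{ics},$$

a per-(mode, stage) cell mean, a subject random intercept shared across all
six cells (SD = half the outcome's average cell SD, capped below the
smallest cell SD), and a symmetric truncated-Gaussian residual (±2.5 SD,
drawn by inverse-CDF so the truncation is exactly mean-preserving) scaled
so the marginal cell SD matches the configured value. There is no period or
carryover effect, matching the analysis model. Arms (PCV-first/VV-first)
are a seeded balanced permutation, 6/5 at n = 11.

Internal consistency is by construction, not by accident:

* the blood-gas panel is generated first (Pao2 from the oxygenation index,
  Paco2, hemoglobin, arterial saturation, venous PO2), the venous
  saturation is then *solved* so the panel realizes the drawn shunt target,
  and the recorded Qs/Qt is recomputed from the panel through the
  gas-exchange equations — so `qs_qt` always equals
  `shunt_fraction(oxygen_contents(panel))` bit-exactly;
* $\eta = G/H$ and $P_{driving} = \mathrm{PIP} - \mathrm{PEEP}$ exactly;
* at the CP stage the standardized residuals of $H$ and of the oxygenation
  index share a correlation (default −0.6): animals whose tissue elastance
  rises most during insufflation lose the most oxygenation. Only the sign
  of the resulting association is asserted in tests; its magnitude was
  never a reported quantity.

## Where the default numbers come from

Cell means and SDs for the oxygenation index and Paco2 at CP and post-CP,
and for all hemodynamic/ventilation outcomes at all six cells, are the
reported stage summaries this package emulates. START means for the gas
outcomes are printed nowhere and are back-computed from the reported
relative changes (e.g. START PCV Paco2 = 48.4/1.28 ≈ 37.8 mmHg); the
back-computation is internally consistent with the reported post-CP values
(37.8 × 1.19 ≈ 45.0 vs 44.6 printed). Absolute levels of Raw, G, H and
Qs/Qt were reported only graphically, so their defaults are stated rabbit
physiology: H = 200 cmH2O/L (which makes a 7 mL/kg breath cost ≈ 5.5 cmH2O
of driving pressure, matching the reported 5.4 ± 0.8), G = 40 (η = 0.2),
Raw = 20 cmH2O·s/L, baseline shunt 0.08 — each carrying the reported
relative stage changes (G and H +65% at CP with η constant; shunt +32%
PCV / +61% VV). These four outcomes are explicitly configurable
assumptions and are excluded from acceptance-level moment checks.

## What the generator does and does not emulate

It reproduces: the crossover design and its within-subject correlation,
stage-dependent means and dispersions, mechanics–oxygenation coupling at
CP, and raw oscillometry signals whose ground truth is each record's
mechanical state seen through the tracheal tube (proportional Gaussian
noise on both channels). It does **not** emulate: CO2 absorption kinetics,
hemodynamic–ventilation coupling, period/carryover effects, non-Gaussian
tails, or drift within a stage. A green test therefore establishes that the
pipeline recovers what this stated world contains — not that the world is
complete.

# Statistics

The analysis is the classical two-way within-subject ANOVA: each effect
(mode, stage, interaction) is tested against its own subject-interaction
error term. Sphericity is assessed with Mauchly's test on orthonormal
contrast scores — stage scores from mode-averaged data, interaction scores
from the Kronecker contrast of the six cells — and Greenhouse–Geisser and
Huynh–Feldt epsilons adjust the degrees of freedom; the two-level mode
factor is spherical by construction (W = 1, ε = 1). The decomposition is
computed from first principles; base R's `aov` and `mauchly.test` are used
in the test suite as independent references (agreement to 1e-8 on F and to
1e-10 on W and ε). Shapiro–Wilk (cell-centered residuals) and
Brown–Forsythe (across cells) are reported as diagnostics and never switch
the test, mirroring how such studies report them.

Post-hoc contrasts are all 15 pairwise cell comparisons per outcome,
treated as one family and adjusted by the Holm–Šidák step-down
$\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m-i+1}$ with monotonicity enforced.
Relative changes from baseline are computed per subject
($100(x_{stage} - x_{START})/x_{START}$), then summarized as mean and
t-based 95% CI — the per-subject-then-average definition (not the ratio of
means) because subject-level intervals are what crossover studies report;
t-based rather than bootstrap intervals were chosen as the simplest method
consistent with the reported format. Note the mean per-subject ratio
carries a small Jensen term ($\approx \sigma^2/\mu^2$ of the baseline,
under 1% here), which is visible when comparing recovered percent changes
with the ratio of configured cell means.

# Orchestration and determinism

`run_study()` chains generation → per-record oscillometry refit → gas
exchange → statistics and optionally writes `cohort.csv`, `fits.json`,
`results.json` and `report.md` (all plain text, no timestamps — byte-stable
for a fixed configuration). The master seed fans out through a
deterministic integer hash (`derive_seed`) into independent streams per
stage, so changing, say, the oscillometry noise level never perturbs the
cohort draws. The analysis consumes the *fitted* mechanics, not the
generating truth, so mechanics results inherit realistic measurement error.
Cohorts of fewer than three subjects complete with an under-powered warning
(the elastance–oxygenation correlation degrades to NA below n = 3).

# Numerical choices, degeneracies, limitations

* Constant outcomes yield F = 0 (not NaN); missing design cells are an
  error, never imputed.
* Shunt targets are clamped to [0.01, 0.9] and solved venous saturations to
  [0.10, 0.98·SaO2] before the recorded shunt is recomputed, so extreme
  residual draws bend toward physiology rather than leaving the domain of
  the Berggren equation.
* Configurations with cell SD > mean/2 warn about truncation bias.
* The grid-oracle comparison in the acceptance suite allows machine-level
  slack (1e-12 of the spectral energy) because the oracle grid's center
  point is the generating truth itself: both costs are numerical zeros on
  noiseless data.
* Known limitations: a single-compartment linear lung (no recruitment
  dynamics, no nonlinear/viscoelastic time-domain tissue model), standalone
  apneic oscillometry windows (no within-breath tracking or coherence
  gating), and a purely statistical — not mechanistic — stage model for the
  cohort.
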