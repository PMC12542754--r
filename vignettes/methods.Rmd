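---
title: "Models and methods: radiotracer rates and spring-water speciation"
author: "springcarb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: radiotracer rates and spring-water speciation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(springcarb)
```

This vignette is the package's own account of the science it implements:
the rate model and its assumptions, the speciation model and the
simplifications it makes, the tunable parameters with their defaults and
why, what the synthetic-data generator does and does not emulate, and
the numerical choices.

## 1. The radiotracer rate model

A microcosm assay adds a known activity of ¹⁴C-labelled substrate
(bicarbonate or acetate) to a sealed bottle of spring water and mat
slurry, incubates it in situ, and counts the label that ended up in
biomass (assimilation, filter capture) or was respired to CO₂
(dissimilation, headspace capture into an absorbent). The estimator is

$$ r = \frac{(\mathrm{DPM}_T - \mathrm{DPM}_K)\; n_{mmol}\; M_C\; \nu_C\; \alpha}
            {\mathrm{DPM}_{added}\; \mathrm{gdw}\; (\mathrm{wt\%C}/100)\; t\; F_s} $$

in mg C (g C)⁻¹ h⁻¹. It is, in words: the fraction of the added label
converted (net of the abiotic retention measured in the HgCl₂-killed
controls), scaled to the total substrate pool — because the organisms
draw on native and labelled molecules alike — converted to a carbon
mass via $M_C \nu_C$, corrected by the isotopic discrimination factor
$\alpha$ for the slower uptake of ¹⁴C relative to ¹²C, and normalised
to incubation time and to the mat carbon in the vial as a biomass
proxy.

**Assumptions.** (i) *Zero-order kinetics*: the fraction of substrate
consumed over a 60-minute assay is small (well under 1% in the default
configuration), so depletion ("bottle effect") is negligible and the
rate is treated as constant. First-order depletion modelling is
deliberately out of scope. (ii) *No decay correction*: ¹⁴C's half-life
is ~5,700 years; over an hour the correction is ~2×10⁻⁸ and ignored.
(iii) *The killed control measures everything abiotic*: adsorption of
tracer to sediment and filter is assumed identical in live and killed
vials, so subtracting the killed mean is unbiased. (iv) $\alpha$ is a
property of uptake biochemistry, applied identically to assimilation
and dissimilation since both route the label through uptake.

**Key parameters.** $\alpha$ defaults to 1.05 (the conventional value
for ¹⁴C uptake discrimination). The µCi→DPM conversion is the
definition of the curie, 2.22×10⁶ DPM/µCi. $F_s$ is 1 for assimilation;
for dissimilation it follows the bottle geometry: a 26.3 mL serum
bottle holding 11.3 mL of liquids/solids leaves a 15 mL headspace, and
a 5 mL syringe draw after expansion samples $5/(15+5) = 0.25$ of the
CO₂ (`headspace_fraction()`). The substrate pool sums the native
concentration carried by spring water + slurry liquid (the slurry is
assumed to carry native substrate at the spring concentration) and the
spike, `activity/specific activity`.

**Uncertainty.** First-order (delta-method) propagation: the DPM
difference contributes an absolute variance
$\sigma_T^2 + \sigma_K^2$ (standard errors of replicate means), every
multiplicative factor contributes its squared relative error. Replicate
variation is typically dominant in field data, and the propagated error
is checked against a 10⁵-draw Monte-Carlo standard deviation in the
test suite (agreement within 10% at input CVs ≤ 10%, where the
linearisation is accurate). A negative net DPM is reported as a
negative rate with `distinguishable_from_zero = FALSE` rather than
clipped: clipping would bias the light-minus-dark difference.

**Treatment contrast.** The field question is whether light drives
assimilation. The package uses the difference of light and dark rates
with errors in quadrature, and a *one-sided Welch t-test* on
per-replicate rates at α = 0.05. Welch was chosen because triplicate
groups with different mean DPM have no reason to share a variance; the
one-sided alternative matches the directional hypothesis (phototrophy
adds to, never subtracts from, dark assimilation). Degenerate
zero-variance groups get p = 0.5/0/1 by the sign of the difference
instead of a division by zero.

## 2. Aqueous speciation and charge balance

The speciation model distributes each measured component total over its
acid–base species by mass action, with two ingredients:

- **pKa(T)**: van 't Hoff correction from 25 °C reference values using
  a reaction-enthalpy proxy, except the two carbonate dissociations,
  which use empirical log K(T) polynomials (accurate to a few 0.001 pK
  units over 0–50 °C, where a constant-enthalpy extrapolation drifts).
  Defaults at 25 °C: acetate 4.756, formate 3.745, HSO₄⁻ 1.99,
  carbonate pK₁ 6.35, pK₂ 10.33, NH₄⁺ 9.25, HF 3.17 — all overridable
  via `acid_base_couples(overrides = ...)`.
- **Activity coefficients**: the extended Debye–Hückel equation
  $\log_{10}\gamma = -A z^2 \sqrt{I}/(1 + B a \sqrt{I})$ with A and B
  computed from the density and dielectric constant of water at the
  sample temperature, and Kielland ion-size parameters. Neutral species
  get γ = 1. pH is −log₁₀ of the H⁺ *activity*; concentrations entering
  ionic strength and charge balance are activity/γ.

Because γ depends on the ionic strength and the ionic strength on the
speciation, the two are iterated to a fixed point (relative tolerance
10⁻¹⁰ on I, maximum 100 iterations; these dilute waters converge in a
handful). Charge imbalance is reported as the field convention percent
of mean charge, 100·(Σ cations − Σ anions)/(½(Σ cations + Σ anions))
in equivalents, and the charge-balance pH is found by bisection on
pH ∈ [0, 12] — the imbalance is strictly decreasing in pH, so a
bracketing sign change guarantees a unique root; iteration stops when
|CI| < 10⁻⁶ %.

**What is deliberately left out** (and its consequence): ion-pair
complexes (CaSO₄⁰, MgSO₄⁰, FeSO₄⁰ …), redox speciation, dissolved
sulfide (negligible charge below pH 6, as H₂S's first pKa is ~7),
silica (neutral below pH ~9), mineral saturation and any full
equation-of-state treatment of the equilibrium constants. Full
speciation codes used for field campaigns include these; the practical
consequence is that charge imbalances and calculated pH values computed
here are approximate at the few-percent / few-hundredths-of-a-pH-unit
level. That is sufficient to flag an erroneous field pH (a −67%
imbalance is unmistakable) and to reproduce calculated pH values to
±0.1, but *exact* reproduction of sub-percent imbalances — small
differences of large sums — is not promised. Molarity is treated as
molality (ionic strength < 0.02 mol/kg: the density correction is below
0.2%).

## 3. The isotope and elemental budget

Δ¹³C is defined as the simple delta difference
δ¹³C(mat) − δ¹³C(DIC), matching how such field tables are computed,
rather than the exact fractionation ε = 1000(α−1); at −23‰ the two
differ by ~0.08‰, below the measurement error. Errors combine in
quadrature. The molar C:N ratio is (wt%C/12.011)/(wt%N/14.007) with
relative errors in quadrature. δ¹⁵N is carried through unchanged — no
derived quantity consumes it. Report formatting rounds only at
presentation (one decimal for ‰, two significant figures for errors);
stored values are never rounded.

## 4. The synthetic-experiment generator

`microcosm_config()` + `simulate_microcosms()` generate a complete vial
table with known ground truth. The generator inverts the rate equation
to get the expected biomass (or headspace) DPM for a vial's true rate,
adds the abiotic adsorption that the killed controls measure, and
observes Poisson-distributed gross counts over the counting window —
Poisson because scintillation counting literally counts decay events.
Vial-to-vial biological variability multiplies each live vial's true
rate by a mean-one log-normal factor.

The defaults *are* the field design the package targets: triplicate
light/dark/killed treatments, 60-minute incubation, a 5.3 µCi
bicarbonate spike at 54 mCi/mmol (0.71 µCi at 110 mCi/mmol for
acetate), 10 mL spring water + 1 mL slurry + 0.2 mL spike + 0.1 mL
amendment, 11 mM native DIC, and true light/dark rates of 7 and 0.5
mg C (g C)⁻¹ h⁻¹. Where the field study does not publish a value, a
realistic one was chosen once and documented: 20 ± 2 mg dry mat per
vial (the ±10% reflecting slurry aliquot heterogeneity across six
weighed aliquots), 9.11 ± 0.07 wt% C, 5% analytical error on native
DIC, 1% on the spike activity, counting for 10 min at 90% efficiency
over a 30 CPM background, 500 DPM killed-control adsorption, and a 15%
biological CV. These are instrument-typical numbers, not fits.

**What the simulator does not emulate** — and hence what passing
recovery tests do and do not show: no isotopic exchange with headspace
CO₂ during incubation, no time-resolved kinetics (a single endpoint),
no spatial heterogeneity of the mat beyond the log-normal rate
multiplier, no counting-efficiency drift within a run. Recovery tests
therefore validate the *estimator* (bias, error calibration, test
size), not the field protocol itself.

Determinism: all randomness flows from the single `seed` argument
through R's RNG; equal configurations and seeds are bit-identical.

```{r recovery, eval = FALSE}
# the calibration experiment run by the acceptance suite (100 seeds):
cfg <- microcosm_config(true_light_rate = 7.5, true_dark_rate = 0.5)
est <- vapply(1:100, function(s)
  recover_rates(simulate_microcosms(cfg, seed = s), cfg)$contrasts$rate,
  numeric(1))
# mean(est) recovers the light-driven truth of 7 to well within 5%
```

## 5. Numerical choices and degenerate inputs

- Quench curve: monotone piecewise-linear interpolation, clipped to the
  calibrated range (no extrapolation — efficiency beyond the calibrated
  ends is unknowable and clipping is conservative). No functional form
  is imposed because instruments differ.
- Below-background counts convert to 0 DPM, not negative.
- Missing killed controls: rates are computed against zero abiotic
  retention and flagged with a warning rather than refused — a
  field-sample reality.
- Single-replicate designs: rates are computed; the Welch test is
  reported as unavailable (`p = NA`).
- Pure water (an all-zero composition) balances at the neutral pH of
  Kw(T), which the solver returns; `charge_imbalance()` errors only if
  the total charge is identically zero.
- A composition whose imbalance does not change sign over pH 0–12
  cannot be balanced by pH alone; the solver reports the endpoint
  imbalances instead of silently returning a bracket end.
- Problem sizes in the shipped tests: Monte-Carlo error checks use
  10⁵–2×10⁵ draws; recovery calibration uses 100 seeds of the
  triplicate design; speciation property tests sweep the four bundled
  field samples and 25 perturbed variants. The whole suite runs in well
  under a minute.

## 6. Known limitations

- The activity model is valid to I ≈ 0.1 mol/kg; brines are out of
  scope.
- No ion pairs or redox couples (see §2): sub-percent charge imbalances
  are approximate.
- The rate estimator assumes the killed control is an unbiased abiotic
  blank; processes that only occur in live vials but are not metabolic
  (e.g. surface adsorption enhanced by biofilm) would bias rates high.
- The Welch contrast treats replicate rates as independent; shared
  nuisance errors (one gdw measurement for all vials) are handled in
  the propagated error of the mean rates, not in the test.
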