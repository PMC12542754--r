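# springcarb

Quantifying microbial carbon metabolism in acidic hot springs from in
situ radiotracer microcosms, together with the aqueous geochemistry
needed to interpret the habitat.

## The problem

Warm, acidic, moderately sulfidic springs host mats of the acidophilic
purple nonsulfur bacterium *Rhodopila globiformis*, an anoxygenic
phototroph whose ecology is poorly constrained by culture work. Two
field measurements carry most of the quantitative load in such studies:

1. **Carbon transformation rates** from ¹⁴C-spiked microcosms: serum
   bottles of spring water and mat slurry amended with NaH¹⁴CO₃ or
   ¹⁴C-acetate, incubated in the spring in the light, in the dark, and
   poisoned (killed controls), then counted by liquid scintillation.
2. **Water chemistry**: major ions, DIC, organic acids and stable
   isotope ratios, from which the speciation of the carbon pool, the
   internal consistency of the analysis (charge balance) and the
   biomass–DIC isotope fractionation are derived.

`springcarb` implements both halves as a tested, reusable pipeline, plus
a synthetic-experiment generator so the whole estimator can be validated
by parameter recovery without any field data.

## The estimator

Counts are converted to disintegrations per minute through a quench
curve (piecewise-linear counting-efficiency calibration), and the
zero-order substrate conversion rate is

```
rate = (DPM_T − DPM_K) · mmol · M_C · ν_C · α
       ─────────────────────────────────────────────
       DPM_added · gdw · (wt%C/100) · t · F_s
```

in mg C (g C)⁻¹ h⁻¹, where `DPM_T` and `DPM_K` are the mean treatment
and killed-control DPM, `mmol` the total (native + labelled) substrate
pool, `M_C` the molar mass of carbon, `ν_C` the carbons per substrate
molecule, `α` = 1.05 the ¹⁴C isotopic discrimination factor,
`DPM_added` the activity added, `gdw` and `wt%C` the dry mass and
carbon content of the mat in the vial, `t` the incubation time and
`F_s` the fraction of converted label sampled for counting (1 for
filter-captured assimilation, 0.25 for a 5 mL headspace draw in the
dissimilation variant). Uncertainty is first-order propagation over
every uncertain input, with the replicate variation of the microcosms
as the dominant term; light-driven rates are light minus dark with
errors in quadrature and a one-sided Welch test.

The geochemistry half resolves measured totals into species (carbonate
system, bisulfate, organic acids, ammonium, fluoride) using
temperature-corrected dissociation constants and extended Debye–Hückel
activity coefficients iterated to self-consistency with the ionic
strength, reports the charge imbalance as a percent of mean charge, and
solves for the charge-balance pH by bisection.

## Worked example

Simulate the default field design (triplicate light/dark/killed 60-min
bicarbonate assay, 5.3 µCi spike at 54 mCi/mmol into an 11 mM DIC
spring water, true light/dark rates 7 and 0.5 mg C (g C)⁻¹ h⁻¹) and
recover the rates:

```r
library(springcarb)
cfg   <- microcosm_config()
vials <- simulate_microcosms(cfg, seed = 42)
fit   <- recover_rates(vials, cfg)
fit
#> Radiotracer carbon transformation rates (mg C (g C)^-1 h^-1)
#>
#>  substrate   assay_mode treatment n dpm_mean dpm_se net_dpm  rate    se distinguishable
#>        DIC assimilation     light 3   104700   7480  104200 7.430 0.840            TRUE
#>        DIC assimilation      dark 3     8343    936    7835 0.558 0.063            TRUE
#>
#> Light-driven (light minus dark) rates:
#>  substrate   assay_mode     contrast rate   se p_value significant
#>        DIC assimilation light - dark 6.87 0.84 0.00269        TRUE
```

The recovered light-driven rate (6.87 ± 0.84) estimates the configured
truth (6.5): the light vials converted ~0.9% of the added label, the
dark vials ~0.07%, and the Welch test flags the contrast as a real
light effect.

Derived water-chemistry quantities for the bundled field samples:

```r
render_report(spring_waters()$Amphitheater_2017)
#> Derived quantities for 'Amphitheater_2017'
#> ------------------------------------------------
#> Delta13C (mat - DIC), permil: -22.9 ± 0.2
#> Mat C:N, mol:mol: 8.08 ± 0.08
#> Charge imbalance at field pH 3.76: +0.38%
#> Charge-balance pH: 3.77
#> CO2(aq) fraction of DIC at pH 3.77: 99.7%
```

A Δ¹³C near −23‰ between mat biomass and DIC is the fingerprint of
Calvin-cycle carbon fixation; the near-zero charge imbalance says the
ion analysis is internally consistent; and at pH 3.77 essentially the
whole DIC pool is dissolved CO₂, the form that crosses membranes
passively.

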