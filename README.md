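# photolim

Quantitative analysis of photosynthetic limitations in C3 (rice, wheat)
and C4 (maize) cereal leaves under water deficit (WD), high growth
temperature (HT) and their combination (HT-WD).

`photolim` takes leaf-level gas-exchange, chlorophyll-*a* fluorescence and
Rubisco biochemistry records and turns them into the quantities plant
ecophysiologists use to ask *where* photosynthesis is being lost under
stress: is CO2 failing to reach the chloroplast (stomatal and mesophyll
diffusion), or has the carboxylation machinery itself been impaired
(Rubisco amount and activation state)?

## What it computes

**Fluorescence.** PSII operating efficiency and linear electron transport:

    ΦPSII = (Fm′ − Fs) / Fm′        J = ΦPSII · PPFD · α · β

with leaf absorbance α (≈0.86–0.87 for these species) and PSII
partitioning β (0.5 for the C3 species, 0.4 for maize).

**C3 diffusion (variable-J method).** Gross assimilation
AG = AN + Rdark/2, chloroplast CO2 from the RuBP-regeneration-limited
inversion

    Cc = Γ* · (J + 8(AN + Rd)) / (J − 4(AN + Rd))

and mesophyll conductance gm = AN / (Ci − Cc). Records violating the
J > 4(AN + Rd) feasibility condition are flagged and excluded, not
clipped.

**C4 bundle-sheath CO2.** With gm and gbs held constant in maize, the
mass balance Cm = Ci − AN/gm, Vp = Vpmax·Cm/(Cm + Kp),
Cs = Cm + (Vp − AN − Rm)/gbs, alongside a rectangular-hyperbola
description of each AN–Ci curve.

**Biochemical Vcmax.** From the ¹⁴C assay (15.54 kBq μmol⁻¹ bicarbonate,
60 s reaction) and gel densitometry:

    Vcmax = [Rubisco] · (8 sites / 550 kDa) · activation state · kcat

with kcat = 2.1, 2.2 and 4.1 s⁻¹ for rice, wheat and maize at 25 °C, and
activation state = initial/total carboxylase activity.

**Limitation partition (Grassi–Magnani).** Relative to the control
treatment, the decline of AG is split into stomatal (SL), mesophyll (MCL)
and biochemical (BL) components using reference-point weights built from
gs, gm and the Rubisco-limited slope ∂A/∂Cc; DL = SL + MCL by
construction. Uncertainty is propagated by a bootstrap over replicates.

**Statistics.** Factorial fixed-effects ANOVA
(species × irrigation × temperature), Duncan's multiple range test
(studentized-range based, P < 0.05) and the trait–trait regressions
(AN vs activation state, activation state vs J).

A synthetic-experiment generator builds complete factorial datasets
through the same forward models, so every inverse stage can be tested
against known ground truth without any external data.

## Worked example

```r
library(photolim)

activation_state(0.31, 0.36)                      # rice control activities
#> [1] 0.8611111
activity_from_counts(assay_raw(0.4662, tsp_conc = 10))
#> [1] 0.3                                        # umol CO2 mg-1 TSP min-1

exp <- generate_experiment(seed = 1)              # 3 species x 4 treatments x 5
lf  <- derive_c4(derive_c3(add_fluorescence(exp$leaf_records)))
bio <- derive_biochem(exp$biochem)
lim <- analyze_limitations(lf, bio, n_boot = 500, seed = 2)
subset(lim, species == "rice",
       select = c(treatment, SL, MCL, BL, DL, BL_se))
#>   treatment    SL   MCL   BL    DL BL_se
#> 1        WD 0.125 0.073 0.21 0.198 0.015
#> 2        HT 0.011 0.037 0.64 0.048 0.016
#> 3     HT-WD 0.148 0.105 0.78 0.253 0.025
```

Reading the table: under WD the diffusive limitation (DL ≈ 0.20) and the
biochemical one (BL ≈ 0.21) contribute similarly in rice, while under HT
and HT-WD the biochemical term dominates — the pattern expected when high
temperature halves the Rubisco activation state while leaving
conductances largely intact.

One call runs everything and writes the CSV outputs plus a JSON manifest
recording seeds, constants and their provenance:

```r
simulate_and_run("out/", seed = 1)
```

A thin command-line wrapper is installed at
`inst/cli/photolim.R` (`simulate` and `run-all` subcommands).

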