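---
title: "Models and methods behind photolim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photolim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photolim)
```

`photolim` implements a complete analysis chain for leaf-level
photosynthesis under water deficit and high-temperature stress in rice,
wheat and maize: fluorescence-derived electron transport, diffusional CO2
transfer into the chloroplast (C3) or bundle sheath (C4), biochemical
reconstruction of the maximum carboxylation rate, and the partition of
the photosynthetic decline into stomatal, mesophyll and biochemical
components. This vignette explains the models, the tunable parameters
and their defaults, the synthetic-data generator used for validation,
and the numerical and design choices a maintainer should know about.

## The experimental design the package assumes

Three species (rice and wheat, C3; maize, C4) are crossed with two
irrigation levels (well-watered, WW; water deficit, WD) and two growth
temperatures (25 °C control; 38 °C, HT), giving the four treatment
labels control, WD, HT and HT-WD, with 4–5 replicate plants per cell.
The WD treatment is defined operationally: a plant counts as
water-stressed once its stomatal conductance `gs` has fallen by at least
40% relative to the well-watered mean. All gas exchange is measured at
25 °C leaf temperature, saturating light (PPFD 1500 µmol m⁻² s⁻¹) and
ambient CO2 of 400 µmol mol⁻¹; all kinetic constants refer to 25 °C and
no temperature-response functions are applied anywhere.

## Fluorescence and electron transport

PSII operating efficiency is the Genty-type ratio
`ΦPSII = (Fm′ − Fs)/Fm′`, and linear electron transport is
`J = ΦPSII · PPFD · α · β`. The leaf absorbance `α` is a numeric input
(measured values for these species cluster at 0.86–0.87); the
photosystem partitioning fraction `β` is fixed by photosynthetic type —
0.5 for the C3 species and 0.4 for maize — because that is how the
underlying experiment treated it. Each record carries its own `α` and
`β`, so per-record overrides are possible.

## C3 diffusion: the variable-J method

Gross assimilation is `AG = AN + Rdark/2`: half of the pre-dawn dark
respiration is assumed to persist in the light. The daytime
mitochondrial respiration `Rd` used *inside* the variable-J formula
follows the same convention (`Rd = rd_fraction · Rdark`,
`rd_fraction = 0.5` by default, configurable). The source experiment
measured only pre-dawn `Rdark` and did not state its daytime convention,
so this choice is explicit in the run manifest.

The chloroplast CO2 concentration comes from inverting the
RuBP-regeneration-limited (Harley-type) assimilation equation with the
fluorescence-derived J:

$$C_c = \Gamma^* \frac{J + 8(A_N + R_d)}{J - 4(A_N + R_d)},$$

and mesophyll conductance from the drawdown, `gm = AN/(Ci − Cc)`. The
inversion only makes sense when `J > 4(AN + Rd)`; records failing that
test (or yielding `Cc ≥ Ci`) are flagged `infeasible` and excluded from
treatment means rather than clipped, because clipping would silently
bias `gm` downward. The count of such records is reported in the
manifest.

`Γ*`, `Kc`, `Ko` and the oxygen mole fraction are not measurable from
the package's inputs; they default to the standard tobacco-derived 25 °C
set (`Γ* = 42.75` µmol mol⁻¹, `Kc = 404.9` µmol mol⁻¹,
`Ko = 278.4` mmol mol⁻¹, `O = 210` mmol mol⁻¹). Every constant carries a
provenance flag — `paper` (the measured kcat values), the
`literature-default` set above, or `user` for overrides — so a reader of
the manifest can always see which numbers were assumptions. The
forward FvCB model (`fvcb_forward()`) exists to close the loop: leaves
simulated with it at known `gm` must be recovered exactly by the
variable-J chain, which is the package's core self-test.

## C4 (maize): bundle-sheath CO2 with constant conductances

Maize's carbon-concentrating mechanism is handled with a deliberately
reduced von Caemmerer-type balance in which both the mesophyll
conductance `gm_c4` (default 1.0 mol m⁻² s⁻¹) and the bundle-sheath
conductance `gbs` (default 0.01 mol m⁻² s⁻¹) are constants:

* mesophyll CO2: `Cm = Ci − AN/gm_c4`;
* PEP carboxylation: `Vp = Vpmax·Cm/(Cm + Kp)` with defaults
  `Vpmax = 120` µmol m⁻² s⁻¹, `Kp = 80` µmol mol⁻¹;
* mesophyll respiration: `Rm = Rm_fraction · Rdark`, default 0.5, the
  common convention in the C4 modelling literature;
* bundle-sheath CO2: `Cs = Cm + (Vp − AN − Rm)/gbs`, with the leak rate
  `gbs·(Cs − Cm)`.

Because the exact variant of the C4 model used upstream is not
recoverable, `Vp` can alternatively be taken from the fitted AN–Ci
hyperbola's initial slope (`vp_source = "hyperbola"`), using
`(Amax/K)·Cm`; the Michaelis form is the default. A sensitivity argument
supports the constant-conductance simplification: the bundle-sheath CO2
is so large (thousands of µmol mol⁻¹) that the downstream Rubisco-limited
rate is insensitive to moderate errors in `gm_c4` or `gbs`.

The biochemical analysis of maize is restricted to C3-cycle (Rubisco)
activity: the forward model is the Rubisco-limited rate evaluated at
`Cs`, and no PEPC/PPDK limitation is partitioned.

Each AN–Ci curve is also summarised by a rectangular hyperbola
`AN = Amax·Ci/(K + Ci)`. The fit profiles the 1-D residual sum of
squares over `K` (given `K`, `Amax` is a linear least-squares
coefficient) and then polishes with Levenberg–Marquardt when that
improves the fit. The profiled form cannot fail to converge and handles
the degenerate flat-plateau curve (all AN equal), which drives `K` to
its lower boundary and is flagged rather than trusted.

## Rubisco biochemistry

The ¹⁴C assay arithmetic converts acid-stable counts to activity:
µmol CO2 fixed = counts(kBq)/15.54 (kBq µmol⁻¹), scaled to a per-minute
rate by `60/reaction_time` (the protocol quenches at 60 s) and
normalised by the TSP in the 10 µL aliquot. The activation state is the
initial/total activity ratio; values in (1, 1.05] are treated as
measurement noise and clipped to 1 with a warning, larger excesses are
an error, because initial activity cannot biochemically exceed total.

Rubisco amounts come from gel densitometry against purified-Rubisco
standards (linear calibration, minimum R² 0.95, 15 µg TSP per lane), and
Rubisco activase from immunoblots normalised per µg TSP against the
5/10/15 µg serial dilution of a control extract run on the same blot
(control = 1), separately for the large and small isoforms.

The biochemical maximum carboxylation rate is

$$V_{cmax} = [\mathrm{Rubisco}]\;(\mathrm{g\,m^{-2}})
  \cdot \frac{8\ \mathrm{sites}}{550\,000\ \mathrm{g\,mol^{-1}}}
  \cdot \mathrm{activation\ state} \cdot k_{cat},$$

with kcat 2.1/2.2/4.1 s⁻¹ for rice/wheat/maize at 25 °C. Converting
per-TSP amounts to a leaf-area basis needs TSP per leaf area, which the
source data do not provide; the pipeline accepts a measured `tsp_area`
column or a config constant (default 6 g TSP m⁻², a mid-range value for
herbaceous leaves) and records which path was used.

## The limitation partition

Following the Grassi–Magnani approach, the reference (control) operating
point defines weights

$$l_s = \frac{(g_{tot}/g_s)\,\partial A/\partial C}{g_{tot} + \partial A/\partial C},\qquad
  l_{mc} = \frac{(g_{tot}/g_m)\,\partial A/\partial C}{g_{tot} + \partial A/\partial C},\qquad
  l_b = \frac{g_{tot}}{g_{tot} + \partial A/\partial C},$$

with `g_tot = (1/gs + 1/gm)⁻¹` (gs converted from H2O to CO2 basis by
1.6) and the Rubisco-limited slope
`∂A/∂C = Vcmax(Γ* + Km)/(C + Km)²`, `Km = Kc(1 + O/Ko)`, evaluated at
the reference `Cc` (C3) or `Cs` (maize). The weights sum to one as an
algebraic identity. Stress components are

$$S_L = l_s\,\Delta\ln g_s,\quad MC_L = l_{mc}\,\Delta\ln g_m,\quad
  B_L = l_b\,\Delta\ln V_{cmax},$$

with `Δln x = ln x_ref − ln x_stress`. The log-difference form was
chosen because it composes exactly (a 50% drop applied in two steps
gives the same answer as in one) and its total approximates the *log*
decline of AG; for small perturbations it equals the relative decline to
first order, and `1 − exp(−total)` converts it to the relative-decline
scale for deep stress. The raw-fractional variant
(`method = "fraction"`), which tracks the relative decline directly, is
available for sensitivity checks. Components that come out negative
(a factor improved under stress, e.g. the higher activation state of
WD maize) are clipped to zero with a warning; `DL = SL + MCL` holds
exactly in every output row. For maize the mesophyll conductance is the
constant `gm_c4`, so `MCL` is structurally zero and diffusive limitation
is carried by the stomatal term.

The decomposition runs on treatment means (n = 4–5 replicates);
uncertainty is propagated by a nonparametric bootstrap over replicates
within the stressed and control cells (default 2000 resamples, seeded).
Gas-exchange leaves and biochemistry disks are different physical
samples of the same plants, so replicate-level Vcmax enters through the
treatment mean rather than by pairing.

## Statistics

The factorial ANOVA treats species, irrigation and temperature as fixed
factors with all interactions. Balanced designs use the sequential
sum-of-squares partition, which is exact and order-invariant there;
unbalanced designs (replicate loss) fall back to Type II sums of squares
via `car::Anova` with a logged warning — the design itself does not
dictate an SS type for unbalanced data, so the choice is explicit.

Duncan's multiple range test compares pairs spanning *p* ordered means
against the least significant range
`LSR_p = q(α_p, p, df)·√(MS_res/n)` at the protection level
`α_p = 1 − (1−α)^(p−1)`, with the studentized-range quantile obtained
from `stats::qtukey` (numerical inversion of the studentized range
distribution, which the historical printed tables tabulate). The
standard containment rule applies — a range declared non-significant
protects all ranges inside it — and letters are assigned by the sweep
over maximal non-significant spans. Unequal group sizes use the harmonic
mean n with a warning. The test suite checks the grouping against an
independent recursive implementation of the stepwise procedure on 200
random instances.

## The synthetic-data generator

`generate_experiment()` emulates the factorial design so that every
inverse stage has recoverable ground truth. Control-treatment means for
the biochemistry are the published control values (Rubisco amount
0.49/0.34/0.15 mg mg⁻¹ TSP; initial activities 0.31/0.19/0.08 and total
activities 0.36/0.44/0.13 µmol mg⁻¹ min⁻¹ for rice/wheat/maize), which
also fix the implied control activation states (0.861, 0.432, 0.615).
Conductance and respiration means (gs 0.35/0.30/0.20 mol H2O m⁻² s⁻¹,
gm 0.30/0.25 mol m⁻² s⁻¹, Rdark 1.5 µmol m⁻² s⁻¹) are typical
well-watered values for chamber-grown cereals at saturating light; the
replicate-level gs/gm/AG table of the source experiment is not publicly
available, so these are documented plausible placeholders, chosen once.

Treatment effects are multiplicative and reproduce the qualitative
stress pattern: WD halves `gs` in every species (satisfying the ≥40%
reduction that defines the treatment, enforced as a config invariant)
and depresses `gm` in the C3 species and Rubisco amount in rice and
maize, with a *higher* activation state in WD maize; HT halves the
activation state in all species; HT-WD multiplies both effect sets.
Replicate noise is multiplicative log-normal (positivity-preserving,
median-preserving, truncated at ±3σ) with CVs of 5–10% by quantity.

Generation is forward-model consistent: sampled gs, gm and biochemical
Vcmax are pushed through the Rubisco-limited steady state (C3) or the
constant-conductance C4 balance (maize), and the electron transport
assigned to each leaf is the one consistent with its operating point,
`J = 4(AN + Rd)(C + 2Γ*)/(C − Γ*)`. Fluorescence is generated backwards
from that J (Fm′ uniform in 0.5–0.8, Fs solved), so the fluorescence
stage has nontrivial inputs with known truth. Maize additionally gets an
8-point AN–Ci curve per replicate by re-solving the steady state over an
ambient-CO2 grid, with Gaussian observation noise (σ = 0.3 µmol m⁻² s⁻¹
by default).

What passing tests on these data do **not** show: the generator draws
from the same model family the pipeline inverts, so recovery tests
validate the algebra and the code, not the physiological adequacy of
the variable-J or constant-conductance assumptions on real leaves. Real
data add patchy stomatal closure, fluorescence-gas-exchange mismatch in
the sampled leaf area, temperature drift and non-steady states, none of
which are emulated.

## Numerical choices and degenerate inputs

* Steady states are solved with `uniroot` at tolerance 1e-12; the C4
  root lies close to the `Cs > 0` feasibility edge at low CO2, so the
  upper bracket is found by bisecting toward that edge before root
  finding.
* Negative net assimilation yields `AG = 0` with a warning (a sanity
  guard for faulty records); such records are never used for `gm`
  estimation.
* CSV output is written at 17 significant digits so write–read round
  trips are lossless for doubles, which is what makes byte-identical
  reruns possible.
* The run manifest records the config hash (FNV-1a), seed, every
  constant with provenance, the Rd convention, infeasible-record counts
  and all warnings, so a run can be audited and reproduced exactly.

## Problem sizes

The validation suite and the acceptance script use 50-leaf noiseless
recovery batches for the C3 and C4 inversions, 200 random instances for
the Duncan-vs-oracle comparison, 200 simulated factorial experiments
(n = 5) for the ANOVA power check on the halved activation state, and
bootstrap sizes of 200–2000 depending on context. These sizes keep the
whole suite comfortably fast on a single CPU while leaving sampling
error far below the tolerances being checked.

## Known limitations

* All constants are 25 °C values; the package deliberately has no
  temperature-response machinery, matching the measurement protocol.
* `Γ*` inside the variable-J formula is a literature default; the
  provenance flags make the choice visible rather than guessing what any
  particular instrument export assumed.
* The C4 limitation partition excludes C4-cycle enzymes (PEPC, PPDK) by
  design.
* Gel images are not processed; densitometry readings are numeric
  inputs.
* The bootstrap treats replicates as exchangeable within treatment;
  there is no repeated-measures or pot-level structure.
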