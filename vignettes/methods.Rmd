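---
title: "Balance-based analysis of oxygen contamination in closed gas-recirculation fermenters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balance-based analysis of oxygen contamination in closed gas-recirculation fermenters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(o2balance)
```

## The system and the problem

Anaerobic chain-elongation fermenters convert lactate, acetate and H~2~/CO~2~
into medium-chain carboxylates such as *n*-caproate, with hydrogenotrophic
methanogens as a competing H~2~ sink. When the whole gas phase is recirculated
through a closed external reservoir, every gas species becomes balanceable:
nothing leaves the loop, refills are logged, and an inert tracer (He) ties
fractions to absolute amounts. This package implements the quantitative
machinery such a system enables:

* a **He-dilution estimate** of the total system gas volume,
* an **indirect O~2~ contamination estimate** from the N~2~ fraction of the
  loop, exploiting the fixed 3.73 N~2~:O~2~ volumetric ratio of air,
* **dilution-corrected volumetric rates** for the liquid phase of a CSTR,
* a **degree-of-reduction electron ledger** with a percent closure error,
* **test-vs-control contrast tables**, and
* **rarefaction + significance-masked Spearman correlation** of genus counts
  against process rates.

Because raw time series from real campaigns are rarely published, the package
ships a **stoichiometric reactor simulator** that reproduces the operating
regime (1 L CSTR, HRT 14 d, 133 mM lactate + 200 mM acetate feed, closed loop
refilled with 10 L H~2~:CO~2~ 80:20, 240 mL ethylene, 120 mL He) and provides
exact ground truth for every estimator. All development-time guarantees are
statements about this synthetic system.

## Conventions

**Units.** Liquid concentrations in mM, rates in mmol L⁻¹ d⁻¹ (production
positive). Gas amounts are tracked internally in mmol and exchanged with the
user in mL at 0 °C and 101.325 kPa, i.e. 22.414 mL/mmol (`ML_PER_MMOL`). The
literature mixes mL- and mmol-based statements; one declared reference makes
the conversions bit-stable.

**Compounds.** Carboxylates are registered as neutral free acids (lactic,
acetic, ... caprylic acid) for molar mass and electron accounting; speciation
and charge are ignored, which is what makes "12 g/L = 133 mM lactate"
arithmetic work. The degree of reduction is the standard
γ = 4C + H − 2O − 3N on the free-acid formula (ammonia-N reference), so
γ(CO~2~) = γ(H~2~O) = 0 and γ(O~2~) = −4: oxygen enters ledgers as
electron-*accepting* capacity. Biomass, when enabled, uses the generic
CH~1.8~O~0.5~N~0.2~ (γ = 4.2); it is excluded by default because optical
density was monitored but biomass was never stated to enter the balances.
Ethylene (the methanogenesis inhibitor) is registered but inert: no
consumption is ever booked.

**Reaction balancing.** `balance_reaction()` solves unknown stoichiometric
coefficients from element conservation (C, H, O, N, He) and verifies that the
electron balance closes as well. One subtlety is documented rather than hidden:
for lactate disproportionation
(3 lactate → x propionate + y acetate + z CO~2~ + w H~2~O) element conservation
alone leaves a one-parameter family, because the net equation mixes an
oxidative decarboxylation with a reductive branch. The balancer then returns
the unique minimal non-negative *integer* completion — (2, 1, 1, 1), the
textbook 2:1:1 stoichiometry — and errors when no unique integral solution
exists.

## The simulator

`simulate_reactor()` advances a well-mixed CSTR coupled to a closed gas loop
by explicit Euler steps (Δt = 0.05 d):

* liquid species: dC/dt = Σ ν·extent + D(C_feed − C), with D = 1/HRT;
* gas species are exchanged instantly with the loop (no dissolved pools, no
  CO~2~/bicarbonate speciation);
* air leaks add O~2~ at the scheduled rate and N~2~ at 3.73× it;
* a refill (10 L H~2~:CO~2~ 80:20 + ethylene + He by default) is logged when
  the reservoir total falls below 20 % of the refill volume — **or** when any
  refilled species falls below the same fraction of its own refill share.
  The second clause is an operating rule this package adds: inert CH~4~ and
  N~2~ accumulate in a closed loop and pad the total, so a total-only trigger
  would let the H~2~ carrier run dry while the total still looks healthy.

Process rates are *scenario inputs* (piecewise-constant extents per balanced
reaction), not kinetic laws: the artifact's job is estimator validation, and
study reports provide rates, not kinetics. Feeding is modeled as continuous
(the real regime of ~10 small pulses a day is indistinguishable at HRT 14 d
and Δt = 0.05 d). Reactions flagged `limited` (H~2~ oxidation by intruding
O~2~) are capped each step by their available gas substrates, so a scavenging
capacity *larger* than the leak pins O~2~ at zero — the O~2~-below-detection
regime — instead of driving the reservoir negative; unlimited reactions that
would do so raise an error naming the species and time. Euler stepping with a
negativity guard is deliberate: the dynamics are non-stiff at these rates and
an auditable update rule beats an opaque solver here.

Because every reaction is element-balanced and the stepper books feed,
withdrawal, leaks and refills explicitly, a noiseless run conserves every
element and electron equivalents to floating-point accuracy; the test suite
asserts closure to 1 × 10⁻⁶ relative and exact He retention. Measurement
noise is a separate, seeded step (`apply_noise()`): mean-1 lognormal with
CV 5 % on liquid concentrations, additive sd 0.005 on gas fractions followed
by clipping and renormalization. The 5 % CV is the declared liquid assay
noise; 0.005 absolute is a typical GC repeatability for volumetric fractions.
Both are generator defaults, not tuned quantities.

## Rate estimation

`volumetric_rate()` uses the CSTR accumulation-plus-washout form

r = slope + D·(C̄ − C_feed),

with C̄ the *trapezoidal* time-mean over the period. Two slope modes exist:

* `"endpoint"` (two-point) makes the formula an exact discrete bookkeeping
  identity — on noiseless data it recovers piecewise-constant truth to
  < 0.5 % even across curved exponential approaches;
* `"regression"` (default) replaces the endpoint slope by the least-squares
  slope, which is markedly more stable under measurement noise but carries a
  curvature bias of up to ~2 % when a period starts far from steady state.

Noiseless-recovery guarantees are therefore stated for the endpoint mode and
noise robustness for the regression mode. A practical limit worth knowing:
the relative error of any such estimator scales with σ·D/|r| for a compound
whose background concentration dwarfs its turnover. Acetate fed at 200 mM
with ~3 mmol L⁻¹ d⁻¹ net consumption cannot be recovered to 10 % relative
under 5 % concentration noise; products and the mostly-consumed substrate
(lactate) can, and the recovery tests cover those.

## Gas accounting

With cumulative He additions known from the event log, the system gas volume
is V_gas = He_added / y_He (`estimate_gas_volume()`); each gas sample prefers
a measured volume and falls back to this tracer estimate.

The O~2~ contamination estimator is deliberately indirect — dissolved-oxygen
probes are useless at micro-aeration levels — and reads the *nitrogen* that
must have entered with the air:

rate = (Y₂V_gas,₂ − Y₁V_gas,₁) / (3.73 (t₂ − t₁) V_liquid),

in mL O~2~ L⁻¹ d⁻¹. It is valid when N~2~ is neither formed nor consumed and
O~2~ stays below detection (a 0.1 % threshold attaches a validity warning
otherwise). With per-sample gas volumes the estimator is exactly unbiased on
synthetic data; the classical caveat about leak-driven volume growth applies
to the constant-volume approximation, and the test suite demonstrates that
regime explicitly (bias grows monotonically with the leak when V_gas is held
at its period-start value). Per-interval estimates are averaged
duration-weighted, *retaining* negative intervals — truncating them would
bias the mean upward. The standard error is taken from the anoxic control
reactor, whose per-interval estimates scatter around zero with the same
measurement noise: se = sd(control intervals)/√n_intervals. Under default
noise the resulting ±2 se interval covers the true leak in ≥ 90 % of seeded
replicates.

`gas_species_rate()` differences Y·V_gas across a period and discounts logged
refill additions; `attribute_h2()` splits H~2~ consumption into the
methanogenic share (4 mol H~2~ per mol CH~4~, from the balanced
stoichiometry) and the remainder ("non-CH~4~ H~2~ consumption"), whose molar
ratio to O~2~ consumption is reported against the H~2~-oxidation reference
value of 2.0.

## The electron ledger

`build_ledger()` multiplies each period rate by duration and γ: feed
substrates enter as supply inflows (D·C_feed·T·V·γ) with matching residual
outflows, products leave via withdrawal, reservoir H~2~ consumption is an
inflow, CH~4~ an outflow, and O~2~ ingress books 4 e⁻ per mol as accepted
electrons. The closure error is 100·(out − in)/in with total inflow as the
denominator — "percent of the supplied electron pool" — so a negative error
means unexplained consumption. On noiseless balanced scenarios the error is
< 0.1 %; under default measurement noise it stays within ±3 % in ≥ 90 % of
replicates, the magnitude range a well-run campaign reports (fractions of a
percent to ~1.6 %). Removing any single flow shifts the error by exactly that
flow's signed share, which makes the ledger linear and auditable.

## Contrasts and the report layer

`percent_change()`, `rate_as_pct_of_control()` and `fold_change()` store
unrounded values; only the report layer rounds, half away from zero, to the
integer percent (or one-decimal fold) figures that appear in prose. When a
caller supplies a stated figure that disagrees with its own operands,
`contrast_phrase()` *flags* the discrepancy instead of matching it — fidelity
to arithmetic over typography.

## Community stage

`rarefy_counts()` subsamples every sample without replacement to a common
depth (default: the shallowest sample), seeded, via vegan's rarefaction draw.
Relative abundances are computed *after* rarefaction, and taxa are filtered
to the most abundant by mean relative abundance (default 1 %).
`spearman_matrix()` computes tie-corrected Spearman ρ (Pearson on mid-ranks)
between taxa and process covariates; p-values are two-sided, by seeded
permutation (10,000 draws) below n = 12 paired observations and by the
t-approximation above. Cells with p ≥ 0.01 are masked but keep their ρ; no
multiple-testing correction is applied by default (a raw-p mask is what a
p < 0.01 correlation figure states), with Benjamini–Hochberg available via
`fdr = TRUE`. Constant vectors yield flagged `NA` cells rather than errors.

The synthetic community generator (`generate_community()`) links expected
log-abundance affinely to true process rates through a softmax, with
Dirichlet-multinomial counts at a per-sample depth — enough structure to
validate that a genuinely rate-linked genus survives rarefaction and masking.
It emulates none of the upstream reality of amplicon data (extraction and PCR
bias, chimeras, denoising); passing tests say the *correlation machinery* is
sound, not that taxonomic profiles of real communities are recoverable.
Pairing time-resolved rates with discrete community samples defaults to
period means; same-day pairing is available
(`community_pairing = "same_day"`).

## Orchestration, determinism and problem sizes

`run_pipeline()` chains simulate → liquid rates → gas accounting → electron
ledger → contrasts → community, writing only typed CSV/TSV/JSON tables;
every stage consumes its predecessors' tables, never their formatting.
All randomness flows through explicit seeds in the run config, so identical
config + seeds reproduce outputs byte for byte. The bundled analysis scripts
(`analysis/01_simulate.R` … `06_community.R`) run a 59-day reactor pair with
a 32-day, 220 mL O~2~ L⁻¹ d⁻¹ contamination and a 60-day six-phase campaign
for the correlation stage; the full workflow and the test suite each complete
in well under a minute of compute per stage, with Monte-Carlo checks sized at
100–200 replicates — enough for the ±2–3 % binomial resolution the
assertions need.

## Known limitations

* No kinetics: extents do not respond to substrate or inhibitor levels
  (beyond the hard availability cap), so the simulator cannot emulate
  acclimatization or inhibition dynamics.
* No dissolved-gas pools or pH/speciation; gas transfer is instantaneous.
* The Eq.-style O~2~ estimator inherits its stated validity conditions; in
  the detectable-O~2~ regime it only warns.
* The electron ledger trusts the rate table; a compound measured but missing
  from it silently carries no electrons (the conservation tests catch this
  for simulated data, not for arbitrary real inputs).
* Biomass electrons are excluded by default; enabling them requires a
  biomass rate in the table.
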