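# o2balance

Balance-based analysis of oxygen contamination in anaerobic fermenters with
closed, recirculating gas reservoirs — plus a stoichiometric reactor
simulator that provides ground truth for every estimator.

## The problem

Chain-elongation fermenters convert lactate, acetate and H₂/CO₂ into
medium-chain carboxylates (*n*-caproate, *n*-caprylate), with
hydrogenotrophic methanogenesis (CO₂ + 4 H₂ → CH₄ + 2 H₂O) competing for H₂.
Small air leaks — on the order of 100–500 mL O₂ L⁻¹ d⁻¹ — reshape both the
product spectrum and the community, but dissolved-O₂ probes cannot see them.
When the gas phase is closed and recirculated, indirect accounting can:

* **system gas volume** from an inert He tracer: `V_gas = He_added / y_He`;
* **O₂ contamination rate** from the N₂ that must accompany air (N₂:O₂ =
  3.73 by volume):

  `rate = (Y₂·V_gas,₂ − Y₁·V_gas,₁) / (3.73 · (t₂ − t₁) · V_liquid)`

  in mL O₂ L⁻¹ d⁻¹, with a standard error derived from an anoxic control
  reactor;
* **volumetric production/consumption rates** for the CSTR liquid phase:
  `r = slope + D(C̄ − C_feed)`, D = 1/HRT;
* an **electron ledger** in degree-of-reduction equivalents
  (γ = 4C + H − 2O − 3N; O₂ books 4 e⁻/mol as accepted electrons) with a
  percent closure error;
* **test-vs-control contrasts** (percent and fold changes, unrounded values
  stored, integer percent in reports);
* **rarefaction and significance-masked Spearman correlation** of genus
  counts against process rates (p < 0.01, permutation p-values at small n).

Intended users are bioprocess researchers running (or reviewing) gas-tight
fermentation campaigns who want the balance arithmetic reproducible, and
method developers who need a ground-truth generator to validate such
estimators.

## Worked example

Simulate a contaminated reactor (1 L, HRT 14 d, 133 mM lactate + 200 mM
acetate feed; air leak of 220 mL O₂ L⁻¹ d⁻¹ on days 27–59, scavenged by H₂
oxidation), overlay measurement noise, and estimate the leak back:

```r
library(o2balance)

rs <- data.frame(
  reaction = c("methanogenesis", "elongation_c4", "elongation_c6",
               "h2_oxidation"),
  t_start = c(0, 0, 0, 27), t_end = c(59, 59, 59, 59),
  extent  = c(16.5, 3.63, 2.12, 25))
leak <- data.frame(t_start = 27, t_end = 59, o2_rate = 220)
sc   <- reactor_scenario(duration = 59, rate_schedule = rs,
                         leak_schedule = leak)
traj <- simulate_reactor(sc)
obs  <- apply_noise(traj, seed = 1)

period <- rate_period(27, 59)
suppressWarnings(o2_rate_with_uncertainty(obs$gas, period, liquid_volume = 1))
#> O2 contamination days 27-59: 220.7 +/- NA mL O2 L-1 d-1 (15 intervals)
#>   note: 11 interval(s) with O2 above the detection threshold

as.numeric(volumetric_rate(obs$liquid, "n-caproate", period,
                           feed_mM = 0, hrt = 14))
#> [1] 2.051636   # true extent: 2.12 mmol L-1 d-1
```

(The warning suppressed above says no control series was supplied, hence the
`NA` standard error; the detection-threshold note fires because gas-fraction
noise occasionally lifts the measured O₂ fraction past 0.1 %.)

The full workflow lives in `analysis/01_simulate.R` …
`analysis/06_community.R`; each stage is a thin driver over the package that
reads its predecessor's tables from `results/` and narrates what it finds.
A run of the bundled reactor-pair study prints, among other things:

```
days 27-59: O2 219 +/- 3 mL L-1 d-1 | CH4 6.23, H2 -43.66 mmol L-1 d-1 |
            non-CH4 H2 18.73 (H2:O2 = 1.91)
electron ledger days 5-27:  in 7922.9 e-mmol, out 7837.7 e-mmol, error -1.07%
electron ledger days 27-59: in 10099.2 e-mmol, out 10181.5 e-mmol, error +0.82%
  n-butyrate production 1% less (1.49 of 1.50)
  n-caproate production 74% less (0.56 of 2.19)
propionate fold change: 6.7 x control
  methanogen_like ~ ch4_production: rho = 1.00 (p = 0.0030)
```

i.e. the true 220 mL O₂ L⁻¹ d⁻¹ leak is recovered within its uncertainty,
the electron pool closes to about ±1 %, O₂ suppresses caproate and methane
while butyrate is untouched and propionate multiplies, the non-CH₄ H₂:O₂
molar ratio lands at the H₂-oxidation value of 2, and the rate-linked genus
survives rarefaction and the p < 0.01 mask.

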