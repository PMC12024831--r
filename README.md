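# clopbbm

Physiologically based biopharmaceutics modeling (PBBM) of clopidogrel
solid dispersions: an open, tested R implementation of the in vitro → in
silico pipeline that links formulation factors (drug release rate) to
predicted pharmacokinetics.

Clopidogrel hydrogen sulfate is a weakly basic BCS class II antiplatelet
drug: freely soluble in the stomach (≈269 mg/mL at pH 1.2) and practically
insoluble at intestinal pH (0.016 mg/mL at pH 6.8), so oral absorption is
dissolution- and precipitation-limited. The package is written for
formulation and biopharmaceutics scientists who want to ask, mechanistically:
*if a solid dispersion releases drug with this in vitro profile, what
fraction is absorbed, where along the gut, and what plasma exposure
results?*

## What's inside

* **Solubility & dose number** — tabulated pH–solubility with log-linear
  interpolation; `D0 = D / (V0 · C0)` with the `D0 < 1` high-solubility
  classification.
* **Release kinetics** — nonlinear least-squares fits of the five
  classical models (zero-order `F = k0·t`, first-order
  `F = 100(1 − e^{−k1 t})`, Higuchi `F = kH·√t`, Korsmeyer–Peppas
  `F = k·t^n`, Hixson–Crowell cube-root law), R² ranking, and mechanism
  classification from the diffusional exponent (`n ≤ 0.45` Fickian,
  `0.45–0.89` anomalous, `> 0.89` case-II/erosion).
* **The simulator** — nine serial GI compartments (stomach → ascending
  colon) with first-order transit, pH-dependent dissolution
  (shrinking-particle Noyes–Whitney for solids, tabulated
  controlled-release profiles for dispersions), supersaturation-limited
  precipitation, absorption flux `ka = 2·Peff/R` per compartment, hepatic
  first-pass extraction (`Fb = Fa·(1 − FPE)` with FPE = 96.5%), and
  three-compartment disposition solved by eigendecomposition
  (terminal `t½ = ln2/λz` = 4.40 h for the clopidogrel constants).
* **Validation arithmetic** — non-compartmental PK metrics, fold error
  (`predicted/observed`) with the inclusive two-fold acceptance band, and
  percent-improvement comparisons.
* **Synthetic dissolution data** — a seeded generator of Bio-Dis
  pH-gradient (1.2/6.0/6.4/6.9/7.4; 330 min) cumulative-release curves
  with calibrated presets for the four studied formulations (copovidone
  and poloxamer 407 dispersions at 1:5 and 1:9).

## A worked example

Simulate a 75 mg dose of the slow-releasing 1:9 poloxamer dispersion (P9)
through the full pipeline:

```r
library(clopbbm)
res <- run_pipeline(list(
  formulation = list(type = "dispersed", preset = "P9"),
  dose = list(amount_mg = 75, water_mL = 200),
  solver = list(t_end_h = 48, dt_h = 0.02),
  seed = 1
))
res$simulation
#> PBBM simulation (po, 75 mg)
#>   Fa = 85.27%, Fb = 2.98%
#>   Cmax = 8.2 ng/mL at tmax = 0.72 h; AUC0-inf = 26.65 ng h/mL

regional_absorption_fractions(res$simulation)[c("cecum", "asc_colon")]
#>     cecum asc_colon
#>  19.66099  34.80466

attr(res$release_fits, "summary")
#>              model r_squared
#> 1 korsmeyer_peppas 0.9213608
#> 2          higuchi 0.9134820
#> 3      first_order 0.6601529
#> 4   hixson_crowell 0.5846656
#> 5       zero_order 0.3958571
```

Reading the output: 85% of the dose is absorbed but only 3% reaches
systemic circulation — clopidogrel's 96.5% hepatic first-pass extraction
removes the rest. More than half of the absorption happens in the cecum
and ascending colon because the erosion-controlled matrix (best described
by Korsmeyer–Peppas among the five models) releases drug over many hours
while it transits distally. The fast-releasing copovidone 1:5 dispersion,
by contrast, reaches Fa ≈ 97% with almost entirely duodenal/jejunal
absorption, and a conventional immediate-release tablet only Fa ≈ 56%,
because its dissolved gastric bolus precipitates on entering the
intestine.

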