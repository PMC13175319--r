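# fucflux

Constraint-based strain design for **l-fuculose** production in
*Escherichia coli*.

l-Fuculose is a rare deoxyketohexose of cosmetic and pharmaceutical
interest that occurs only in traces in nature. A practical microbial route
runs the l-fucose catabolic pathway in reverse: the aldolase FucA condenses
lactaldehyde (LAD) and dihydroxyacetone phosphate (DHAP) into
l-fuculose-1-phosphate, which innate sugar phosphatases dephosphorylate to
l-fuculose. Competing reactions drain both substrates and product — FucO
reduces LAD to 1,2-propanediol, AldA oxidizes it to lactate, TpiA pulls
DHAP into glycolysis, and FucI/FucK isomerize or rephosphorylate the
product — so rational strain design asks which deletions, and which culture
conditions, channel flux toward the product.

`fucflux` makes that analysis reproducible as a tidyverse-style R package:

* **Model core** — BiGG-dialect JSON reader/writer for constraint-based
  models, stoichiometric matrix assembly, gene–reaction (GPR) boolean
  rules, and in-silico gene deletions.
* **Pathway extension** — grafts the l-fuculose pathway (and its competing
  routes) onto any host model with elemental mass-balance checking.
* **FBA engine** — flux balance analysis, `max c'v` subject to `S v = 0`
  and bounds, via a deterministic two-phase simplex written for this
  package, plus flux variability analysis (FVA) to resolve degenerate
  optima, and an exhaustive vertex-enumeration oracle that independently
  certifies optima on networks of up to 12 reactions.
* **Campaigns** — aerobic/anaerobic scenario tables, oxygen-uptake sweeps,
  glucose:LAD substrate-ratio scans, and the Fuc 1–4 deletion strain
  series, all returning tibbles with `autoplot()` methods.
* **Fermentation metrics** — titer, substrate consumption, molar yield
  (`100 × (titer / 164.16) / LAD consumed`, MW l-fuculose 164.16 g/mol) and
  fold improvement from time-course CSV tables (`ND` handled as missing).
* **Synthetic data** — a hand-specified "mini-core" host emulating the
  functional blocks of the *E. coli* core model, seeded toy networks with
  closed-form optima, and a fermentation time-course simulator, so the
  whole pipeline runs without downloads.

## Worked example

```r
library(fucflux)

model <- build_fuculose_model()   # mini-core host + l-fuculose pathway
model
#> <constraint_model> mini_core+fuculose
#>   metabolites: 25  reactions: 31  genes: 6
#>   objective: BIOMASS

solve_fba(model)
#> <flux_solution> max BIOMASS on mini_core+fuculose
#>   status: optimal  objective: 8.09091  max|S.v|: 2.42e-13
```

Growth (in mini-core biomass units) is maximized at 8.09 with unlimited
oxygen. The oxygen sweep then asks, per oxygen uptake bound, how much
l-fuculose the cell can secrete while still meeting a fixed growth demand
(half the best attainable growth):

```r
sweep <- oxygen_sweep(model)
sweep[c(1, 3, 6, 11), 1:4]
#>   o2_bound max_growth biomass_floor max_fuculose
#> 1        0       2.18          4.05         0
#> 2       -4       4.36          4.05         1.17
#> 3      -10       7.18          4.05         5.00
#> 4      -20       8.09          4.05         5.00
```

Anaerobically (row 1) the growth demand cannot be met at all — every NADH
produced in glycolysis must be disposed through FucO, so all lactaldehyde
leaves as 1,2-PDO and fuculose production is zero; with increasing oxygen
both growth and attainable fuculose rise until production saturates at the
LAD uptake bound (5 mmol/gDW/h). The strain series applies the Fuc 1–4
deletion genotypes:

```r
strain_series(model)[, c("strain", "deletions", "max_growth", "max_fuculose")]
#>   strain    deletions                  max_growth max_fuculose
#> 1 wild-type ""                               8.09         5.00
#> 2 Fuc1      "fucI,fucK"                      8.09         5.00
#> 3 Fuc2      "fucI,fucK,tpiA"                 1.27         5
#> 4 Fuc3      "fucI,fucK,tpiA,fucO"            1.27         5
#> 5 Fuc4      "fucI,fucK,tpiA,fucO,aldA"       1.27         5
```

Deleting *tpiA* forces every DHAP through the aldolase (growth falls to
1.27 because glucose intake becomes limited by the LAD supply), while the
product ceiling stays at the LAD bound. Fermentation outcomes are
quantified from time-course tables; on a simulated noisy batch:

```r
tc <- simulate_timecourse(fermentation_params(sigma = 2, seed = 1))
summarize_fermentation(tc, reference_titer = 1.55)
#>   max_titer t_max lad_consumed molar_yield_pct fold_vs_reference
#> 1      57.3    72         5.00            6.99              37

fold_improvement(50.25, 1.55)   # engineered titer vs microbial benchmark
#> [1] 32.4
```

A thin command-line front end over the same functions lives in
`inst/cli/fucflux.R` (`synth`, `simulate`, `sweep-o2`, `scan-substrate`,
`strains`, `metrics`).

## Scientific scope

FBA predicts steady-state flux capabilities, not batch titers: the
experimentally observed strain ranking involves effects outside the model
(notably DHAP toxicity after *tpiA* deletion), and the package deliberately
reports model predictions only. See the methods vignette
(`vignettes/fuculose-strain-design.Rmd`) for the model, the campaign
protocols, and known limitations.
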