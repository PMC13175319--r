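---
title: "Flux-balance strain design for l-fuculose production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-balance strain design for l-fuculose production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fucflux)
```

## The biological problem

l-Fuculose can be made microbially by running l-fucose catabolism in
reverse: the class II aldolase FucA condenses lactaldehyde (LAD) with the
glycolytic intermediate dihydroxyacetone phosphate (DHAP) into
l-fuculose-1-phosphate, which innate sugar phosphatases hydrolyse to
l-fuculose. In a glucose + LAD medium the two substrates compete for the
same cell: DHAP is pulled into glycolysis by TpiA, LAD is reduced to
1,2-propanediol by FucO (an NADH sink) or oxidized to lactate by AldA, and
the product itself can be isomerized to l-fucose by FucI or
rephosphorylated by FucK. Flux balance analysis (FBA) over a
stoichiometric model answers two design questions: which culture
conditions (oxygen, substrate ratio) permit fuculose flux at all, and
which gene deletions remove the competing drains.

## Model and assumptions

A `constraint_model` holds metabolites, reactions (stoichiometry, bounds
in mmol·gDW⁻¹·h⁻¹), genes and GPR rules, and an objective reaction. FBA
solves

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

the usual steady-state LP. Conventions follow the dominant BiGG JSON
dialect so real core-model files load unmodified: exchange reactions are
written `met_e ->` with negative flux = uptake; irreversible reactions
default to bounds (0, 1000) and reversible to (−1000, 1000); `and` binds
tighter than `or` in GPR strings; compartments are limited to cytosol and
extracellular (periplasm collapsed into the cytosol — none of the pathway
chemistry distinguishes it). Gene deletions act through the GPR rules:
a reaction whose rule evaluates false gets both bounds set to zero, which
is idempotent and monotone in the deletion set.

## The bundled mini-core host

No particular core-model release is pinned; instead the package ships a
hand-specified host whose behaviour is fully derivable from its stated
stoichiometry (a real core model remains usable through
`read_model_json()`). Its lumped reactions are:

| id | reaction | note |
|----|----------|------|
| `GLYC_UP` | glc + 2 ATP → DHAP + G3P + 2 ADP | upper glycolysis |
| `TPI` | DHAP ⇌ G3P | gene *tpiA* |
| `GLYC_LO` | G3P + 2 ADP + NAD → pyr + 2 ATP + NADH | lower glycolysis |
| `RESP` | NADH + ½ O₂ + 2 ADP → NAD + 2 ATP | P/O ratio 2 |
| `LDH` | pyr + NADH → lactate + NAD | fermentative overflow |
| `ACK` | pyr + ADP → acetate + ATP | overflow with ATP gain |
| `BIOMASS` | pyr + 10 ATP → 10 ADP + biomass | objective |
| `ATPM` | ATP → ADP, lower bound 1 | maintenance |

with exchanges for glucose (lower bound −10), oxygen (−20 aerobic, 0
anaerobic), acetate, lactate and biomass. The glucose:LAD uptake defaults
(10 vs 5) mirror the 10 g/L glucose + 5 mM LAD medium in round numbers;
only their ratio matters for the scan campaigns. The lumped reactions
deliberately elide CO₂ and water and carry no elemental formulas, so the
mass-balance checker skips them; DHAP and lactate do carry formulas
because the grafted pathway reactions are checked against them.

One structural property is worth stating because several results follow
from it: anaerobically the bare host cannot grow. Each triose oxidized in
`GLYC_LO` yields one NADH, and the only anaerobic NADH sink, `LDH`,
consumes one pyruvate per NADH — exactly the pyruvate the triose produced.
Lactate fermentation therefore covers ATP maintenance but leaves no
pyruvate for biomass. Lactaldehyde changes this: FucO reduction of LAD to
1,2-PDO is an external electron sink, freeing one pyruvate per LAD. This
is why, at the anaerobic growth optimum, all LAD is diverted to 1,2-PDO
and the fuculose flux-variability range collapses to (0, 0).

## The pathway extension

`extend_with_fuculose_pathway()` adds 14 reactions (with the default
toggles) and the corresponding species, non-destructively. Directionality
choices: `FCPA` (the aldolase) and `FUCO` are reversible — with slow
dephosphorylation, fuculose-1-phosphate can be reconverted to LAD and DHAP
by the reverse aldolase reaction; the phosphatase `FCP`, kinase `FCLK`,
and `ALDA` are irreversible. The isomerase, kinase and AldA branches are
toggleable but default to on, since the competing-route analysis depends
on them. Product exchanges (`EX_fcl`, `EX_pdo`, `EX_fuc`) are
secretion-only: the medium supplies none of them, and a reversible
1,2-PDO exchange would let the LP run FucO backwards on imported PDO to
manufacture lactaldehyde. *fucA* overexpression is represented only by the
`FCPA` reaction being present at default capacity — FBA has no notion of
expression level, so the model cannot distinguish promoter strengths.

Mass balance is checked per element from metabolite formulas
(lactaldehyde C3H6O2, DHAP C3H7O6P, fuculose-1-phosphate C6H13O8P,
l-fuculose/l-fucose C6H12O5, 1,2-PDO C3H8O2, lactate C3H6O3). Cofactor
pairs are declared with a net transfer formula — NADH counts as NAD + H2,
ATP as ADP + HO3P — which makes redox and phosphoryl reactions balance
exactly without proton or charge bookkeeping. When the host lacks free
water/phosphate species, the phosphatase and AldA reactions omit them; an
imbalance attributable purely to elided H2O/H3PO4 is reported as
balanced-with-elision rather than as an error, and a water-carrying host
receives the full forms (the test suite exercises both).

## Solver and numerical choices

No LP package is required: the engine is a dense two-phase simplex on the
bounded standard form, with Bland's rule for both the entering and the
leaving variable, so it terminates on degenerate bases and is fully
deterministic for a fixed model ordering. Pivot and entering tolerances
are 1e-9; phase-1 feasibility is declared below 1e-7; optimal solutions
satisfy max|S·v| ≤ 1e-8 and respect bounds to 1e-9 (both asserted by
tests). Infinite bounds are handled by variable reflection/splitting, so
genuinely unbounded objectives are detected rather than truncated.

FBA optima are generically non-unique, so every biological claim is
asserted through flux variability analysis: the objective is pinned to
`fraction × optimum` with a relative slack of 1e-6 and each reaction is
minimized and maximized. The slack means a mathematically zero range can
appear as ~1e-5 numerically; tests therefore use a 1e-4 tolerance when
asserting "no flux".

Two independent routes certify the solver. `enumerate_vertices_oracle()`
exhaustively enumerates the basic solutions of the bounded LP (every
choice of rank(S) basic columns with the remaining fluxes at either
bound); since all bounds are finite the feasible region is a polytope and
the optimum sits on such a vertex. The enumeration is exponential and
refuses models above 12 reactions; `build_micro_core()` provides a
condensed 12-reaction production network that reproduces the redox
scenarios in miniature for exactly this purpose. Seeded linear-chain toy
models with closed-form optima (the bottleneck capacity) give a second,
solver-independent reference.

## Campaign protocols

A single-objective FBA would report zero fuculose under every condition —
product formation always costs biomass — so each campaign point runs two
optimizations: maximal growth, then maximal `EX_fcl` subject to a growth
demand. The demand protocol is the one genuinely open design choice. The
package fixes the demand across the grid at
`biomass_fraction × (best growth at the most permissive grid point)`
(default fraction 0.5, `floor = "reference"`). The question this poses —
how much product can the cell make while meeting one and the same growth
requirement — is what renders oxygen limitation visible: anaerobically
the demand is unreachable and attainable production is zero, matching the
prediction that oxygen supply is essential for fuculose flux. The
alternative (`floor = "per-point"`), which rescales the demand to each
point's own maximum, answers a different question; under it even the
anaerobic point shows positive fuculose at half its (much lower) growth
optimum, because lactate fermentation leaves ATP slack below the growth
optimum. Both protocols are monotone in the control bound — relaxing an
uptake bound only enlarges the feasible set — and both are available; the
fixed-demand protocol is the default because it reproduces the study's
qualitative predictions, including the threshold that glucose must be
supplied at or above the LAD charge for fuculose synthesis to be
sustained (the substrate scan turns positive exactly at |glc| = |LAD| =
5 under the default settings).

The strain series uses a per-strain demand (half that strain's own
maximal growth): the strains are structurally different models, not a
relaxation series, so a common absolute floor would conflate growth
penalty with production capacity there.

## Fermentation metrics and the simulator

`summarize_fermentation()` defines titer as the maximum observed product
concentration (robust to late-phase degradation; endpoint mode is a flag)
and molar yield as `100 × (titer / 164.16) / (LAD consumed in mM)` with
consumption = first observed − minimum observed LAD. The yield
denominator is consumed LAD on a molar basis; published percentage yields
for such experiments are not always mutually consistent with a single
denominator convention, so the package documents its definition explicitly
and does not claim to reproduce any particular printed yield. `ND` values
parse as missing and are excluded from every extremum, never imputed.

The simulator emulates the structure of the reported batch cultures:
logistic OD600 reaching stationary phase by ~24 h, glucose consumption
coupled to growth, acetate plateauing with growth, linear LAD depletion
(complete by 48 h by default), 1,2-PDO accumulating as a fixed fraction
(0.85) of consumed LAD, and product formed as
`yield × consumed LAD × 164.16` mg/L. With `sigma = 0` the summary
inverts the generator exactly (relative error at machine precision);
with noise, Gaussian errors (sd `sigma` mg/L on fuculose, the molar
equivalent on LAD) are added and clipped at zero. Because titer is a
maximum over noisy plateau points, recovery is biased upward by roughly
`sigma × E[max of a few standard normals]` — about 3% at sigma = 2 mg/L —
which the acceptance checks bound at 5% over 50 replicates. What passing
these tests shows is that the metric definitions are self-consistent and
noise-robust; it does not validate the simulator against real HPLC/GC-MS
data, which carry calibration and derivatization-loss structure the
generator does not model.

## Problem sizes and runtime

All analyses run on the 31-reaction extended mini-core, the 12-reaction
condensed network, and chains of up to 12 reactions; the oracle
comparisons use 100 seeded toys and the noise study 50 replicates. These
sizes keep the full test suite and the acceptance script in the
seconds-to-a-minute range on one core while still exercising every code
path; they are stated here so that reported quantities can be tied to the
exact inputs that produced them.

## Known limitations

* FBA predicts flux capabilities, not titers or rates: the model cannot
  reproduce the experimental strain ranking (which is shaped by DHAP
  toxicity after *tpiA* deletion), enzyme expression levels, or the
  isomerase equilibrium position, and does not attempt to.
* The mini-core is a functional caricature: lumped stoichiometry, no
  proton/charge balancing, no phosphate bookkeeping outside the pathway,
  a single fermentation branch per redox fate.
* The kinase/isomerase futile cycles are present but never active at LP
  optima; conclusions about FucI/FucK removal therefore rest on the
  product-retention argument, not on a flux gain in the model.
* SBML, thermodynamic annotations, parsimonious FBA and MOMA/ROOM-style
  knockout predictors are out of scope.
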