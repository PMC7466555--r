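---
title: "Methods: phase-resolved physiology, core-model flux analysis and absolute proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-resolved physiology, core-model flux analysis and absolute proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oleoflux)
```

`oleoflux` analyses batch cultivations of oleaginous yeasts growing on
xylose, where growth runs through three limitation-defined phases:
unlimited exponential growth (P1), nitrogen-limited growth on xylose
(P2), and consumption of previously secreted polyols after xylose
exhaustion (P3). This vignette records the models, estimators, numerical
choices and their rationale; it states no empirical result beyond what
the package's tests and the acceptance script themselves compute.

## Phase segmentation

Two criteria locate the P1/P2 boundary, and the default takes the
earlier of the two:

* **Nitrogen exhaustion.** Cumulative nitrogen incorporated into biomass
  is `biomass_n_fraction * (DCW - DCW0)` (mol-N/L); the boundary is the
  interpolated time at which it reaches the nitrogen supplied by the
  medium. `segment_phases()` defaults to 0.0075 mol-N/gDCW
  (protein-dominated biomass); when analysing data whose protein content
  is known — as for the synthetic reference batch, whose nitrogen-excess
  protein content is 0.48 g/gDCW — the measured value
  (0.48 × 0.16 / 14.007 ≈ 0.00548 mol-N/gDCW) should be passed instead,
  exactly as a laboratory analysis would use its protein assay.
* **Log-linear breakpoint.** The breakpoint of a continuous two-piece
  linear fit of ln(DCW) on time, accepted only when the second slope
  drops by at least 10% of the single-slope fit and the two-piece SSE
  improves on the one-piece SSE by 10%; this guards against noise-driven
  spurious breaks.

The P2/P3 boundary is the interpolated time at which xylose falls below
the depletion threshold (default 0.5 g/L; the measurement floor of
routine sugar HPLC). Batches without a nitrogen event or without xylose
depletion return one or two phases.

## Rate estimators

The specific growth rate is the least-squares slope of ln(DCW) against
time over the samples inside the phase. Specific conversion rates use,
by default, the difference quotient between the first and last *measured
samples* inside the phase divided by the logarithmic mean of the
endpoint biomass values, `(X2 - X1)/log(X2/X1)`. For a segment in which
consumption is proportional to biomass and biomass grows exponentially,
this estimator is exact — the log-mean is precisely the time-averaged
biomass — and it remains unbiased for linear growth. Rates are computed
between measured samples rather than interpolated phase boundaries
because linear interpolation across a 24-h sampling interval of an
exponential trajectory biases both the concentration change and the mean
biomass.

A pooled `method = "regression"` variant (slope of concentration against
biomass times μ, exact under the same assumptions) is available; with
very few in-phase samples it offers no advantage, and the endpoint form
is the default. Off-gas CO2 arrives as an instantaneous volumetric rate,
so its specific rate is the mean of the pointwise ratios
`CO2_rate/DCW` over in-phase samples, again exact for proportional
growth.

Both estimators share an honest limitation: with 24-h sampling, a ~48-h
P1 window and a few percent multiplicative noise on concentrations of
order 70 g/L, the early-phase concentration difference (~7 g/L) is
noise-dominated and single-replicate rate estimates can be far off. The
study design this package emulates measured triplicate cultivations for
this reason; the pipeline compensates by widening constraint tolerances
(below) rather than by pretending to better data.

## Yields, carbon balance and C/N

`Y = Δproduct/ΔDCW`, `Y_S = Δproduct/Δ(consumed carbon substrates,
summed in g)`, `q = Δproduct/Δt`, per phase (sample endpoints) and for
the whole batch (first/last sample). The carbon balance divides
recovered carbon (biomass + secreted polyols + intracellular lipid and
carotenoid + CO2) by consumed substrate carbon. Lipid and carotenoid
mass is subtracted from the DCW term before applying the biomass carbon
content, so product carbon is never double-counted; defaults are
0.48 g-C/gDCW for non-lipid biomass (standard yeast value), an average
triacylglyceride C57H104O6 for lipid and β-carotene C40H56 for total
carotenoid. C/N ratios are plain mole ratios from the compound registry.

## The core metabolic model

The curated network (~100 reactions, compartments c/m/e) covers every
route the flux analyses discuss: XR/XDH/XK xylose assimilation, both
arabitol isoform routes pooled into an "artificial" arabitol, oxidative
and non-oxidative PPP, phosphoketolase plus phosphate transacetylase,
the glycolytic trunk, the pyruvate node (PYC, PDC, PDH, the
mitochondrial carrier), acetyl-CoA sources (ACS, ACL, PTA), TCA and
glyoxylate cycles, NADP-malic enzyme, glutamate/glutamine assimilation,
lumped fatty-acid synthesis and β-oxidation, mevalonate-route lumps for
the four pigments (β-carotene, γ-carotene, torulene, torularhodin), an
oxidative-phosphorylation lump with fixed P/O (1.5 per NADH, 1 per
FADH2), and biomass/NGAM pseudo-reactions.

Bookkeeping conventions worth knowing:

* **Neutral formulas.** All species carry fully protonated bookkeeping
  formulas and zero charge, so elemental balance is the only audit;
  every non-pseudo reaction balances C/H/O/N/P/S exactly (fractional
  formulas, as for the average protein residue `C5H7.2N1.2O2.8`, are
  allowed). FADH2 is a bookkeeping species of formula H2.
* **Lipid lump.** Fatty-acid synthesis is lumped to oleoyl-CoA (C18:1,
  9 acetyl-CoA, 16 NADPH, one O2/NADH desaturation) so that the average
  triacylglyceride used for mass accounting, C57H104O6 (tri-C18:1),
  balances exactly; a C16 lump would contradict that formula.
* **Biomass.** `set_biomass_composition()` recomputes the biomass
  pseudo-reaction from measured protein, lipid and carotenoid contents;
  carbohydrate (as anhydroglucose units) absorbs the remainder together
  with a fixed RNA+ash residual (default 0.05 g/gDCW), so precursor
  coefficients dotted with their species masses give exactly
  1 g/gDCW. The growth-associated ATP cost (30 mmol/gDCW) is retained.
* **Arabitol routes.** The isoform chemistry of the arabitol
  dehydrogenases is enzymatically unresolved, and the production routes
  are encoded as lumped pseudo-reactions with a configurable cofactor
  spec (default: the L-route regenerates 1 NADPH + 1 NADH, the D-route
  1 NADH per arabitol). These lumps assert a net cofactor yield rather
  than an elementally audited mechanism — a net reduction cannot
  elementally co-produce reduced cofactors — and are therefore flagged
  pseudo. The catabolic lump uses the real L-isoform chemistry
  (arabitol + 2 NAD + NADPH → xylulose + 2 NADH + NADP, balanced) and is
  closed by default: running production and catabolism simultaneously
  would cycle cofactors out of nothing, so `apply_constraints()` opens
  catabolism only for phases that consume arabitol, where no xylose is
  available to drive the production lumps. Co-consumption of xylose and
  arabitol in one constraint set is consequently not supported.

`validate_model()` reports elemental imbalances, dead-end species
(evaluated with exchanges open) and, optionally, FVA-blocked reactions.
Models read and write losslessly as native JSON and as SBML Level 3 +
FBC v2.

## Constraint-based analyses

Measured data enter as a fixed growth rate plus exchange windows
`value ± max(SD, tol_rel × value)` (default `tol_rel` 5%; how tightly
the original rates were fixed is not documented, so the tolerance policy
is explicit configuration). Secretion can be fixed or treated as an
upper bound. The objective maximises the non-growth-associated ATP
maintenance reaction — with growth and exchanges measured, leftover ATP
capacity is the natural scalar objective — and a parsimonious second
step (minimum total absolute flux at the fixed NGAM optimum) selects a
unique reported solution from the degenerate optimal face.

The LP layer is a bounded-variable two-phase revised simplex
(`bounded_simplex()`): Dantzig pricing with a Bland fallback against
cycling, basis systems re-solved from scratch each iteration for
robustness, warm starts from a previous basis of the same feasible
region (used by FVA, which re-solves one polytope under ~200
objectives). Feasibility/optimality tolerances are 1e-9; oracle
comparisons in the tests use 1e-6. Infeasible constraint sets are
diagnosed by relaxing measured constraints one at a time and naming
those whose relaxation restores feasibility.

Flux sampling constrains NGAM to at least `ngam_fraction` (default
0.95) of its maximum and walks the polytope with artificial-centering
hit-and-run in null-space coordinates: warm-up points are the FVA vertex
solutions, directions are drawn from stored points minus the running
centre, 100 × dimension warm-up steps are discarded and every 10th step
is recorded; everything is seeded. Degenerate (zero-volume) polytopes
return the FVA vertex with a warning. Flux comparability across phases
uses carbon-normalised fluxes (divided by total carbon uptake in
C-mmol/gDCW/h, so P3 polyol co-consumption is handled symmetrically).

## Proteomics

The total protein approach assigns each protein
`coverage × signal_i / Σ signal × 1e6` µg per g protein (coverage
default 0.90 — the assumed fraction of protein mass captured by the
quantified set). The default signal is the per-protein light/heavy
ratio against the 1:1 labelled internal standard, median-centred per
sample; a ratio-free intensity mode exists. Missing abundances are
floored at half the smallest positive per-sample abundance before log2.

Differential allocation uses a Welch two-sided t-test on per-sample
median-centred log2 abundances with Benjamini–Hochberg adjustment.
Median-centring matters because abundances are shares of a fixed total:
a genuine rise of one protein group otherwise depresses every other
share and manufactures spurious "down-regulation". The test choice and
missing-value policy are documented defaults, not claims about any
original analysis. A note on power: with triplicates, the p-values a
plain t-test can reach are bounded by the 4-degree-of-freedom tail, so
clearing an adjusted 1% threshold across ~3000 proteins requires
per-channel CVs of a few percent; the package's power simulation pins
the ≥90%-recovery regime at CV ≈ 3% for four-fold changes.

Reporter metabolites aggregate per-protein Z-scores
(`Z = Φ⁻¹(1 - p/2)` signed by fold-change direction; unsigned one-tail
for the "distinct" class) over each metabolite's enzyme neighbourhood as
`Z_met = ΣZ/√k`, corrected by the mean and SD of `n_background`
(default 1000) random size-k draws; water and phosphate pools are
excluded from neighbourhoods. Allocation profiles report per-category
mass fractions (categories derivable from model subsystems) and the
cumulative share of the top-N proteins (default 100).

## The synthetic-data generator

The generator is the package's definition of the study conditions, not a
tuning dial. Defaults: 70 g/L xylose with 1.95 g/L ammonium sulfate
(medium C/N ≈ 80 mol/mol), inoculum 0.1 g/L, phase rates
μ = 0.060/0.020/0.005 1/h and xylose uptake 1.74/0.41 mmol/gDCW/h
(P1/P2), secretion yields 0.20 g/g arabitol and 0.10 g/g xylitol (≈30%
of consumed carbon as polyols), P3 polyol consumption 0.055 + 0.025
mmol/gDCW/h, phase-wise carotenoid production 0.042/0.0105/0.009
mg/gDCW/h and lipid production 0.0108/0.010/0.0019 g/gDCW/h, 24-h
sampling over 192 h, and multiplicative log-normal noise of 2% (DCW),
3% (HPLC concentrations) and 5% (titres). The biomass nitrogen content
(0.00548 mol-N/gDCW, i.e. 0.48 g/gDCW protein at 16% N) places nitrogen
exhaustion after ~23 g/L xylose consumed, the observed switch point; the
batch ends at 192 h so the final sample still lies in the active polyol
regime. Phase switches are exhaustion-triggered (nitrogen, then xylose —
limitation events, not saturation kinetics); the P2 growth-rate change
is a step, with an optional exponential decay.

Integration advances biomass exactly (exponential step, ≤0.1 h) and
feeds the pools with the exact integral of biomass over each step
(`ΔX/μ`), so noise-free output closes every recovery loop to machine
precision: segmentation, μ, rates, yields and a carbon balance of
exactly 1. CO2 evolution is computed as the closing term of the carbon
balance; an `unmeasured_fraction` routes that share of consumed carbon
outside the measured pools instead. What the generator does *not*
emulate: lag phases, substrate-saturation kinetics, replicate
correlation structure, carotenoid-species trends resolved per pigment,
and endpoint product contents as high as a long stationary P3 would
accumulate — passing recovery tests on generated data therefore
demonstrates estimator correctness, not robustness to every property of
real cultivations.

The proteome generator draws log-normal base intensities (meanlog 10,
sdlog 1.5, ~3000 proteins, triplicates), applies configured log2 effects
per condition, and emits light/heavy pairs in which the heavy channel is
the common internal standard; overlapping affected sets with conflicting
effects are rejected.

## Pipeline behaviour and known limitations

`run_pipeline()` chains simulation/ingest → physiology → per-phase
constraint building → FBA (optional sampling) → proteomics and writes a
manifest (version, seed, input checksums). Phase constraint sets derive
from the fitted rates; because single-replicate rate estimates carry the
sampling noise discussed above, the pipeline widens the relative
tolerance stepwise (5, 10, 20, 40, 70%) until the measured windows admit
a steady-state solution and records the tolerance used — the mechanical
analogue of manually reconciling noisy rate sets.

Known limitations, verified by the package's own analyses:

* The full genome-scale reconstruction's printed flux percentages are
  not reproducible on a ~100-reaction core network; the package targets
  the qualitative orderings instead. One ordering genuinely fails here:
  the sampled-mean normalised phosphoketolase flux does not rise from P1
  to P2 (ratio ≈ 0.97), because on this network phosphoketolase competes
  with transketolase for xylulose-5P while the oxidative PPP must supply
  nearly all NADPH for P2 lipid synthesis. What does hold is stronger in
  one sense: FVA shows P2 *requires* nonzero phosphoketolase flux while
  P1 does not.
* With the default NADH-linked D-route, forcing D-arabitol-only
  production lowers the NGAM optimum; re-configuring the route
  NADPH-linked narrows that gap but does not close it entirely, since
  the L-route lump also regenerates NADH (worth a few percent of the
  objective via oxidative phosphorylation).
* Mitochondrial NADPH metabolism, compartmented proton balances and
  enzyme-capacity constraints are outside the model's scope.
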