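---
title: "Digestate characterization: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digestate characterization: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digestate)
```

## The problem

Full-scale anaerobic digesters convert the carbohydrate, fat and protein of
organic substrates into biogas, leaving a digestate whose residual organic
matter still carries methane potential. To decide where further gas can be
won — longer retention, post-digestion, post-treatment of recalcitrant
protein — one needs a stationary mass balance from substrate to final
digestate: how much of each macromolecule was destroyed, how much of the
outgoing protein is newly formed microbial biomass rather than undegraded
feed, and how the stoichiometric methane potential changed along the way.
This package implements that analysis for plants described by routine
monitoring data (TS, VS, pH, Kjeldahl-N, NH4-N, crude fat, sequential
detergent fiber, sugar monomers, VFA profiles), plus the survey-level
statistics used to compare plants.

## Stream model and unit conventions

All concentrations live on a single canonical basis, **g per kg wet
weight**; `convert_basis()` maps the other bases found in plant reporting
(% of TS, % of VS, mg/L) onto it exactly, and liquids default to a density
of 1 kg/L because plant records almost never state densities. Optional
analytes are *absent*, never silently zero: an operation that needs a
missing macromolecule stops and names it.

The sequential detergent-fiber assay measures NDF, then ADF, then ADL on
the same material, so

- hemicellulose = NDF − ADF,
- cellulose = ADF − ADL,
- lignin-like matter = ADL,

and free (non-structural) sugars are the total sugar monomers minus
hemicellulose and cellulose. Lab noise can violate the ordering
`NDF ≥ ADF ≥ ADL` or push the free-sugar estimate slightly negative;
violations within **5% relative** are clamped with a warning (measurement
noise), anything larger is treated as data corruption and raises an error.
"Carbohydrates" means free sugars + hemicellulose + cellulose.
Lignin-like matter is deliberately excluded: native lignin is essentially
recalcitrant under anaerobic conditions, carries no realistic methane
potential, and is tracked as its own fraction.

## The mass balance

Biogas leaving a reactor removes mass from the liquid, so outgoing
concentrations are not directly comparable with ingoing ones. The liquid
volume (mass) reduction is reconstructed from the specific gas production:
per kg of feed, `vol_red = specific_gas × (x_CH4·ρ_CH4 + (1−x_CH4)·ρ_CO2) / 1000 g`
with ideal-gas densities at 273.2 K and 1.01325 bar (ρ_CH4 = 0.716,
ρ_CO2 = 1.964 g/NL) and the non-methane remainder treated as CO2. Outgoing
amounts are then `conc_out × (1 − vol_red)` per kg of feed. When neither a
volume reduction nor gas data is available the balance proceeds with
`vol_red = 0` under a prominent warning; this is conservative and biases
efficiencies downward.

The adjusted VS reduction is
`1 − TS_out·VS_out·(1 − vol_red) / (TS_in·VS_in)` — the complement of the
remaining fraction, so a well-digested food-waste plant reports, e.g.,
0.77 rather than 0.23. The degradation efficiency of a fraction X is
`(X_in − X_out,adj) / X_in`; the *ingoing* amount is the denominator
(anything else fails to reproduce a 27→17 g/kg step as a 37% reduction).
Negative efficiencies (accumulation) are legal and flagged, since
near-zero sugar degradation does occur in practice when substrates arrive
pre-fermented.

Microbial growth recycles degraded VS into new biomass: the model assumes
**0.1 g biomass per g VS degraded, 50% of it protein**, giving
`Y_prot = 0.05 × degraded VS` with
`degraded VS = TS_in·VS_in·1000·VS_red_adj`. The residual substrate-derived
protein is the measured digestate protein minus Y_prot, floored at zero.
`chain_stages()` reports protein efficiency both ways: *raw* from measured
concentrations (biomass included, the number a plant operator sees) and
*corrected*, where each stage's outgoing protein is first reduced by that
stage's Y_prot; the overall corrected efficiency composes multiplicatively
across stages. Nitrogen mineralization is
`(NH4_out − NH4_in) / Kjeldahl_out`.

## Methane potentials and ammonia

The theoretical methane potential (TMP) uses lumped Buswell coefficients —
**0.42 NL CH4/g carbohydrate, 1.01 NL/g fat, 0.50 NL/g protein** — plus the
VFA contribution from molar methane equivalents of the element balance
`CcHhOo → (c/2 + h/8 − o/4) CH4` (acetate 1.0, propionate 1.75, butyrate
2.5, valerate 3.25, caproate 4.0; the iso acid shares its linear isomer's
formula), at 22.414 NL/mol. TMP reduction compares the substrate TMP with
the volume-adjusted TMP of a digestion step; the adjustment is applied
because it keeps TMP_red coherent with the mass balance (for the worked
food-waste plant the adjusted and unadjusted routes differ by about one
percentage point).

Residual methane potential (RMP) measurements are normalized to 273.2 K
and 1.01325 bar and reported per kg VS and per kg wet weight. Free
ammonia — the inhibitory species — follows the ammonium/ammonia
equilibrium `NH3-N = TAN / (1 + 10^(−pH) / 10^(−(0.09018 + 2729.92/T_K)))`.
The measured NH4-N is interpreted as total ammoniacal nitrogen (TAN);
routine titrimetric assays do not distinguish the two. For the
thermophilic dry digester of the bundled survey transcription this formula
yields 0.75 g/kg against a transcribed 0.74; the transcribed table was
evidently computed from unrounded inputs, so the package asserts its own
computed value rather than forcing agreement. Likewise, the transcription
prints a biomass protein of 6.5 g/kg for that plant where the printed VS
and VS reduction give 5.85; the package computes 5.85 and does not force
the printed figure.

## The synthetic generator

`generate_survey()` forward-simulates multi-stage plants so that every
pipeline stage is testable without external data. Category templates (FW,
AW, AWM, WWTP) carry composition priors transcribed from the printed
full-scale values — e.g. food waste at VS ≈ 120 g/kg ww with 22% protein,
32% crude fat, 10% hemicellulose, 12% cellulose, 16% free sugars and 8%
lignin-like matter of VS, digested at 42 °C, 35 d HRT, OLR 4.2 — and
between-plant variation is drawn from mean-preserving lognormals
(CV 0.08, a plausible spread for plants of one substrate category).
One detail in the printed food-waste composition is internally
inconsistent by rounding: the carbohydrate subfractions (10 + 12 + 16%)
sum to 38% while the total is printed as 39%; where the *total* is the
input (TMP) the package uses 39%, where the partition matters the
subfractions are used.

The sewage-sludge template reads the printed ingoing VS of "2.7–2.8 g/kg"
as 2.7–2.8% of wet weight (27–28 g/kg): the printed digestate solids
(TS 1.6–1.7%, VS ≈ 65% of TS) would otherwise exceed the substrate VS, and
the plant's substrate TMP of 11–12 NL/kg ww is only of the right magnitude
under the percent reading.

Per stage, the degraded mass of each analyte is the feed mass times the
true fraction. Methane comes from the Buswell coefficients applied to the
gross degraded masses; CO2 volume is set to 100% of the CH4 volume for
carbohydrate-like matter and protein and 43% for fat, constants that
approximate Buswell CO2/CH4 ratios and exist only to produce realistic
volume reductions (roughly 0.1 for food waste). Biomass bookkeeping is
chosen to be *exactly* consistent with the analysis side: if G is the
gross degraded VS, the net measured VS destruction is D = G/1.1, biomass
is B = 0.1·D and biomass protein 0.5·B — precisely what the Y_prot
estimator reconstructs from the measured VS reduction. Consequently, at
zero measurement noise the pipeline recovers every true degradation
fraction to numerical precision (the package tests assert 1e−9; observed
error is ~1e−15), and per-analyte mass closes exactly
(`feed = digestate·(1−vol_red) + degraded`).

Measurement noise is multiplicative, lognormal and mean-preserving, and
acts on the *analytes* (hemicellulose, cellulose, lignin, free sugars,
protein, …), with the assay values NDF/ADF/ADL and total monomers
recomposed afterwards — noising the raw assay values instead would make
derived differences like hemicellulose absorb the absolute noise of the
much larger NDF, which is not how replicate fiber analyses behave. Repairs
(fiber ordering, NH4 ≤ Kjeldahl-N) are applied with warnings where noise
breaks an invariant.

What the generator does **not** emulate: microbial community dynamics,
inhibition kinetics, temporal variation, water-balance closure (the gas
mass is removed from the analyte ledger but the wet-mass ledger is not
re-equilibrated), EPS/viscosity chemistry, or trace-element effects.
Passing recovery tests therefore shows the algebra of the pipeline is
right, not that real plants satisfy the stationarity and yield
assumptions.

## Statistics layer

Features are centred and scaled per column; columns with any missing value
are dropped (matching the survey convention of analysing only complete
parameters), and zero-variance columns are removed with a warning.
Ward clustering is implemented with the Lance–Williams update on squared
Euclidean distances (the "Ward.D2" contract: merge heights in distance
units, each merge minimizing the within-cluster variance increase), with a
deterministic lowest-index-first tie-break; the tests verify the full
merge sequence against a brute-force O(n³) sum-of-squares oracle and the
heights against `stats::hclust`. PCA is `stats::prcomp` on the scaled
matrix with a fixed sign convention (the largest-magnitude loading of each
component is positive) so outputs are reproducible; explained fractions
are reported against total variance and rank-deficient inputs are
truncated with a warning. Pearson scans report r and the two-sided
t-distribution p per pair on pairwise-complete observations; p-values are
deliberately unadjusted, matching per-pair significance thresholds, with a
Benjamini–Hochberg column added as a clearly separate extension. Enzyme
activities are normalized to the per-enzyme maximum.

## Problem sizes and tolerances

The test suite uses sizes at which the oracles are exhaustive and the
suite stays fast: 50 synthetic plants for recovery (exactness asserted at
1e−9; mean absolute error under 5% analytical CV asserted < 0.03, with
~0.02 observed), 8×5 matrices for the brute-force Ward comparison, 1000
replicates for noise-calibration checks, and 1e−12 for mass closure and
algebraic identities. Basis conversions round-trip to 1e−12 relative; the
fiber clamping tolerance is 5% relative, as above.

## Known limitations

The balance is stationary — no first-order or ADM1 kinetics — so it
describes *what* was degraded, not *how fast*. The biomass yield (0.1 g/g,
50% protein) is a literature constant, not fitted; plants with unusual
growth yields will mis-allocate protein between biomass and residue, and
a high overall VS reduction can push the estimated Y_prot above the
measured protein (the residual is then floored at zero with a warning).
The volume-reduction reconstruction assumes all gas is CH4 + CO2 and
ideal. VFA methane equivalents cover the C2–C6 linear and iso acids only,
and the macromolecule TMP uses three fixed coefficients rather than
elemental formulas per compound.
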