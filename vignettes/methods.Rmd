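---
title: "Models and methods behind switchflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind switchflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchflux)
```

`switchflux` re-creates, at desk scale, a model-driven comparison of an
antibiotic-producing *Streptomyces* strain and its cluster-deletion mutants
across the phosphate-depletion metabolic switch. This vignette documents
the models, the numerical choices, and the design decisions that were
genuinely open — in enough detail that a reader can judge what the
package's passing tests do and do not establish.

## The constraint-based core

A `metabolic_model` is a pair of tibbles (metabolites, reactions) plus a
gene set and an objective. Fluxes are in mmol·gDW⁻¹·h⁻¹; the biomass
reaction's flux is the specific growth rate in h⁻¹; the conventional
"infinite" bound is ±1000. Exchange reactions are identified structurally
(single-metabolite stoichiometry) — the `EX_` prefix is display convention
only.

Flux balance analysis solves the LP `max v_obj` subject to `S v = 0` and
bounds. No LP library for R is assumed: the package compiles its own dense
bounded-variable two-phase simplex (`src/simplex.cpp`). Design points:

* feasibility tolerance fixed at 1e-9; reduced-cost tolerance 1e-9;
* Dantzig pricing with a switch to Bland's rule after a run of 60
  degenerate pivots, so termination is guaranteed;
* every optimum returned is a *basic* solution, i.e. a vertex of the flux
  polytope — the random flux sampler depends on this;
* infeasibility and unboundedness are reported as distinct statuses.

The solver is validated two independent ways in the test suite: against a
brute-force enumeration of all basic solutions on random small LPs, and —
via the SBML writer — against cobrapy/GLPK, which must reproduce the toy
model's FBA optimum from the serialized file. Alternative optima are a fact
of LP life: tests assert objective values and feasibility, never individual
fluxes of a degenerate vertex.

FVA minimizes and maximizes each reaction's flux, optionally under
`v_obj >= fraction * optimum`. It is checked against an explicit two-LP
loop on the full toy model.

Model I/O supports SBML Level 3 Version 1 with the fbc package (bounds as
shared constant parameters, gene rules as nested `fbc:and`/`fbc:or`
associations, subsystem/pathway as COBRA-style note lines) and a flat TSV
dialect. Bounds are serialized with 17 significant digits so that a
write/read round trip reproduces them bit-exactly.

### Biomass prosthetic groups

`update_biomass_prosthetics()` sets each prosthetic-group metabolite's
biomass coefficient proportional to the abundance-weighted sum over
annotated proteins, scaled so the groups' total mass equals a configured
fraction of biomass (default 0.01 g/g), then rescales the remaining
consumed coefficients to preserve 1 g biomass per unit flux. The
proportional-allocation rule is a declared simplification: only the intent
(group levels follow measured protein levels) is carried over, since the
full procedure would require per-precursor molecular masses that a toy
model does not track. The allocation is invariant to rescaling all
abundances, which the tests assert.

## Thermodynamics-guided directionality curation

Reactions with a standard transformed Gibbs energy below a lenient
threshold (default −30 kJ/mol) are proposed forward-irreversible; the rule
is applied *symmetrically* (ΔG above +30 becomes backward-irreversible),
and everything in between is opened to reversibility. Symmetric application
and the re-opening of mid-range reactions are design choices: they make the
proposal operator idempotent, which the suite tests. ΔG uncertainty is
carried in the tables but does not enter classification — no published rule
exists for it here.

ATP-driven curation makes every reversible ATP-consuming reaction
forward-irreversible unless its ΔG estimate is positive or it appears in an
exception list (ATP synthase and adenylate-kinase analogs in the toy).

Proposals are arbitrated against growth/knockout phenotype tests: apply
all, then — in ascending reaction-id order, a deterministic convention —
revert each proposal singly and keep the reversion only if it *strictly*
increases the MCC, recomputing after every kept reversion. Published
curations of this kind discard proposals against such test data without
stating the statistic or the order; the greedy MCC criterion here is this
package's own declared procedure. Strict improvement avoids churn
on ties; an undefined MCC (zero denominator) ranks below any defined one.

Phenotype evaluation treats *growth* as the positive class (the sensible
reading when growth-positive tests dominate), calls growth at an FBA
optimum above 1e-6 h⁻¹, counts infeasible test models as predicted
no-growth, and reports any metric with a zero denominator as `NA`, never
silently 0.

`recover_confusion()` enumerates all integer `(tp, fn, tn, fp)` splits of
`n` whose accuracy/sensitivity/specificity round to stated values. Rounding
is matched with an inclusive half-ulp tolerance: a printed 0.48 accepts an
exact 0.475 even though binary floating point would nudge `round()` to
0.47. At `n = 241` with targets 0.80/0.96/0.48 the match is *not* unique —
nine integer splits are consistent, all with MCC between 0.52 and 0.54 —
so the acceptance test asserts that the published split is among them and
that every consistent split reproduces the published MCC of 0.53 within
0.01.

## Enzyme-constrained models

The GECKO construction: reversible reactions are split into irreversible
copies (`<id>` forward, `<id>_bwd` backward); OR branches of a gene rule
become one copy per isozyme behind an *arm* reaction that carries the total
flux (so a shared bound cannot be doubled by parallel copies); each
catalyzed copy consumes its enzyme species at `1/kcat` per unit flux, AND
groups coupling every subunit at stoichiometry 1; catalyzed reactions
without a kcat match receive the model-median kcat, flagged
`median_fallback`. Enzymes are supplied by usage reactions drawing
mass-weighted protein from a shared pool capped at
`sigma * f * p_total` — defaults 0.5, 0.4 and 0.45 g/gDW, the usual GECKO conventions. Complex subunit
stoichiometry defaults to 1 per subunit; no stoichiometry data are in
scope.

Applying a proteome sample turns each measured protein's usage reaction
into a direct bound at its abundance and reduces the pool cap by the
measured mass. If a target growth rate is infeasible and flexibilization is
requested, the single most limiting measured bound — the usage reaction at
its bound with the largest reduced cost at the growth optimum — is doubled,
up to 20 times, with every relaxation logged. Condition-specific models
constrain each measured exchange to its rate ± a relative tolerance
(default 5%) and bound growth below at `(1 − tolerance) * mu`; infeasible
rate sets are diagnosed by single-constraint relaxation and reported by
name.

Net-flux FVA for split pairs is computed on an auxiliary variable tied to
`v_fwd − v_bwd` by an extra balance row — never by separate per-copy FVA,
which futile forward/backward cycling would inflate. Enzyme constraints can
only shrink the feasible set, so every ec range width is at most the parent
width; the cumulative width distributions reproduce, qualitatively, the
sharp reduction in the fraction of highly variable reactions expected from
proteome allocation limits.

## Random flux sampling and its summaries

Each draw maximizes an objective with i.i.d. standard-normal coefficients
over *all* reactions; the optimal basic solution is stored. Maximization
only — the coefficient signs are symmetric, so both directions of every
facet are covered. Several vertex-sampling recipes exist; the
standard-normal objective is this package's declared variant. Identical seeds give identical sample
matrices (the solver is deterministic).

Pathway activity per condition is the sum of |mean flux| over member
reactions (a direction-free activity measure; a signed variant sits behind
the `signed` flag), divided by that condition's measured CO2 evolution
rate, then Z-scored per pathway across the declared standardization set —
all conditions jointly by default, so two strains can share a color scale.
The divisor can be the measured respiration rate (default) or the model's
CO2 exchange flux, and is recorded in the result. Zero-variance rows are emitted as 0 with an explicit flag, never
NaN. Heatmap row ordering uses average-linkage hierarchical clustering on
Euclidean distance and is presentation-only.

Metabolite budgets partition each reaction's `coefficient x flux` into
producing and consuming sides; steady state guarantees the sides balance,
for every sampled vertex and hence for the means.

## Cultivation-rate estimation

* Growth rate: least-squares slope of `ln(cdw)` vs time. The automatic
  window is the R²-maximizing prefix (at least 4 points, ties to the
  longest) ending at or before the earliest depletion event, which on a
  noise-free exponential recovers the rate exactly.
* Depletion: linear interpolation of the first genuine downward crossing of
  the threshold; series that start at or below the threshold (products)
  yield "none"; later re-crossings are reported with a warning.
* Specific rates: per interval, `q = dC / (dt * X_bar)` with the
  logarithmic-mean biomass `X_bar = (X2 − X1) / ln(X2/X1)` — exact for
  exponential segments, so `q_substrate * yield = mu` holds identically on
  noise-free generator output. No single standard estimator exists for
  batch-culture exchange rates; the log-mean interval estimator is this
  package's declared choice.
* Production comparison: biomass-normalized titer (concentration / cdw)
  evaluated at equal time after the depletion event in both series —
  end-of-run aligned by default, mirroring the rationale of aligning
  strains by their regulon response rather than wall-clock time. A
  rate-based variant (slope of the normalized titer after depletion) is
  provided and agrees exactly when accumulation is linear.

## The synthetic study

The generator plants the published physiology as study conditions and
keeps them fixed:

| preset | growth rate (h⁻¹) | phosphate depletion (h) | germicidin A/B scale |
|--------|-------------------|--------------------------|----------------------|
| M145-like | 0.21 | 35 | 1.00 / 1.00 |
| M1146-like | 0.21 | 38 | 0.73 / 0.75 |
| M1152-like | 0.15 | 47 | 0.08 / 0.18 |

The germicidin scales are back-calculated from the published production
reductions (92/82% and 27/25%): the generator plants the phenomenology, not
its mechanism. Germicidin concentrations are built as
`scale * q * (t − t_dep)+ * cdw`, i.e. the scale acts on the
biomass-normalized production, so depletion-aligned titer ratios recover
the scales exactly. Switch behavior is imposed piecewise (exponential
growth, then arrest), not emergent from regulation, which is out of scope.

Numerical/design choices a reader should know:

* **Sampling grid.** Hourly samples over 0–72 h. Phosphate declines
  linearly to zero at the preset depletion time, so threshold-crossing
  interpolation recovers the planted time exactly for integer-hour presets.
* **Toy network.** ~58 reactions, 51 metabolites, 36 genes; formulas carry
  carbon counts only (currency metabolites and products are unannotated, so
  the elemental-balance invariant applies exactly to the fully annotated
  core). Growth is phosphate-limited on the reference medium by
  construction: maximal growth = phosphate uptake bound / biomass phosphate
  coefficient = 0.2/0.5 = 0.4 h⁻¹, hand-checkable. Substrate-per-biomass
  presets (glucose 0.8, glutamate 1.05 mmol/g for the producer; 0.62/1.3
  for the slow strain) plant the glucose:glutamate uptake-ratio contrast
  while keeping every condition model feasible within the enzyme budget;
  the implied biomass yields are nominal, not literal g/g yields, because
  the lumped biomass equation tracks only a fraction of real cell mass.
  Ammonium transport is reversible — these strains secrete excess ammonium.
* **Proteome.** Abundances are demand-proportional: a parsimonious
  (minimum-total-flux) reference state of the rate-constrained model
  defines each reaction's needed flux, and enzymes get
  `headroom * flux / kcat` (headroom 2), with planted post-switch factors
  (oxidative phosphorylation ×1.8, fatty-acid synthesis ×0.3, glycolysis
  ×0.6), a logistic transition of width 1.5 h, log-normal noise (sd 0.1 on
  the log), 10% of proteins withheld as unmeasured, and per-sample total
  mass clipped to 90% of the `f * p_total` budget. Planted per-cluster
  synthase capacity (2.2e-3 pre-switch) and precursor-node overcapacity
  (pentose phosphate, malonyl-CoA and pyruvate nodes) were calibrated once
  so that the sampled fatty-acid vs cluster malonyl-CoA drain ratio falls
  in the published 3–6 range on pre-switch producer conditions, then
  frozen.
* **Phenotype tests.** Media swaps and single-gene knockouts labelled with
  the model's own FBA ground truth, resampled to 197 growth / 44 no-growth
  tests, then an exact planted number of labels flipped in each class (42
  and 6). Because predictions equal ground truth by construction, the
  evaluated confusion is deterministic — tp 155, fn 6, tn 38, fp 42 — and
  reproduces the published accuracy/sensitivity/specificity/MCC.
* **Thermodynamics.** Planted-consistent ΔG means at ∓45 kJ/mol (0 for
  truly reversible reactions) plus Gaussian noise; at the default 5 kJ/mol
  noise the −30 kJ/mol rule recovers essentially all planted directions
  (the acceptance property asks for ≥ 90%).

What passing tests therefore show: the *methods* behave correctly on data
whose generating process is known and whose published contrasts are planted
by construction. They do not show that the toy network's flux predictions
transfer to the real organism — the toy has no regulation, no maintenance
ATP demand, lumped redox stoichiometry, carbon-only balancing and nominal
yields.

## Problem sizes and runtime choices

The shipped analyses use the sizes that make the full picture
reproducible in minutes on one core: 200 sampled vertices per condition in
the acceptance properties (enough that the Monte-Carlo error of pathway
means is well inside the asserted intervals), 60 per condition in the
pipeline default, two condition models per strain in the pipeline (one
pre-, one post-switch; all eight per strain are constructed and checked
feasible in the tests), and the full 241-test phenotype suite. The
brute-force confusion recovery at n = 241 runs in well under a second.

## Known limitations

* The simplex is dense; it is comfortable to a few hundred reactions but
  not a tool for full genome-scale reconstructions.
* The MCC-greedy proposal arbitration is order-dependent by design
  (ascending reaction id); a different deterministic order could keep a
  different proposal subset with equal MCC.
* Flexibilization relaxes only measured protein bounds; a shortfall caused
  by the shared pool is reported as an error rather than silently widened.
* The monotone alignment works on Z-scored mean regulon profiles, so a
  pure linear time trend is shift-invisible after standardization; the
  phosphate-response regulon's step-like induction is what makes the
  alignment informative, in the toy as in the organism.
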