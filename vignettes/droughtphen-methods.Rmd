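---
title: "Methods: drought tolerance typing, indices and BLUP stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought tolerance typing, indices and BLUP stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtphen)
```

## The analysis problem

`droughtphen` analyses balanced controlled-environment drought trials on
cereal genotype panels. The reference design it targets is a winter barley
panel: 28 genotypes (two spike architectures, two-row `2R` and six-row
`6R`), three watering regimes — control (`C`), a single drought episode at
booting (`Ds`), and a double episode at first node appearance plus booting
(`Dd`) — with 4 pot replicates per cell and 18 morphological and
yield-related traits per plant (`trait_registry()`). Four traits are
computed from the measured ones (`MTKW`, `ATKW`, `ASN`, `ASW`); the
denominators of the per-spike averages are not fully determined by their
names, so the formulas in `trait_registry()` are explicit, documented
reconstructions (`ASN = (MSN + SSN) / RT`, etc.) and `derive_traits()`
never overwrites a measured value.

The package answers three linked questions:

1. **Which genotypes tolerate drought?** Via the classical index set
   computed on grain yield: stress intensity `SI = 1 - Ȳs/Ȳp`,
   susceptibility `DSI = (1 - Ys/Yp)/SI`, stress tolerance
   `STI = Ys·Yp/Ȳp²`, yield stability `YSI = Ys/Yp` and the absolute gap
   `TOL = Yp - Ys`. The stress mean `Ys` is the equally weighted average of
   the `Ds` and `Dd` cell means (the two regimes are treated as one stress
   level), and the grand means `Ȳs`, `Ȳp` weight genotypes equally — with
   balanced replication this equals the pooled mean, and it keeps the
   statistics well-defined if a trait is subset.
2. **What tolerance *types* exist?** Each trait is expressed as change
   percent-of-control (`100 · stress/control`), genotypes are clustered on
   their change profiles, and group responses are summarised as proportions
   of the panel-average change with compact-letter significance displays.
3. **How heritable and stable is yield?** A balanced random-effects
   genotype × treatment model yields variance components, heritabilities
   and shrinkage BLUPs of genotype means.

## Index classification rules

Per-index classes follow the conventional cut-offs (`DSI < 1` tolerant,
strict inequality so the boundary falls on the sensitive side; `STI ≥ 1`
high / `≥ 0.5` moderate / `< 0.5` low). The joint labels reproduce the
published decision rule: `most_tolerant` requires `DSI < 0.4`,
`YSI ≥ 0.75`, `STI ≥ 1` *and* a `TOL` in the lowest quartile;
`most_susceptible` requires `DSI > 1.5`, `YSI < 0.3`, `STI < 0.2` and a
top-quartile `TOL`. "Lowest/highest TOL" is not a numeric cut-off in the
source description, so the quartile (default 25%) is an explicit,
configurable operationalisation (`tolerance_thresholds()`). The consensus
ranking averages the four per-index ranks (DSI, TOL ascending; STI, YSI
descending) with name-order tie-breaks, making it deterministic.

## Response profiling choices

* **Distance and linkage.** Euclidean distance with complete linkage on raw
  (unstandardised) change% values — the defaults of the heatmap tooling
  this workflow descends from. Change% already puts traits on a common
  relative scale, which is the argument for not re-standardising; both
  options are parameters of `cluster_axis()`.
* **Group identity.** Dendrogram label order is arbitrary, so clusters are
  renumbered by descending mean grain-yield change%: group 1 is always the
  least affected, group `k` the most affected. `k = 3` is the default cut
  (the panel's empirical group count) and a parameter.
* **Group profiles.** `group_profile()` reports both the raw group mean
  change% and the normalised profile (group mean as a percentage of the
  unweighted panel-average change). The raw values are what panel-level
  summaries quote; the normalised profile is the plotting scale. With one
  group the profile is identically 100.
* **Letters.** One-way ANOVA followed by Tukey HSD with a compact letter
  display (via `multcomp`), at `P = 0.05`. The source analysis does not
  name its post-hoc test; Tukey HSD is the standard choice for
  all-pairwise letters and its type-I error is verified by simulation in
  the test suite.
* **Variance partition.** `anova_ss_partition()` is a fixed-effects
  two-way ANOVA; SS% components sum to 100 by construction. It refuses
  unbalanced layouts rather than silently switching to a type-II/III
  decomposition.

## The balanced BLUP model

The model is `y_ijk = μ + g_i + τ_j + (gτ)_ij + ε_ijk` with treatment
fixed and genotype and interaction random. (The source description of the
model is self-contradictory — the text says genotype is fixed while the
results plot genotype BLUPs, which exist only for random effects; the
random-genotype reading is adopted.) For balanced data the
expected-mean-squares estimators are closed form:

* `Vr = MS_error`, `Vge = (MS_gt − MS_error)/r`, `Vg = (MS_g − MS_gt)/(rt)`

with negative estimates truncated at zero and flagged. These equal REML
whenever interior (verified against `lme4` in the tests), and the
shrinkage predictor `BLUP_i = μ + h²mg (ȳ_i − μ)` equals the explicit
Henderson mixed-model-equation solution (verified to 1e-8). `Vph` is
defined as `Vg + Vge + Vr`, `h²mg = Vg/(Vg + Vge/t + Vr/(tr))`, accuracy is
`√h²mg`. Prediction intervals use the error degrees of freedom and
prediction-error variance `(1 − h²mg)·Vg`, the variance of
`g_i − BLUP(g_i)` in the balanced case. No general unbalanced REML is
claimed: unbalanced input is an error, which keeps every number in this
module verifiable against closed forms.

## Multivariate summaries

Correlations and PCA run on genotype-mean trait matrices per treatment
(replicate-level input would mix residual noise into the biplot).
Correlation P values come from the t transform, unadjusted by default with
optional Benjamini–Hochberg (the conservative choice is left to the user
because the source analysis states none). PCA standardises by default
(correlation-matrix PCA) and fixes component signs so the
largest-magnitude loading is positive, making scores reproducible across
eigen solvers.

## The synthetic cohort generator

`default_study_spec()` encodes the study conditions as a generative model
with known ground truth; it is first-class, tested code, not a fixture.
On the natural scale:

```
y = μ(trait, row) · m(trait, trt, row) · a(trait, trt, archetype) · p
    · e^(g − Vg/2) · e^(ge − Vge/2) + ε,    truncated at 0
```

* `μ` — control baselines per trait and row type, anchored to the
  published row-type levels (two-row control yield 4.7 g, main-ear grain
  number 24 vs 40.63, etc.).
* `m` — multiplicative treatment effects encoding the published
  panel-level responses (two-row yield 2.45 g under `Ds` and 2.2 g under
  `Dd`; six-row reductions 47.52%/44.24%; main-ear grain weight
  −53.12%/−54.42%). The published summaries quote the two-row single-stress
  reduction as "48%", which matches 2.45/4.7 exactly.
* `a` — archetype stress-retention modifiers. Three planted tolerance
  archetypes mirror the panel's empirical groups: 14 *main-ear preservers*
  (yield retention ≈ 65% of control, high main-ear and side-ear
  retention), 6 *side-ear compensators* (≈ 52%), 8 *susceptibles* (≈ 27%,
  main-ear parameters near zero at 8% retention, biomass *increasing* to
  ≈ 109% of the panel-average change). Modifiers are normalised within
  each row type so row-level means equal `m` exactly; they apply only
  under stress.
* `p` — a genotype-specific double-stress priming factor, `N(1, 0.35)`
  truncated at 0.05, applied to the `Dd` response of yield traits. The SD
  is set so roughly half the genotypes out-yield their single-stress level
  under double stress (the published count is 14 of 28, with per-genotype
  ratios spanning 43–190%).
* Noise: mean-one lognormal genotype (`Vg = 0.04`, CVg ≈ 20%) and
  genotype × treatment (`Vge = 0.01`) effects, plus additive residuals
  with an 8% replicate CV — deliberately tight values reflecting a
  controlled phytotron design, chosen once so that the planted archetypes
  are recoverable by the default clustering (the design's linchpin
  recovery property). Because all multiplicative effects are mean-one,
  every cell's expectation equals `μ·m·a` exactly
  (`expected_cell_means()`), which the Monte-Carlo moment tests exploit.

An additive-scale variant (`variance$scale = "additive"`,
`y = μ·m·a + g + ge + ε`) exists for variance-component recovery
experiments where the truth must be the literal `Vg`/`Vge`/`Vr`.

**What the generator does not emulate.** Trait values are drawn
marginally given the shared genotype/archetype/priming effects; arithmetic
identities between measured traits (e.g. `GY = MSW + SSW`,
`DENS = SPS/EaL`) hold only in expectation, not record-wise. There is no
physiological simulation and no unbalanced or missing-data structure.
Consequently, passing recovery tests demonstrates that the *methods*
behave correctly under the stated statistical structure — not that real
field data will be as separable. In particular, the synthetic PCA
variance-explained percentages are not calibrated to the published ones:
the generator reproduces group-level means, not the full covariance
spectrum of real trait data.

## Numerical and reproducibility choices

* All randomness flows through one seed per simulation
  (`set.seed(seed, "Mersenne-Twister", normal.kind = "Inversion")` with a
  documented draw order); identical (spec, seed) pairs give identical
  tables, and specs round-trip through YAML at 17 significant digits.
* Missing values are explicit `NA`s, never zero-filled; balanced-design
  operations refuse unbalanced cells instead of imputing, because the EMS
  formulas assume balance.
* Zero denominators in derived traits and zero control means in change%
  become `NA` with a note, never infinities.
* Treatment labels are matched case-sensitively after whitespace
  stripping, with a documented alias map (`"control"→C`, `"single"→Ds`,
  `"double"→Dd`) for external tables.
* Degenerate inputs have defined behaviour: all-equal values share letter
  "a"; `SI = 0` makes DSI `NA` with a warning; `h²mg` hits 0 and 1 exactly
  in the corresponding degenerate generators.

## Problem sizes used in the tests

The packaged checks run the full 28 × 3 × 4 design where the claim is
about the study conditions (classification recovery pooled over 20
cohorts; clustering recovery at a stated seed), 500 simulated trials for
variance-component recovery at the design size, and 1,000 null
simulations for the type-I-error calibrations of the letter display and
the correlation P values — sizes chosen so Monte-Carlo standard errors are
small relative to the tolerances being asserted. The acceptance script
averages panel statistics over 60 replicate cohorts for the same reason.

## Known limitations

* Balanced designs only; no REML for unbalanced data and no imputation.
* Single-trait BLUP; no multi-trait or marker-based prediction.
* The published group memberships may depend on the (unstated) distance,
  linkage and scaling of the original heatmap; the defaults here are a
  documented choice, not a certainty.
* Whether main-ear density is measured or equals `SPS/EaL` is unstated;
  it is treated as measured.
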