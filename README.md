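# parotidbp

Spatially varying dose constraints for the contralateral parotid gland
(CPG) in head-and-neck radiotherapy, via **artificial base plans**.

## The idea

Post-radiotherapy loss of stimulated saliva output is conventionally
managed by bounding the *mean* CPG dose, but the gland is not functionally
homogeneous: its caudal-anterior region — home to the secretory duct and
the densest stem/progenitor-cell population — predicts toxicity far better
than the rest. This package makes a conventional optimizer spatially aware
without touching the optimizer:

1. **Subsegment** the CPG into 18 equal-volume cells ranked S1 (most
   important) to S18 by relative importance to saliva output.
2. **Synthesize an artificial base plan**: a dose distribution that is
   nonzero only inside the CPG, giving each subsegment a uniform dose
   proportional to its importance (five standard variants: `BP_10`,
   `BP_20`, `BP_30` scale importance by D0 = 10/20/30 Gy; `BP_20,5` keeps
   only S1–S5 of the 20 Gy variant; `BP_top5` puts a flat 50 Gy on S1–S5).
3. **Load it as pre-existing dose** and re-optimize with two ordinary
   whole-gland constraints whose values absorb the base plan: CPG maximum
   dose bounded by the base-plan maximum plus a 0–15 Gy margin, and the
   clinical mean bound shifted up by the base-plan CPG mean.

The optimizer, believing the important subsegments are already dosed,
steers delivered dose away from them — at matched target coverage.

The package also ships DICOM RT-STRUCT/RT-DOSE I/O, a synthetic
head-and-neck phantom generator (no external data needed anywhere), a Hill
dose-response ensemble predicting stimulated saliva output at one year, and
a small demonstration fluence optimizer that shows the mechanism end to
end.

## Worked example

```r
library(parotidbp)

phantom <- make_phantom(phantom_config(seed = 42L))   # synthetic case
masks <- phantom_masks(phantom)                       # CPG + PTV masks
table <- importance_table_synthetic()
ranked <- assign_ranks(partition_equal_volume(masks$CPG), table, "right")
ranked
#> <parotid_labelmap> rank (S1..S18) labels, 1927 voxels, 65 x 52 x 57

suite <- make_variant_suite()
bp <- build_base_plan(ranked, masks$PTV, suite$BP_30, scaling_factors(table))
subsegment_means(bp, ranked)
#> # A tibble: 18 × 3
#>    rank n_voxels mean_dose
#>   <int>    <int>     <dbl>
#> 1     1      107     26.9
#> 2     2      107     21
#> 3     3      107      5.36
#> 4     4      107     10.3
#> 5     5      107      1.08
#> 6     6      107      4.85
#> # ℹ 12 more rows
```

(Rank 2 sits at exactly 30 × 0.7 = 21 Gy; ranks whose cells intersect the
PTV average lower because the base plan is zeroed in the CPG–PTV overlap so
that target coverage is never penalized.)

```r
constraint_set(bp, masks$CPG, clinical_mean_bound = 20, dmax_margin = 10)
#> # A tibble: 1 × 5
#>   cpg_dmax_bound cpg_mean_bound_shifted dmax_margin bp_max bp_mean_cpg
#>            <dbl>                  <dbl>       <dbl>  <dbl>       <dbl>
#> 1             40                   24.5          10     30        4.46

means <- subsegment_means(phantom$clinical_dose, ranked)
saliva_predict(means$mean_dose, hill_params_synthetic())
#> <saliva_prediction> S = 0.4928 of baseline (total loss 0.5072)
```

End-to-end demonstration (control vs base-plan-constrained optimization at
matched PTV coverage, on a coarse 4 mm grid for speed):

```r
cmp <- matched_coverage_pair(
  make_phantom(phantom_config(grid_spacing = 4, seed = 7L)),
  make_variant_suite()$BP_30)
cmp
#> <bp_comparison> BP_30 vs control at matched V98 (0.996 vs 0.999)
#>   S1 mean: 39.98 -> 22.33 Gy;  S: 0.624 -> 0.644 (+3%)
```

Mean dose to the most important subsegment drops from 40 to 22 Gy while
target V98 stays matched within 0.005 and predicted saliva output rises.
`tidy(cmp)`, `glance(cmp)` and `autoplot(cmp)` give per-rank tables and
plots.

A command-line interface covering the same pipeline (phantom generation,
subsegmentation, base-plan construction, constraint reporting, plan
evaluation, outcome prediction, demonstration run) lives at
`system.file("cli", "parotidbp.R", package = "parotidbp")`; see the header
of that script for all commands.

**Placeholders, clearly labelled:** the shipped importance table and Hill
parameters (`importance_table_synthetic()`, `hill_params_synthetic()`, and
their JSON copies under `inst/extdata/`) are synthetic stand-ins with the
documented structure — the clinically fitted values are not
redistributable. Replace them via `read_importance_table()` /
`read_hill_params()` for any real use.

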