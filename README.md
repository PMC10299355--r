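# defolmap

Rapid assessment of insect-pest defoliation from aerial imagery, with
spatial pattern statistics and survey economics.

When a defoliating outbreak (for example beet armyworm, *Spodoptera
exigua*, in soybean) hits a patchwork of field blocks, managers need three
answers fast: **how much** foliage is gone, **where** the damage clusters,
and **whether** a drone survey beats sending a crew. defolmap implements
that workflow end to end for agronomists, extension entomologists and
remote-sensing analysts:

* **Defoliation quantification** — green-pixel counting on RGB
  orthomosaics via the excess-green index (ExG = 2G − R − B > τ),
  calibrated against an undamaged reference area:
  defoliation % = 100 (1 − gf_block / gf_reference), plus the standard
  ground-survey damage categories (none / low / medium / high / severe).
* **Geostatistics** — Matheron semivariograms of per-cell defoliated-pixel
  counts on a square grid (default 54 m); exponential, spherical and
  Gaussian model fits selected by minimum RSS and maximum r²; the degree
  of spatial dependence DD = 100 (C₀+C − C₀)/(C₀+C) with weak (≤ 25),
  moderate, strong (≥ 76) classes.
* **SADIE** — Spatial Analysis by Distance IndicEs built on an exact
  transportation solve of the distance to regularity D; index of
  aggregation I_a = D_obs / mean(D_perm), permutation probability P_a, and
  per-unit patch/gap clustering indices v_i, v_j with |v| > 1.5 marking
  strong cluster membership.
* **NDVI change detection** — NDVI = (NIR − Red)/(NIR + Red) on
  before/during/after raster triplets; loss, regrowth and overlap maps.
* **Survey economics** — C_aerial = (T_UAS + T_analysis)(F_expert +
  F_technology)/N per block against C_ground = F_labor · T_ground/N, with
  time and cost breakeven block counts.
* **Synthetic scenes** — Gaussian random fields with a chosen variogram,
  rendered vegetation/soil RGB scenes with per-pixel truth, and NDVI
  triplets, so the whole pipeline is testable without imagery.

## Worked example

```r
library(defolmap)

## simulate a spatially aggregated damage field and render it
grid  <- grid_spec(cell_size = 54, n_rows = 12, n_cols = 12)
pars  <- variogram_params("exponential", nugget = 0.2, partial_sill = 0.8,
                          range_eff = 540)
field <- generate_damage_field(pars, grid, seed = 1)
scene <- render_scene(field, grid, px_per_side = 10, seed = 2)
scene

## quantify defoliation against a pristine reference
rep <- estimate_block_defoliation(classify_green(scene$rgb),
                                  reference_green_fraction = 1)
rep[, c("defoliation_pct", "category")]

## spatial structure of the per-cell damage counts
counts <- count_damage_per_cell(scene$truth_mask, grid,
                                pixel_size = scene$pixel_size_m)
best <- select_best_model(fit_variogram_models(
  empirical_semivariogram(counts, n_bins = 10)))
best

## SADIE aggregation test
sadie(counts, K = 999, seed = 3)

## is the drone survey worth it?
breakeven(survey_cost_params(), "time")$breakeven_N
```

Output:

```
Synthetic damage scene: 120 x 120 px (5.4 m/px), 12 x 12 cells
  defoliated pixels: 9060 of 14400 (62.9%)
  defoliation_pct category
1        57.22222     high
Variogram fit (gaussian model)
  nugget C0 = 289.8, partial sill C = 325.8, total sill = 615.6
  effective range = 345.8 m
  r2 = 0.977, RSS = 2112
  degree of spatial dependence DD = 52.9% (moderate)
SADIE analysis of 144 units (K = 999 randomizations)
  distance to regularity D = 2.881e+05
  index of aggregation Ia = 2.198 (Pa = 0.0010)  [significant aggregation]
  mean clustering indices: patches vbar_i = 2.026 (Pvi = 0.0010), gaps vbar_j = -2.028 (Pvj = 0.0010)
[1] 2
```

Reading it: the simulated outbreak removed ~57% of the canopy relative to
the reference (category *high*; the truth is 62.9% and the gap is the
color jitter pushing some soil pixels past the green threshold). About
half the count variance is spatially structured (DD = 52.9%, *moderate* —
the rendering's binomial pixel noise contributes nugget on top of the
field's structure), SADIE confirms significant aggregation into patches
and gaps (I_a = 2.2, P_a = 0.001, mean |v| ≈ 2 > 1.5), and the aerial
survey's person-hours beat the ground crew's from the second block on.

`run_pipeline()` chains all stages (simulate → defoliate → grid →
variogram → SADIE → NDVI → economics) from one seeded config and writes
CSV/JSON/PNG products plus a manifest; `inst/cli/defolmap.R` is a thin
command-line wrapper with `run`, `econ`, `variogram` and `sadie`
subcommands.

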