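# habscape

Scenario-driven land-use simulation coupled with habitat-quality assessment,
for landscapes under joint urbanization and agricultural-reclamation
pressure (the motivating system is a coastal delta plain with eight land
classes: cultivated, garden, forest, grassland, construction, water body,
wetland and saline-alkali unused land). The package is aimed at landscape
ecologists and planners who want to ask: *given a calibration pair of
land-use maps and a set of planning scenarios, what does each scenario do to
habitat quality?*

## The model chain

1. **Demand** — a Markov chain calibrated on the land-use pair
   (t0 → t1) projects per-class cell demands to the horizon:
   `S_{t+1} = S_t · P^n`, with fractional `n` (horizon years over
   calibration years) via matrix eigenpowers. Planning scenarios may
   override the projection with tabled demands.
2. **Suitability** — a one-hidden-layer neural network (sigmoid units,
   cross-entropy, fixed seed) maps 15 normalized driver rasters (terrain,
   distances, socioeconomic, climate) to per-class occurrence
   probabilities, renormalized so `Σ_k sp(x, k) = 1` on every cell.
3. **Allocation** — a cellular automaton moves cells from surplus to
   deficit classes by roulette competition over
   `TProb = sp · Ω · Inertia_p · (1 − cost)`, where `Ω` is the weighted
   3×3 neighborhood share, `Inertia_p` self-adjusts from the demand gaps of
   the last two iterations, and `cost ∈ {0, 1}` encodes the scenario's
   conversion allowances. Restricted areas (ecological redline, permanent
   farmland) are frozen. Validation against an observed map reports overall
   accuracy and Cohen's kappa.
4. **Habitat quality** — InVEST-style scoring
   `Q_x = H_j (1 − D_x^z / (D_x^z + k^z))` with `z = 2.5`, `k = 0.5`, where
   the degradation index `D` accumulates distance-decayed influence
   (linear `1 − d/d_max`, or exponential `exp(−2.99 d/d_max)` truncated at
   `d_max`) of six threat types (urban, rural, transportation, mining,
   cultivated, saline-alkali land), weighted by threat weight and per-class
   sensitivity. Quality maps are graded into five bins and compared across
   scenarios.

Four packaged scenarios (S1 business-as-usual, S2 fast cultivated-land
expansion, S3 ecological security, S4 sustainable development) reproduce
the printed planning parameters (demands in hm², neighborhood weights,
conversion allowances, threats, sensitivities) verbatim; a synthetic-
landscape generator provides fully reproducible inputs, so the entire
pipeline runs and is tested without any external data.

## Worked example

```r
library(habscape)
res <- run_pipeline(list(seed = 42))   # 120 x 120 synthetic landscape, S1-S4
cat(sprintf("hindcast: overall accuracy %.3f, kappa %.3f\n",
            res$validation$overall, res$validation$kappa))
print(res$summary[, c("scenario", "mean_q", "Lower", "Higher",
                      "iterations", "converged")], digits = 3)
```

```
hindcast: overall accuracy 0.899, kappa 0.873
  scenario   mean_q Lower Higher iterations converged
1       S1 7.34e-08   100      0          1      TRUE
2       S2 6.78e-08   100      0          1      TRUE
3       S3 7.94e-08   100      0          1      TRUE
4       S4 8.03e-08   100      0          3      TRUE
```

The hindcast line re-simulates the later calibration map from the earlier
one and scores the agreement — kappa well above the 0.75 usually taken as
reliable. Each scenario row shows the mean habitat quality of the simulated
horizon map, the share of cells in the lowest and highest quality grades,
and the automaton's convergence. On this synthetic landscape the literal
(unnormalized) degradation sum saturates — thousands of threat-source cells
within each kernel push quality toward zero, hence the tiny means; the
scenario *ordering* (S4 sustainable development highest, business-as-usual
and expansion lowest) is the informative output, and
`degradation_index(..., normalize_kernels = TRUE)` provides the
unit-mass-kernel variant if absolute levels are wanted. See the methods
vignette (`vignettes/habscape-methods.Rmd`) for the full discussion.

A thin CLI over the same functions lives at `inst/cli/habscape.R`
(subcommands `run`, `synth`, `fit-transition`, `quality`, `validate`).

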