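# spagranger

Directional regulator→target inference from spatial transcriptomics, for
analysts who want to know not just *which* genes co-vary across a tissue
but *which way the influence points and how far it reaches*. Typical users
have a cells × genes UMI count matrix with 2-D coordinates (Slide-seq,
Visium-scale bead data, imaging-based panels) and a curated candidate list
of TF→target or ligand→receptor pairs.

## The idea

Granger causality says x causes y when x's past improves prediction of y
beyond y's own past:

```
y_t = Σ_ℓ α_ℓ y_{t−ℓ} + Σ_ℓ β_ℓ x_{t−ℓ} + ε_t ,   causal ⇔ some β_ℓ ≠ 0.
```

Tissue has no time axis, but layered tissue has a *depth* axis. The package

1. learns a smooth scalar spatial potential per cell (the **isodepth**
   d(x, y), the direction of maximum spatial expression variation), with a
   continuous piecewise-linear 1-D expression model h(d) and Poisson/UMI
   count likelihood;
2. orients a k-nearest-neighbor graph of cells (k = 7) from higher to lower
   isodepth — strictly descending a scalar field, the result is a DAG;
3. aggregates each candidate regulator over ℓ-step graph ancestors with
   row-normalized adjacency powers `(Aᵀ)^ℓ`, ℓ = 1…L, and trains per target
   a small neural network `ŷ = σ(Σ_ℓ (Aᵀ)^ℓ X W₁ℓ + y_self w_s + b₁) W₂ + b₂`
   whose first layer carries a **hierarchical group lasso over lag
   suffixes** (longer lags penalized more), optimized by proximal gradient
   descent — an exact prox with true zeros;
4. sweeps the penalty λ over a grid, keeps fits whose first-layer sparsity
   is strictly between 5% and 95%, and ensembles regulator scores across
   the valid fits. Each detected pair gets a **lag** — the graph distance
   at which the regulator acts, a proxy for its spatial range. Inverting
   the isodepth (d′ = max d − d) reverses every edge, so both directions of
   information flow can be probed.

Everything is testable against ground truth: the built-in generator plants
lagged interactions on a known DAG, and on directed-path graphs the model
reduces exactly to classical time-series Granger causality, where an OLS
F-test is the oracle.

## Worked example

Five hundred cells in a three-layer strip, 20 genes, five planted
interactions (lags 1–3) among 40 candidate pairs:

```r
library(spagranger)
bench <- benchmark_suite("easy", seed = 7)
bench$dataset
#> spatial_dataset: 500 cells x 20 genes
#>   coordinate range: x [8.411, 996.7], y [0.884, 599.3]
#>   labels: layer0, layer1, layer2

fit <- fit_isodepth(bench$dataset, isodepth_config(n_pieces = 3, epochs = 400, seed = 1))
cor(fit$field$values, bench$truth$true_isodepth, method = "spearman")
#> -0.943
```

The fitted isodepth tracks the generative depth axis almost perfectly —
with inverted sign, which is expected: the potential is only identified up
to a monotone transform. Probing both orientations resolves it:

```r
cfg <- granger_config(max_lag = 5, epochs = 500, hidden_width = 8,
                      lambda_count = 8, seed = 1)
tab <- infer_interactions(bench$dataset, bench$pairs, fit$field, cfg,
                          direction = "both", context = "strip")
head(as.data.frame(tab), 8)
#>   regulator target pair_type direction score lag context
#> 1       TF4    TG4 tf_target  backward 0.465   1   strip
#> 2       TF1    TG1 tf_target  backward 0.382   1   strip
#> 3       TF5    TG5 tf_target  backward 0.368   2   strip
#> 4       TF2    TG2 tf_target  backward 0.236   2   strip
#> 5       TF1    TG1 tf_target   forward 0.224   1   strip
#> 6       TF3    TG2 tf_target  backward 0.198   2   strip
#> 7       TF5    TG5 tf_target   forward 0.193   1   strip
#> 8       TF4   TG10 tf_target  backward 0.178   2   strip
```

The top four pairs are all planted ones, detected in the backward run —
the direction that descends the *generative* potential, since the fitted
sign was flipped. Scores are ensemble first-layer group norms (relative
evidence, not p-values); `lag` is the graph distance at which the
regulator's influence peaks, so `TF5 → TG5` at lag 2 reaches across
roughly two neighbor hops while the lag-1 pairs act on immediate
neighbors. `summarize_lags()` turns the lag column into per-regulator
spatial-range summaries, and `rank_frequent_targets()` lists targets hit
by many regulators.

When the generator's own potential is supplied instead of the fitted one
(`bench$field`), the same configuration ranks every planted pair above
every decoy (AUPRC = 1) and recovers all five planted lags exactly — the
numbers `scripts/acceptance.R` recomputes.

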