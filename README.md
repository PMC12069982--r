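# nutriclass

Hybrid metaheuristic clustering and fuzzy gradient boosting for child
nutritional-status classification.

Childhood malnutrition surveillance classifies children under five into
WHO categories derived from anthropometric z-scores — severe wasting
(weight-for-height z < −3), wasting (z < −2), underweight
(weight-for-age z < −2), stunting (height-for-age z < −2) and
overweight (weight-for-height z > +2).  nutriclass implements, as a
tested R package, a hybrid analysis of such data for biostatisticians
and epidemiological modellers:

* **Fire Hawk Optimizer (FHO)** — a seeded population metaheuristic for
  box-constrained minimization.  Candidates split each iteration into
  *hawks* (the elite) and *prey*; hawks move by
  `Fh' = Fh + r₁·GB − r₂·Fh_near` toward the global best `GB`, prey
  move relative to their territory's hawk and the "safe places" (mean
  prey positions), with elitism via the archived incumbent.
* **FHO-K-Means** — clustering by minimizing the within-cluster sum of
  squares `E = Σ_k Σ_{j∈k} ‖y_j − c_k‖²` over centroid encodings, with
  a one-step k-means refinement of every candidate and farthest-point
  reseeding of empty clusters; the number of clusters is selected by
  mean silhouette over a candidate range.
* **EGBF** — second-order gradient-boosted trees (softmax
  cross-entropy; leaf weight `u* = −P/(Q+β)`, structure score
  `−½ Σ P²/(Q+β) + αH`) whose split selection is modulated by fuzzy
  entropy over triangular low/medium/high feature memberships:
  candidates are scored by `(1−λ)·ĝ_struct + λ·ĝ_fuzzy`, λ = 0 reducing
  to plain second-order boosting.
* **Synthetic data** — child-level cohorts with label-consistent
  z-scores and country-level prevalence tables with planted cluster
  structure, so every stage is testable offline.
* **Pipeline** — simulate/load → min-max normalize → cluster (cluster
  id appended one-hot) → stratified split → train → evaluate, fully
  determined by one global seed.

## Worked example

```r
library(nutriclass)

cfg <- pipeline_config(cohort = cohort_spec(n_records = 1000, seed = 1),
                       fho = fho_config(pop_size = 15, max_iters = 20),
                       egbf = egbf_config(rounds = 50), seed = 42)
report <- run_pipeline(cfg)
report
#> nutriclass pipeline report (n = 1000 )
#>   chosen K: 4  cluster sizes: 180/216/300/304
#>   macro accuracy 0.9778  sensitivity 0.9330  F1 0.9338  MSE 0.01607
report$metrics
#>            class   n sensitivity specificity precision accuracy    f1      mse
#> 1 severe_wasting  56       0.982       0.992     0.965    0.990 0.973 8.58e-03
#> 2        wasting  52       0.846       0.960     0.815    0.940 0.830 4.14e-02
#> 3    underweight  50       0.860       0.984     0.915    0.963 0.887 2.55e-02
#> 4       stunting  43       0.930       0.996     0.976    0.987 0.952 1.24e-02
#> 5     overweight  50       1.000       1.000     1.000    1.000 1.000 1.92e-07
#> 6       adequate  49       0.980       0.988     0.941    0.987 0.960 8.54e-03
#> 7          macro 300       0.933       0.987     0.935    0.978 0.934 1.61e-02
```

The pipeline simulated a 1000-child cohort, normalized its ten numeric
features to [0, 1], clustered them into K = 4 groups with FHO-K-Means,
held out a stratified 30% test set, trained EGBF for 50 rounds, and
evaluated one-vs-rest metrics per class: e.g. 98.2% of severe-wasting
children were recovered (sensitivity) with 96.5% precision, and the
macro row averages the six classes.  Running the same configuration
again reproduces these numbers byte-for-byte — every stage seed derives
from the global seed.

The pieces also work standalone:

```r
# cluster a 152-country prevalence table and pick K
prev <- generate_prevalence_table(152, 4, separation = 8, seed = 1)
x <- apply_minmax(prev[2:7], fit_minmax(prev[2:7]))
ks <- select_k(x, 2:8)          # chosen K = 4 on four planted blobs
autoplot(ks)

# minimize any function on a box
fho_minimize(function(z) sum(z^2), search_space(rep(-5, 5), rep(5, 5)))
```

A thin command-line front-end over the same functions ships in
`inst/cli/nutriclass` (subcommands `simulate`, `cluster`, `train`,
`predict`, `evaluate`, `pipeline`).

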