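# qsardnn

Deep-network QSAR regression for drug discovery: from a raw molecular
descriptor table to a validated activity model, with every stage of the
pipeline — washing, rational splitting, training, variable selection —
reproducible from one seed.

## Who this is for

Quantitative structure–activity relationship (QSAR) modelling maps
precomputed molecular descriptors (MOE/CDK-style numeric columns: logP,
surface areas, charges, …) to a log-scale biological activity (pIC50,
LAC50).  qsardnn is for cheminformaticians who have such a table — often
small, noisy and redundant — and want a regression model whose training
objective, data cleaning and train/test division follow explicit,
auditable rules rather than ad-hoc conventions.

## The model

The regressor is a feed-forward network with tanh hidden layers and a
linear output node, trained by mini-batch SGD against

```
J(W, λ) = −q²  +  (λ/2) Σ_l Σ_ij (W_ij^l)²,
q² = 1 − Σᵢ (h_W(xᵢ) − yᵢ)² / Σᵢ (yᵢ − ȳ)²
```

Because the q² denominator does not depend on the weights, minimising
`J` at `λ = 0` is *exactly* equivalent to maximising q² — the package
asserts this as an algebraic identity.  Training uses inverted dropout
(optional), periodic held-out cost evaluation, early stopping with
best-snapshot restore, and a reduce-on-plateau learning-rate anneal.

Around the core model:

* **Washing** — z-score/min–max normalization; Pauta-criterion (3σ)
  outlier removal measured against each compound's *neighborhood* in
  descriptor space, with removals requiring more than 10 neighbors to be
  statistically significant; greedy pruning of descriptor pairs with
  |Pearson r| above a tolerance (default 0.95); optional PCA.
* **Sphere-exclusion splitting** — a farthest-point variant that
  guarantees every test compound lies within the sphere radius of a
  training compound, with the radius bisected to a requested test
  fraction.
* **Variable selection** — exhaustive or random search over descriptor
  subsets of size k, re-splitting and retraining per subset, scored by
  `min(q²_train, r²_test)`.
* **Applicability diagnostics** — nearest-training-compound Euclidean
  distance attached to predictions; Tanimoto similarity on binary
  fingerprints.
* **Acceptance rule** — a model passes when `q²_train ≥ 0.60` and
  `r²_test ≥ 0.55`.

Everything is configured through one validated `run_config()`, which
round-trips through an XML parameter file.

## Worked example

```r
library(qsardnn)

# a synthetic MOE-style export: 200 compounds, 12 descriptors in
# correlated blocks (rho = 0.97), activity driven by 2 of them,
# one planted 6-sigma activity outlier
tbl <- simulate_descriptor_table(m = 200, n_descriptors = 12,
                                 block_size = 3, rho = 0.97,
                                 active = c(1, 4), noise_sd = 0.2,
                                 n_outliers = 1, outlier_sigma = 6,
                                 seed = 42)

washed <- wash_table(tbl, run_config(radius_quantile = 0.3))
wash_report(washed)
#> # A tibble: 10 × 9
#>    step  kind       name    partner correlation n_neighbors local_mean local_sd
#>  1 pauta compound   cpd0017 <NA>         NA              11     -2.72     0.705
#>  2 pauta compound   cpd0042 <NA>         NA             118     -0.163    1.04
#>  3 prune descriptor d002    d001          0.967          NA     NA       NA
#>  4 prune descriptor d003    d001          0.974          NA     NA       NA
#>  ...                                   # one survivor per correlated block
```

The planted outlier (`cpd0017`, activity 6 local σ from its 11
neighbors' mean) is removed, and each ρ = 0.97 block collapses to its
first column.  Then split, train and inspect:

```r
split <- sphere_exclusion_split(washed, test_fraction = 0.2)
split
#> <split_result> 158 train / 40 test (fraction 0.202, target 0.200),
#>                radius 0.5195, seed compound cpd0081

fit <- train_qsar(washed, split = split, config = run_config(seed = 42))
fit
#> <qsar_model> 4 descriptors -> activity, layers 4-20-20-20-1
#>   q2(train) = 0.986, q2(test) = 0.960, r2(test) = 0.965
#>   (n = 158/40, stopped at epoch 230)
```

Training q² = 0.986 and external-test r² = 0.965 clear the 0.60/0.55
acceptance thresholds (`glance(fit)$accepted` is `TRUE`).  Predictions
take raw descriptor units and replay the stored normalization; the
applicability column reports the distance to the nearest training
compound (0 here — the queried compound is in the training set):

```r
predict(fit, tbl[3, ], applicability = TRUE)
#>   compound_id  .pred      nearest_train_id nearest_train_distance
#> 1 cpd0003      -0.704     cpd0003          0
```

`autoplot(fit)` draws the cost trajectories with the restored snapshot;
`save_model()`/`load_model()` round-trip the model through portable
JSON with bit-identical predictions.  `select_descriptors()` runs the
subset search, and `run_pipeline()` (or the `inst/cli/qsardnn` script)
chains simulate → wash → split → train → predict with every
intermediate artifact materialised.

## Scope

Descriptor *computation* (MOE, CDK), SMILES/SDF parsing, GPU training,
adaptive optimizers and the full Golbraikh–Tropsha acceptability
battery are out of scope.  See `vignettes/qsardnn-methods.Rmd` for the
model details, parameter meanings and design decisions.
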