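---
title: "Models and methods behind qsardnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qsardnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

qsardnn builds quantitative structure–activity relationship (QSAR)
regression models: given a table of compounds described by precomputed
molecular descriptors (MOE/CDK-style exports) and one log-scale activity
column (pIC50, LAC50), it washes the data, divides it rationally into
training and test sets, and fits a feed-forward neural network whose
training objective directly maximises the correlation coefficient
$q^2$.  This vignette records the model, the numerical choices, and the
design decisions that were genuinely open.

## The network and its cost

The regressor is a fully connected feed-forward network with tanh
activations on the hidden layers,
$\tanh(x) = (e^{2x}-1)/(e^{2x}+1)$, and a *linear* output node.  The
default architecture is input–20–20–20–1; with five input descriptors
and biases ignored that is $5\cdot20 + 20\cdot20 + 20\cdot20 + 20\cdot1
= 920$ connection weights (`dnn_count_parameters()`).  The output node
is linear because log-scale activities are unbounded; a tanh output
would cap the dynamic range.  Biases are included by default but are
*never* penalised by weight decay and are excluded from the 920-weight
count, which is a pure connection count.

The training objective is

$$ J(W, \lambda) \;=\; -q^2 \;+\; \frac{\lambda}{2}\sum_{l}\sum_{i,j}
   \bigl(W^l_{ij}\bigr)^2,
\qquad
q^2 = 1 - \frac{\sum_i (h_W(x_i) - y_i)^2}{\sum_i (y_i - \bar y)^2}. $$

Because the denominator $\sum_i (y_i-\bar y)^2$ does not depend on the
weights, $-q^2$ is an affine function of the residual sum of squares:
minimising $J$ at $\lambda = 0$ is *exactly* equivalent to maximising
$q^2$, and the package asserts this as an identity
(`dnn_cost()$total == -dnn_cost()$q2`) rather than a tendency.

### Gradient, mini-batching, and the denominator

Backpropagation gives the exact gradient: the output delta is
$2(h - y)/D$, hidden deltas propagate through $1-\tanh^2$, and the decay
term contributes $\lambda W$.  The gradient is verified against central
finite differences at relative error $10^{-6}$ on every weight of a
small net — the single most important correctness test in the package.

During mini-batch SGD the denominator $D$ is **fixed per training run**
as $\sum_{\text{train}} (y-\bar y)^2$ rather than recomputed per batch.
This keeps every stochastic gradient a constant rescaling of the
mean-squared-error gradient, so the equivalence between minimising $J$
and maximising $q^2$ holds across batches, not only in expectation.  A
per-batch denominator is available (`denominator_mode = "batch"`) but
is not the default: batch-level $\bar y$ fluctuates and breaks the
proportionality.

### Learning-rate scale

A consequence of the $1/D$ factor is that the $q^2$ cost is
*dimensionless*: its gradients are roughly $m \cdot \mathrm{var}(y)$
times smaller than per-sample mean-squared-error gradients.  Step sizes
that look conventional for MSE training (0.01) correspond to steps of
order $10^{-5}$ here and underfit severely.  The default
`learning_rate = 1` therefore corresponds to a conventional per-sample
step of roughly $1/m$; it is stable on every problem size the tests
exercise.  A reduce-on-plateau anneal (halving after every 5
consecutive non-improving evaluations, `anneal = 0.5`) shrinks the SGD
jitter near convergence; set `anneal = 1` to disable.

### Dropout and early stopping

Inverted dropout is applied to hidden activations only (never input or
output): each mini-batch draws a fresh mask, dropped nodes output zero,
survivors are scaled by $1/(1-\text{rate})$, and inference applies no
mask and no scaling.  At rate 0 no random numbers are drawn at all, so
the rate-0 path is bit-identical to inference — a contract the tests
assert.  The default rate is 0: dropout pays off when the parameter
count dwarfs the compound count (it was conceived for nets with
millions of weights), but on the default-sized network it puts a
noise floor of one to two percent unexplained variance under otherwise
clean fits, and weight decay plus early stopping already regularize.
For wide or deep custom architectures, 0.1–0.25 is a reasonable
setting.

Early stopping evaluates the full cost on the held-out set every
`eval_interval` (10) epochs; after `patience` (20) consecutive
evaluations without improvement, training stops and the weight snapshot
from the *best* evaluation — not the last — is restored.  The returned
model therefore reproduces the minimum recorded evaluation cost
exactly.

### Seeding contract

One master seed deterministically derives separate streams for weight
initialisation, epoch shuffles, dropout masks, and subset sampling
(fixed affine maps modulo $2^{31}-1$).  Because the streams are
separate, toggling dropout does not perturb the shuffle sequence, and
every run is bit-reproducible from its config snapshot plus seed.

## Data washing

**Normalization** (z-score default, min–max optional) removes the
arbitrary scale differences of raw descriptor exports; constant columns
are dropped and reported.  The fitted location/scale pairs are stored
in the model so prediction inputs in raw units are transformed
identically.

**Pauta (3σ) outlier washing.**  The premise is the QSAR similarity
principle: compounds close in descriptor space should have similar
activities, and densely sampled activity surfaces are locally normal.
Each compound's neighborhood is the set of other compounds within
radius $r$, with $r$ the 10th-percentile of all pairwise Euclidean
distances — a quantile rule that is scale-free across descriptor
dimensionalities.  A compound is removed only when (a) it has strictly
more than 10 neighbors, because a deviation measured against a sparse
neighborhood is not statistically significant, and (b) its activity
deviates from the neighborhood mean by more than 3 neighborhood
standard deviations.  Statistics are *local* by default: the
neighbor-count rule only makes sense for neighborhood statistics; a
dataset-global variant (`scope = "global"`) is provided for
comparison.  Detection runs once on the original table — removals never
cascade.  Under pure Gaussian activities the two-sided 3σ mass is
≈0.27%, and the measured false-positive rate over 50 seeded replicates
stays below 1%.

**Correlation pruning.**  Two descriptors correlated beyond a tolerance
carry the same signal; the greedy double loop scans columns in file
order and deletes every later not-yet-deleted column whose absolute
Pearson correlation with the current retained column exceeds the
threshold (default 0.95 — the choice is a convention, since no
canonical value exists).  Earlier columns always win, the result
satisfies the bound by construction, and pruning is idempotent.  PCA
(center, covariance, eigendecomposition, order by eigenvalue, project)
is retained as the classical alternative but is not the default: on
strongly collinear descriptor sets the eigenvalue spectrum decays too
smoothly for a principled choice of the component count.

## Sphere-exclusion splitting

External validation needs a test set whose members have training
representatives nearby — otherwise test error conflates model quality
with applicability.  The variant implemented is farthest-point center
selection: the compound with the highest activity seeds the training
set (deterministic, and anchoring the top of the activity range); the
unassigned compound farthest from all centers repeatedly becomes the
next training center, and unassigned compounds within the sphere radius
of a new center become test compounds.  Every test compound is
therefore within the radius of at least one training compound *by
construction*.  The radius that best achieves a requested test fraction
is found by bisection (40 iterations over [0, max pairwise distance]).
Sphere exclusion is a family of algorithms; this member was chosen
because it guarantees the coverage property the split exists for.  The
split depends on the descriptor geometry, so it is recomputed whenever
the descriptor subset changes.

## Variable selection

For small datasets, a wrapper searches descriptor subsets of fixed size
$k$: restrict the table, re-split, retrain with early stopping, and
score.  The default score is $\min(q^2_{\text{train}},
r^2_{\text{test}})$ — demanding quality on both the internal and the
external set simultaneously; a sum-score is available.  Exhaustive
search evaluates all $\binom{K}{k}$ subsets (the complexity is
$O(\binom{K}{k})$ trainings); the random strategy draws distinct
subsets uniformly under a budget, since no better-than-enumeration
traversal is defined for astronomically large $\binom{K}{k}$.  Ties
break by $r^2_{\text{test}}$, then by evaluation order.  Subsets can be
evaluated on several cores; the reduction is ordered, so parallel
results are identical to serial ones.

## Scoring and acceptance

$q^2$ is the fitted-set statistic above (no resampling — the objective
contains none), and can be negative.  $r^2$ is the squared Pearson
correlation between observed and predicted activities on the external
test set, the standard QSAR external-validation convention; being
affine-invariant it is blind to calibration bias, which is why it is
reported *alongside* $q^2$ rather than instead of it (a
coefficient-of-determination variant about a reference mean is
available via `reference_mean`).  A model is accepted when
$q^2_{\text{train}} \ge 0.60$ and $r^2_{\text{test}} \ge 0.55$, both
inclusive.

## The synthetic generator

`simulate_descriptor_table()` emulates the *shape* of descriptor
exports, not their chemistry: block-equicorrelated Gaussian columns
(within a block each column is $\sqrt{\rho}\,z + \sqrt{1-\rho}\,
\varepsilon$, giving exact population correlation $\rho$), a sparse
linear or tanh generative link from a known active subset, Gaussian
activity noise, optional planted outliers displaced by a stated
multiple of their neighborhood activity sd (in dense or deliberately
isolated descriptor regions), and mixed column scales (every third
column ×1000) to exercise normalization.  Defaults: 200 compounds, 30
descriptors in blocks of 3 at $\rho = 0.9$, three active descriptors,
noise sd 0.2.  Passing tests on these tables shows the pipeline's
mechanics are correct; it does not show that real descriptor sets
satisfy the generative assumptions (no molecular graphs, no activity
cliffs beyond the planted outliers, no heavy-tailed descriptor
distributions).

## Problem sizes used by the test-suite and acceptance script

Simulated studies are sized for quick desk-scale runs: 200×5 noiseless
recovery problems for the optimizer, 100×10 planted-pair tables with an
8-8 hidden architecture and a 200-epoch budget for the selection
wrapper (the planted signal is strong, so the search separates the true
pair long before a full-depth run would), 30-compound tight clusters
for planted-outlier detection and 100-compound clusters over 50
replicates for the false-positive rate, and 100 uniform 5-D points for
splitting.  These sizes are the package's own benchmark choices and are
asserted at fixed seeds.  One sizing note: with the neighborhood radius
at the `q`th distance quantile, the average neighbor count is roughly
`q (m - 1)`, so the > 10-neighbor significance rule only engages when
`q (m - 1) > 10`.  The washing benchmarks therefore widen the quantile
(0.7 at m = 30, 0.3 at m = 100) — the appropriate setting for small,
structurally tight series — while the 0.1 default targets datasets of
hundreds of compounds or more.

## Known limitations

* The optimizer is plain SGD with annealing; no momentum or adaptive
  methods.
* $q^2$ here is not leave-one-out cross-validated; reported training
  $q^2$ is optimistic relative to LOO conventions.
* The sphere-exclusion variant is one member of a family; published
  splits produced by other members will not be reproduced exactly.
* Descriptor computation (MOE/CDK), SMILES/SDF parsing, and full
  Golbraikh–Tropsha acceptability batteries are out of scope.
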