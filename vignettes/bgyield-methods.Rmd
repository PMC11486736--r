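---
title: "Yield prediction with missing traits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Yield prediction with missing traits: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgyield)
```

## The problem

Multi-environment maize trials record, for each planting observation, a set
of meteorological aggregates over the growth window, a set of growth traits
(plant height, ear length, disease resistances, several text-valued traits
such as axis color), and the yield at harvest. Raw trial tables are messy in
two specific ways: a substantial fraction of trait cells is missing (lodging,
failed germination, collection errors — typically around 18% of cells), and
planting locations contribute very unequal numbers of observations, because
some regions host many more trial sites than others.

bgyield treats both problems inside a single model. The table is converted to
a bipartite graph; a graph neural network imputes missing trait cells and
predicts yield in one pass; and the regression loss carries a
gradient-harmonizing term that tempers the pull of large residuals, which is
where location imbalance otherwise bites.

## From table to graph

An $n \times (m+1)$ table (features plus yield in the last column) becomes a
complete bipartite graph: $n$ observation nodes $N_i$, $m+1$ feature nodes
$F_j$, and one edge per cell — $n(m+1)$ edges in total. The edge $(i, j)$
carries the z-scored cell value as its scalar weight when the cell is
observed and $0$ when it is missing; missing cells are *present* zero-weight
edges, not absent edges, so every node always sees its full neighborhood.
Feature nodes are initialized with one-hot identity vectors; observation
nodes with their observed-cell indicator (1 where a cell is observed, 0
where missing). Yield cells of evaluation rows are forcibly zeroed and
removed from supervision before any message passing — without this the
transductive evaluation would leak its own labels.

Two preprocessing steps precede graph construction, both fitted on training
rows only and frozen: text traits are label-encoded to positive integers in
first-appearance order (`encode_categoricals()`), and every column —
encoded categoricals and yield included — is z-scored with the *population*
standard deviation (`zscore_normalize()`). Population rather than sample
variance is used throughout (including the weather aggregation below) so
that single-day windows and tiny groups stay well-defined; at the sample
sizes involved the distinction is immaterial.

## The network

Each graph update layer updates nodes from incident edges and then grows
edge embeddings by concatenation:

$$V_i^{l+1} = L_B\!\left(\mathrm{Con}\!\left[\frac{1}{|\varphi_i|}
\sum_{j \in \varphi_i} L_A(\mathrm{Con}[V_j^l, e_{ij}^l]),\; V_i^l\right]\right),
\qquad
e_{ij}^{l+1} = \mathrm{Con}[V_i^{l+1}, V_j^{l+1}, e_{ij}^l],$$

with ReLU after both affine maps $L_A, L_B$, the same transforms for both
node types, and inverted dropout ($p = 0.1$ by default) on node embeddings
during training. The edge update has no parameters: edge dimensions grow
$1 \to 2h+1 \to 4h+1 \to 6h+1$ with hidden width $h$, which is why the
default depth of three layers keeps the growth bounded. A two-layer head
decodes any cell: the final embeddings of the two endpoint nodes are
concatenated and mapped to a scalar. The same head serves trait imputation
(feature columns) and yield prediction (the last column).

Two numerical choices deserve comment.

**Degree-normalized aggregation.** The neighbor aggregate divides the sum by
the neighborhood size $|\varphi_i|$. In a complete bipartite graph
$|\varphi_i|$ is a constant per node type ($m+1$ for observation nodes, $n$
for feature nodes), so this is *exactly* the plain-sum update with a known
constant absorbed into $L_B$ — the model class is unchanged. What changes is
conditioning: ReLU messages have positive mean, so an unnormalized sum over
$n$ neighbors scales feature-node activations by $\mathcal{O}(n)$ per layer,
and at $n = 500$ the forward pass explodes out of the reach of any
reasonable initialization. With the normalization, Glorot-uniform
initialization behaves normally.

**Structured edge embeddings.** Because edge embeddings are pure
concatenations of earlier node embeddings, the training core
(`src/bgnn.cpp`, hand-derived reverse-mode gradients, Adam) never
materializes them: every product against the edge matrix decomposes into
small per-block products against node embedding matrices plus row
expansions, and gradients decompose into grouped sums. The user-facing R
implementation (`bgnn_forward()`, `graph_update_layer()`) materializes the
concatenations literally; the two are tested against each other and against
an independent loop-based oracle, and the compiled gradients are verified by
finite differences.

## Training signal

The total loss is

$$\mathcal{L} = \mathcal{L}_{\text{yield}} +
\lambda \, \mathcal{L}_{\text{rec}},$$

where $\mathcal{L}_{\text{yield}}$ is the chosen regression loss over
training rows with observed yield, and $\mathcal{L}_{\text{rec}}$ is a
self-supervised reconstruction loss: each epoch a fresh random 10% of
observed feature cells is hidden from the input (edge weight and mask bit
zeroed) and the head must reconstruct them ($\lambda = 1$ by default;
$\lambda = 0$ disables the term exactly). This re-hiding is what teaches the
network to impute.

One additional hiding mechanism addresses an asymmetry the re-hiding does
not: training rows carry their own yield on an incident edge, while
evaluation rows carry 0 there. Left alone, the network learns to copy the
incident yield edge and collapses to the mean on evaluation rows. Each
epoch a random fraction `yield_hide_frac` (default 0.5) of training-row
yield edges is therefore hidden from the *input* — supervision is unchanged
— so that half the supervised rows per epoch look exactly like evaluation
rows. Setting `yield_hide_frac = 0` recovers the plain formulation.

Optimization is full-graph Adam (learning rate $10^{-3}$), 500 epochs by
default with early stopping on a training-loss plateau (patience 100 epochs
at relative tolerance $10^{-4}$); a full-scale run in the spirit of the
original protocol would use 20000 epochs, which the `epochs` argument
accepts. All randomness — initialization, dropout, re-hiding — flows from
one seed through R's RNG, so seeded runs are bit-reproducible.

## The gradient-harmonized loss

For residual $d_i = \hat y_i - y_i$ the loss adds a bounded harmonizing term
to L1:

$$\mathcal{L}_{\mathrm{GHM}} = \frac{1}{N}\sum_i \left(|d_i| +
\frac{|d_i|}{\sqrt{d_i^2 + \alpha^2}}\right), \qquad \alpha = 0.3.$$

The added term saturates at 1 for $|d_i| \gg \alpha$ and falls to 0 at
$d_i = 0$: samples with moderate residuals — in imbalanced data,
disproportionately the under-sampled locations — receive extra gradient
weight relative to plain L1, while far-off outliers are not further
amplified. As $\alpha \to \infty$ the term vanishes and the loss reduces to
L1 (this limit is tested).

The defining equation is sometimes written with a *signed* numerator,
$d_i/\sqrt{d_i^2+\alpha^2}$. `ghm_loss()` offers both variants, and the
signed form is its literal default; but `train_bgnn()` deliberately trains
with the absolute variant. The signed per-sample loss is not minimized at
$d = 0$: setting its derivative $\operatorname{sign}(d) +
\alpha^2 (d^2+\alpha^2)^{-3/2}$ to zero for $d < 0$ gives a minimizer at

$$d^\ast = -\sqrt{\alpha^{4/3} - \alpha^2} \approx -0.33
\quad (\alpha = 0.3),$$

i.e. optimizing the signed loss converges to a systematic under-prediction
of a third of a standardized yield unit, and the per-sample loss itself is
negative there ($|d^\ast| + d^\ast/\sqrt{{d^\ast}^2+\alpha^2} < 0$), so a
training loss below zero is the telltale symptom. Imputed cells and yield
predictions alike inherit the downward shift. The absolute variant removes
the bias while leaving the harmonizing behavior intact; for non-negative
residuals the two variants coincide, as do their values in the closed-form
checks.

## Evaluation protocol

`split_by_missingness()` implements the record-quality split: rows with at
most one missing feature train, rows with two or more test (the boundary
case of exactly two, unassigned by the stated criteria, goes to test so
that the training criterion holds exactly). This split presumes the
real-table pattern where missingness concentrates in a subset of records.
Under *uniform* cell-level MCAR with many columns nearly every row has two
or more missing cells and the rule degenerates — the package's own
synthetic-recovery checks therefore pass an explicit random row split via
`test_rows`. Metrics (MAE, RMSE, $R^2$, globally and per location group)
are always computed after inverting the z-transform, in original yield
units.

The random-deletion benchmark (`imputation_experiment()`) starts from rows
with complete features, deletes cells at 10/20/30% MCAR, and compares
mean, median, kNN (Euclidean distance over mutually observed columns,
$k = 5$) and the network in its trait-only variant — the yield node is
removed entirely, and only the reconstruction loss trains, so the
comparison isolates imputation. MAE is computed on deleted cells only, in
original units. The ablation harness (`ablation()`) trains the eight unique
configurations of {dropout on/off} × {2/3/4 layers} × {L1, L2, GHM with
$\alpha \in \{0.3, 0.5, 0.7\}$} with a shared seed and an identical split.

## The synthetic generator

Real trial tables are not redistributable, so `simulate_trial_data()`
generates tables with the statistical structure the method exploits, at a
default scale of $n = 500$ observations and $m = 40$ features (20 weather +
20 traits, 5 of them categorical) — the dimensionality of a realistic trial
table at roughly 1/26 of its sample count, chosen so the full test suite
runs at desk scale:

* **Weather block**: equicorrelated Gaussian ($\rho_w = 0.3$) via a shared
  per-row factor, standing in for shared regional climate.
* **Trait block**: each trait latent loads on one weather column with
  strength $\rho = 0.6$ plus independent noise (unit marginal variance), so
  traits are partially recoverable from weather — the cross-block
  correlation the network exploits when imputing.
* **Categorical traits**: the last 5 trait latents are quantile-binned into
  4 labels; the yield signal uses the latents, the table shows the labels.
* **Yield**: linear terms on the first 5 weather columns and 5 trait
  latents plus 3 weather-by-trait interaction products, then Gaussian noise.
  Everything is jointly Gaussian, so the signal variance follows in closed
  form from the configuration covariance (Isserlis for the product terms),
  and the noise scale is calibrated so the true $R^2$ equals a target (0.8
  by default). The closed form is tested against the empirical signal
  fraction at $n = 5000$.
* **Groups**: location sizes follow a power law ($\propto k^{-1.5}$ over 8
  groups by default), emulating dense versus sparse planting regions;
  per-group residual multipliers let tests construct the imbalanced-noise
  scenario (one group 10 times smaller with twice the residual scale) under
  which the gradient-harmonized loss is compared against L1.
* **Missingness**: MCAR deletes feature cells independently (18% by
  default, matching typical raw-table missingness); MNAR deletes through a
  logistic link on the standardized cell value, intercept-calibrated to the
  same overall rate. Yield cells are never deleted by the generator —
  hiding evaluation yields is the training harness's job, and the two
  mechanisms stay separate.

What the generator does *not* emulate: real weather marginals and seasonal
structure, cultivar genetics, geography, and missingness that correlates
across columns within a record (real trait loss from lodging is row-wise,
not cell-wise). Passing recovery tests on these tables shows the machinery
works under the stated statistical structure; it does not certify accuracy
on any real trial table.

## Problem sizes and runtimes

The package's own checks run at deliberate desk scale: recovery at
$n = 500$, $m = 40$, 500 epochs and three seeds; the imbalance comparison
at $n = 360$, $m = 10$ across three seeds; the deletion benchmark and
ablation grid at $n \le 200$ with reduced epochs and width. These sizes
were chosen as the smallest at which the statistical effects of interest
are reliably visible; the defaults scale up unchanged.

## Known limitations

* Prediction is transductive: a fitted model scores the rows of the table
  it was trained with. Scoring genuinely new rows requires rebuilding the
  graph with those rows included and re-running the forward pass.
* Edge-embedding concatenation makes depth expensive in principle (edge
  dimension grows linearly with depth); the structured implementation keeps
  3–4 layers cheap, but very deep stacks would need an edge projection,
  which the update rule deliberately omits.
* Categorical traits are treated as ordinal integers by the network and
  rounded back to the nearest valid label on output; unordered categories
  with many levels would deserve one-hot feature nodes instead.
* The whole graph is one batch; tables far beyond $10^5$ cells would need
  minibatching, which is out of scope here.
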