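---
title: "Extracting feature importance from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting feature importance from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrelevance)
```

## The problem

A molecular-dynamics trajectory of a biomolecule visits a handful of
metastable conformational states. Given frames labeled by state (or not
labeled at all), which atoms, residues or inter-residue contacts actually
distinguish the states? An answer in the form of a normalized per-feature
*importance profile* turns raw simulation output into candidate collective
variables, mutation targets and mechanistic hypotheses.

`mdrelevance` implements a common protocol around six estimators of that
profile -- three unsupervised (PCA loadings, a Bernoulli restricted
Boltzmann machine, an autoencoder) and three supervised (per-feature
symmetric Kullback--Leibler divergence, random-forest mean decrease
impurity, a multilayer-perceptron classifier) -- with the neural-network
estimators made interpretable through layer-wise relevance propagation
(LRP). A synthetic toy model with known displaced atoms provides ground
truth, and two accuracy scores quantify how well each method recovers it.

## The toy model

`generate_system()` places `n_atoms` atoms uniformly in a cube spanning
`[-b, b]` per axis and assigns each of `n_states` states a disjoint set of
`n_important_per_state` atoms. In linear mode every important atom of a
state is translated by one shared vector of norm `displacement_magnitude`
whose direction depends on the state index; in nonlinear mode the first
atom is translated and each subsequent atom is rotated about the previous
one. `generate_frames()` then draws i.i.d. frames: displaced coordinates
plus independent uniform noise in `[-noise_amplitude, +noise_amplitude]` on
every coordinate, followed (by default) by a uniformly random rotation of
the whole frame about the origin, mimicking the arbitrary global
orientation of unaligned trajectories.

The defaults are the benchmark's standard world: 100 atoms in a `[-1, 1]`
box, 3 states with 10 displaced atoms each, displacement 0.1, noise 0.01,
1200 frames per state. Tests and the acceptance benchmark scale the frame
count down (200 per state) to stay inside a desktop time budget; the
statistical conclusions are unchanged at that size.

Three generator details are deliberate choices where the protocol leaves
room:

* **Noise is applied to all atoms**, not only the displaced ones --
  otherwise the undisplaced atoms would be exactly constant and the
  benchmark degenerate (any variance-based method would trivially win).
* **Rotations are drawn uniformly on SO(3)** via normalized Gaussian
  quaternions.
* **Exactly zero noise is a degenerate stated world**: every state
  collapses to a single repeated configuration, all informative features
  become perfectly tied, and tree or network importance concentrates
  arbitrarily among them. The "easy regime" test therefore uses a tiny
  nonzero noise (0.005 against displacement 0.5, a 100:1 signal-to-noise
  ratio).

`true_importance()` returns the ground truth `psi`: a binary indicator over
atoms, l2-normalized so the benchmark's dot-product score is bounded by 1.

## Featurization

`cartesian_features()` flattens frames to 3N coordinates.
`inverse_distance_features()` computes reciprocal pairwise distances --
either all N(N-1)/2 pairs or the reduced triangulation set connecting atom
i to atoms i+1..i+4, which suffices to reconstruct the geometry with far
fewer features. Distance filters mirror the published real-system recipes:
`filter_contact_changing()` keeps pairs whose distance crosses a cutoff
within the data set (contacts that form and break), `filter_range()` drops
pairs that never visit a band. Filters reason on raw distances in the
coordinate units; the reciprocal transform is applied afterwards. Constant
features are dropped before model fitting (they break min-max scaling and
KL binning), and `minmax_scale()` maps every remaining feature to [0, 1],
recording the (min, max) pair for inversion.

`aggregate_importance_per_atom()` maps per-feature importance back to
atoms: each atom's score is the sum over all features whose descriptor
involves it, normalized to [0, 1]. The default normalization is min--max
rather than plain max-division: with pair features every atom shares pairs
with the displaced atoms, so the raw sums carry a uniform baseline (about a
third of the maximum in the standard toy world) that min--max subtraction
removes. Max-division (`normalize = "max"`) remains available when exact
zeros must be preserved.

## Layer-wise relevance propagation

For a trained network with output `T'` and a target mask `T` (one-hot for
classifiers, all ones for reconstruction networks), the output relevance is
initialized as `R_i = T_i * T'_i` and redistributed backward layer by
layer proportionally to each unit's contribution
`z_jk = rho(a_j, w_jk)`:

* **z+ rule** (unbounded ReLU layers): `rho = a_j * max(0, w_jk)`;
* **z^B rule** (bounded layers, e.g. a [0,1]-scaled input):
  `rho = a_j w_jk - l_j max(0, w_jk) - h_j min(0, w_jk)`.

The denominator `sum_j z_jk` is stabilized by `epsilon = 1e-9` added with
the denominator's sign; biases receive no relevance. With nonnegative
contributions the redistribution is conservative: total relevance is
preserved layer to layer up to the stabilizer, which the test suite checks
on random positive-weight networks against a loop-based hand
implementation. Per-sample relevance is the capability unique to the LRP
methods -- importance can be resolved per frame, then averaged per state or
over the whole ensemble and normalized to an upper bound of 1.

Two places need a decision the printed rules leave open: softmax outputs
seed the relevance with post-activation class probabilities (the
pre-softmax alternative differs by a monotone rescaling of the per-class
mass), and logistic layers propagate through their activations only, with
no activation-derivative factor, exactly as the rules are written.

## The six estimators

* **PCA** -- importance `R_i = sum_j |lambda_j T_ij|` over the leading
  components, eigenvalues normalized to sum 1. Component count by fixed
  `k`, cumulative variance threshold, or the eigengap rule (stop before the
  first component whose predecessor eigenvalue is >= 10x larger).
* **KL** -- per feature and state, in-state versus rest histograms on
  shared bins of width 1% of the pooled range; symmetric divergence
  `(KL(P||Q) + KL(Q||P))/2` in nats, empty bins padded with a 1e-9
  pseudocount before normalization.
* **RF** -- CART forest (Gini criterion, bootstrap, per-node random
  feature subsets, implemented in C++) scored by mean decrease impurity:
  the fraction of samples reaching a node times its impurity decrease,
  summed per splitting feature, normalized per tree and averaged. One
  forest per state in one-vs-rest mode yields state-specific rows.
* **MLP** -- ReLU classifier trained with Adam on [0,1] features; LRP from
  the true-class softmax output. z^B at the input, z+ elsewhere.
* **AE** -- symmetric encoder/decoder regressor reconstructing its input;
  LRP from the reconstructed output with an all-ones mask, since no class
  singles out an output.
* **RBM** -- Bernoulli restricted Boltzmann machine trained by stochastic
  maximum likelihood (persistent contrastive divergence); relevance seeded
  with the hidden activation probabilities and propagated with z^B. Inputs
  must lie in [0, 1]; a learning rate of 1 is flagged because it is known
  to destroy the extracted importance.

`run_repeated()` wraps any estimator in shuffled k-fold cross-validation
over independent iterations: each iteration's profile is the mean over its
folds, the final profile the renormalized mean over iterations with a
per-feature standard deviation, and classifiers record held-out accuracy.

### Training choices that matter

The neural trainers are plain-R Adam implementations (no R deep-learning
stack is assumed). Three defaults deserve explanation:

* **Minibatch size 32.** With full-batch updates a 200-epoch run is only
  200 optimizer steps -- chronically undertrained at benchmark sample
  sizes.
* **Plateau stopping on loss *or* objective.** Training stops after 10
  epochs (configurable) in which neither the data loss nor the full
  objective (loss + L2 penalty) improved by `tol`. On easy data the loss
  saturates in a few epochs while weight decay keeps shrinking irrelevant
  weights -- and it is precisely those weights that set the attribution
  noise floor of the z^B rule, which hands relevance `-h_j * min(0, w)` to
  every input regardless of activation. On hard data, growing weights
  inflate the penalty while the loss still falls; either signal alone
  stops too early.
* **Per-input-kind MLP settings in the benchmark.** The published protocol
  reports each benchmark panel at its best scanned hyperparameters. The
  defaults follow that: on many-feature inverse-distance input the MLP
  uses strong weight decay (`alpha = 1e-2`) and small batches; on
  rotation-entangled Cartesian input it needs full capacity (`alpha =
  1e-4`), clean full-batch gradients and patience 50, because the
  decision surface is genuinely nonlinear and slow to learn.

## Benchmark metrics

With both the measured profile `phi` and the truth `psi` l2-normalized:

* **find-all** `= 1 - |psi - phi| / (|psi| + |phi|)` rewards recovering
  every displaced atom and tolerates moderate noise; an all-zero profile
  scores 0.
* **ignore-irrelevant** `= phi . psi / |phi|` is 1 exactly when `phi` is
  supported inside the truth (a pure subset scores `sqrt(k/n)`), and 0
  when no mass falls on displaced atoms. It is invariant to positive
  scaling of `phi`.

Under this normalization both scores are bounded by 1, and the second is
algebraically a cosine similarity -- symmetric in its arguments even
though its *purpose* is asymmetric (it rewards subsets that find-all
penalizes). `run_benchmark()` scores every method x feature-kind x toy
instance x repeat cell against the union-of-states truth, records
individual failures without aborting, and summarizes each cell as box-plot
statistics (median, quartiles, whiskers at 1.5 IQR -- the conventional
definition, since the published captions name whiskers without defining
them). `hyperparameter_scan()` evaluates a grid of settings with a reduced
benchmark and flags the best row.

A worked example at desk scale:

```{r benchmark, eval = FALSE}
report <- run_benchmark(
  config = toy_config(n_frames_per_state = 200L, seed = 1),
  feature_kinds = c("cartesian", "inverse_distance_full"),
  n_instances = 3L, n_repeats = 3L)
report$summary
```

The qualitative picture this reproduces: on unaligned Cartesian input with
random rotations PCA drops to (or below) random guessing while the MLP
still recovers most displaced atoms; the forest ignores irrelevant atoms
better than it finds all of them; on inverse distances all supervised
methods are close to ideal, with KL and RF typically ahead of the MLP.

## What a green test establishes -- and what it does not

The toy model draws i.i.d. frames: there is no kinetics, no Boltzmann
weighting, no temporal correlation, and state populations are exactly
balanced. Success on it establishes that an estimator can attribute
state-discriminating variance to the correct coordinates under rotational
nuisance and additive noise -- not that it will resolve rare states,
overlapping basins or force-field artifacts in real trajectories. The
real-system presets (`preset_config("cam")`, `"gpcr"`, `"vsd"`) carry the
published featurization recipes -- contact-change filtering at 1.0 nm,
range filtering at (0.5, 0.7) nm, block shuffling in blocks of 100 frames,
fold and iteration counts -- but the deposited trajectories themselves are
external data and are not bundled.

## Numerical notes and limitations

* KL bins: ~1% of the pooled range per bin; features with zero range score
  zero. The pseudocount bounds any single bin's log-ratio at about
  `log(1e9 * n)`, so KL values saturate rather than diverge for disjoint
  supports.
* Profile normalization divides by the maximum (or maximum absolute value
  when no entry is positive, possible with mixed-sign relevance);
  all-zero profiles carry an `all_zero` attribute instead of NaNs.
* The forest breaks split ties by the per-node shuffled feature order, so
  exactly tied features share importance only in expectation over trees.
* Multi-model PDB is the only trajectory format read natively (plus plain
  CSV matrices); binary MD formats (XTC/DCD) require conversion upstream.
  Atom and residue indices are 0-based in memory and 1-based in every file
  written.
* Determinism: every stochastic step is seeded; rerunning any extractor,
  benchmark or CLI command with the same seed reproduces its output
  bit-for-bit.
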