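---
title: "Predicting polymer nanoparticle sizes with a cyclic-graph convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting polymer nanoparticle sizes with a cyclic-graph convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nanoprecipitation — dripping a polymer solution (here THF) into an
antisolvent (water) — produces polymer nanoparticles whose hydrodynamic
diameter controls most of what matters in drug delivery: uptake, loading,
clearance, targeting. The diameter depends jointly on the repeat-unit
chemistry, the degree of polymerization (Dp), the polymer concentration in
the stock solution, and the surfactant. Finding conditions that hit a
target size is traditionally trial and error.

`polygcn` learns this map directly from formulation screens. The only
structural input is the repeat unit as a SMILES string with two `*`
markers on the backbone attachment atoms; everything else is three
numbers (Dp, polymer concentration in g/L, surfactant concentration in
g/L with 0 meaning none).

## The model

**Polymer graphs.** A polymer is represented as a heavy-atom molecular
graph of its repeat unit replicated `ring_size` times (default 10) and
closed into a macrocycle. On this cyclic graph every repeat unit has an
identical environment, so each atom "sees" exactly what it would see in an
infinitely long chain — a far better description of a polymer than the
bare monomer, at a fraction of the cost of a full Dp-length chain. Two
conditions protect this equivalence, and both are enforced:

* no atom featurizer may encode membership of the macrocycle
  (`atom_feature_spec()` rejects ring-membership featurizers), and
* the awareness range of the convolution stack (one bond per layer) must
  not wrap around the cycle (`build_cyclic_polymer()` / the model warn via
  the ring-wrap guard when `ring_size × backbone atoms per unit ≤
  2 × layers`).

Atom features are one-hot element (C, N, O, S, P, F, Cl, Br, I, other),
heavy-atom degree (0–5), formal charge, hybridization (sp/sp2/sp3/other),
implicit hydrogen count (0–4), and an iterative
electronegativity-equalization partial charge — 27 dimensions in total.
This set is this package's own documented choice, assembled from the
featurizers molecular-graph models conventionally use; hydrogens are
implicit (counted, not instantiated), which halves the graph. All
neighbor-dependent features are computed after the final topology is
built, so atoms that gain a backbone bond lose a hydrogen, and the damped
charge iteration (six rounds, so a six-bond influence radius) preserves
the exact unit-to-unit symmetry of the cyclic graph. Atom indices are
1-based throughout, the natural convention in R.

**Convolution.** Each layer updates the node-feature matrix as

$$H_{n+1} = \sigma\!\left(\tilde D^{-1/2}\tilde A\tilde D^{-1/2}\, H_n W_n + b_n\right),$$

where $\tilde A = A + I$ adds self-loops and $\tilde D$ is its degree
matrix. The default stack is 4 layers of width 64 with rectifier
activations and dropout 0.1 on every layer output (training mode only).
The layer is implemented as one matrix expression; a per-node
message-passing oracle in the test suite verifies the two views agree to
below 1e-6 on random graphs.

**Readout.** The convolved graph is pooled into a fixed-length
fingerprint: column-wise max concatenated with a gated weighted sum (a
learned logistic gate per node scales its row before summation; a plain
sum is available via `sum_mode = "plain"` for ablation). Both halves are
permutation-invariant and independent of graph size in length.

**Fused regressor.** The fingerprint (length 128 by default) is
concatenated with the standardized numeric inputs and passed through
fully connected layers $l_{n+1} = \sigma(l_n W_{n+1} + b_{n+1})$ of widths
128–64–32 down to a linear scalar head — the predicted diameter in nm. Dp
and concentration enter as logarithms before standardization (they are
ratio-scale quantities; equal model resolution per fold change), the
surfactant level stays linear because 0 encodes absence. Standardization
statistics come from the training set and are stored in the model; the
raw network output is multiplied by the stored mean training size, which
puts the learning dynamics on a well-scaled footing without clamping the
linear head (non-positive predictions are possible in pathological cases
and trigger a warning rather than being hidden).

**Loss and training.** The loss is the mean absolute percentage error
(MAPE), $\tfrac{100}{n}\sum_i |\hat y_i - y_i|/y_i$ — the relative form
weights a 20 nm error on a 60 nm particle like a 100 nm error on a 300 nm
one. Optimization is adaptive-moment (Adam) with learning rate 1e-3,
batch size 64, default 300 epochs, dropout 0.1, best-validation-epoch
checkpointing, and an 8:2 train/validation split (validation size
`round(0.2 n)`). Gradients are exact reverse-mode derivatives of the full
forward pass, hand-written and validated against central finite
differences. Records sharing a polymer share one graph forward/backward
pass per batch (with a common dropout mask on the graph side), which is
what makes training a few thousand records practical on one CPU. All
randomness — initialization, shuffling, dropout, splits — is derived from
the configured seed; two runs with the same seed are identical.

## Evaluation protocol

`leave_one_polymer_out()` answers the question the method exists for: can
the model predict a polymer it has never seen? For each holdout (one
polymer, or a pair evaluated jointly) all of its records are removed, the
rest is 8:2 split, a model is trained from scratch, and the held-out
records form the test set. Reported are training MAPE, test MAPE, and
"all" MAPE over the validation split pooled with the held-out records.

Large test errors usually trace to one group of formulations with
peripheral parameters — the most extreme Dp, the lowest concentration, or
the surfactant-free subset. `worst_group_analysis()` makes this
decomposition explicit: records are grouped by the exact recorded value
under each key (Dp, concentration, additive), the group with the highest
MAPE across all keys is flagged (ties broken toward the larger group,
then lexicographically), and both test and pooled MAPE are reported with
and without it.

## Data cleaning

Raw screens carry three replicate formulations, each measured three
times. `preprocess_raw()` removes, with machine-readable reason codes:
rows with missing sizes (`missing_size`), polydispersity above 0.3
(`high_dispersity`), sizes outside 10–1000 nm (`size_out_of_bounds`),
measurements deviating more than 30 % from their formulation median
(`replicate_outlier`), and formulations left with fewer than 3
measurements (`insufficient_replicates`). The thresholds are stand-ins
chosen from standard DLS practice and are all configurable in
`filter_config()`. Survivors become one modeling record per measurement —
replicates are deliberately not averaged. Row conservation
(`kept + rejected = input`) holds at every stage, and decisions are
per-row or per-group statistics, so the pipeline is order-invariant.

## The synthetic generator

Because the training corpus of a real screen cannot ship with a package,
`generate_raw_table()` / `generate_clean_dataset()` emulate its
structure: ten methacrylate repeat units (methyl through benzyl and
isobornyl esters), three Dp levels (60, 120, 220), five concentrations
(1–30 g/L), surfactant at 0 or 0.0025 g/L, and the 3 × 3 replicate
structure — 2700 measurements on the default grid. Measurements follow an
invented closed-form law

$$s = a\,\mathrm{Dp}^{\alpha}\, c^{\beta}\, (k/7)^{1/2}\,
      (1 - \gamma\,[\text{surfactant}]),$$

with $a = 15$, $\alpha = 0.4$, $\beta = 1/3$, $\gamma = 0.15$ and $k$ the
heavy-atom count of the repeat unit, under multiplicative lognormal noise
($\sigma_{\log} = 0.05$, since DLS size errors scale with size). The law
is **not** nanoprecipitation physics; it is chosen monotone in Dp and
concentration (echoing the qualitative shape of measured prediction
surfaces), bounded inside the 10–1000 nm DLS window on the default grid,
and structure-dependent only through a descriptor a graph network can in
principle learn. Planted anomalies (3× outliers, high-PDI and
missing-size rows, at 2 % each) come with exact bookkeeping so cleaning
can be scored. An optional `extreme_dp` plant gives one unit an extra
peripheral Dp level (1000, against training levels up to 220) —
reproducing the situation where a held-out polymer carries a group far
outside every other polymer's range, which the worst-group decomposition
should isolate.

What passing on this battery does and does not show: it demonstrates that
the pipeline can learn a smooth, monotone structure–formulation–size law
from a few thousand noisy records and generalize it to an unseen repeat
unit whose descriptor lies inside the battery's range. It does not
demonstrate chemistry: real size laws are not power laws, real residuals
are not lognormal i.i.d., and real repeat units differ in more than a
single scalar descriptor.

## Numerical choices and edge cases

* Problem sizes: the shipped end-to-end checks train on 2000 synthetic
  records for 60 epochs (twice: one split run, one leave-one-out run) —
  sizes chosen to exercise the full pipeline at a scale a laptop CPU
  handles in minutes.
* Fingerprint convergence: the cyclic representation is compared to
  linear chains on the per-unit scale (the weighted-sum half divided by
  the number of repeat units), since the extensive sum of a growing chain
  trivially diverges from any fixed cycle. Empirically the per-unit sum
  half of the distance decays exactly like $1/n$ once the chain interior
  dominates, while the max half settles at a small constant set by the
  hydrogen-capped chain ends: end atoms see a different neighborhood,
  and whenever one of them wins a feature column the max pool keeps a
  constant offset no chain length removes. The distance is therefore
  monotonically non-increasing toward a small plateau (about 5 % of the
  cyclic norm under random weights) rather than to exactly zero; a
  readout limited to interior-dominated statistics would be needed for
  exact convergence.
* Ties in the column-wise max pool route gradients to the first maximal
  node (deterministic); ties in the worst-group analysis go to the larger
  group, then the lexicographically first label.
* Degenerate inputs: empty graphs cannot be pooled; datasets below five
  records cannot be split; holding out every polymer is refused; training
  aborts with the epoch index if the loss turns non-finite.
* Checkpoints and model bundles are flat JSON with a format-version tag,
  serialized at 17 significant digits so save/load round-trips are
  bit-exact.

## Limitations

Single solvent/antisolvent pair and a single surfactant are assumed
(fixed in the emulated screen); no solvent descriptors, no copolymers or
branched topologies, no stereochemistry, no 3D effects (bond angles,
ring strain), no uncertainty quantification. Predictions are reliable
only inside the training parameter space — the worst-group decomposition
exists precisely to make violations of this visible.
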