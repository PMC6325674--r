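---
title: "Models and methods in satox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in satox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`satox` estimates two molecule-level properties from one 1024-bit binary
fingerprint: the synthetic accessibility score (SAscore, 1 = trivially easy
to make, 10 = extremely hard) by regression, and a toxicity score
(Tox-score, 0–1) by classification. This vignette explains the two models,
their assumptions, every tunable parameter that matters, the synthetic data
generators used for testing, and the numerical and design decisions that
were genuinely open.

## Fingerprints and input conventions

All models consume the Open Babel FP2 fingerprint: a 1024-bit hash of linear
atom/bond fragments of up to seven atoms. FP2 is a deterministic,
implementation-defined realization of the classic hashed path ("Daylight
type") fingerprint; the exact Daylight hash is proprietary, so any
deterministic path hash with the same shape is acceptable, provided one
scheme is used consistently. For that reason every fingerprint matrix and
every trained model carries a scheme identifier (`openbabel-FP2-1024`), and
the prediction pipeline refuses to apply a model to fingerprints computed
under a different scheme. One consequence of FP2's fragment definition is
that single-heavy-atom molecules (water, methane) hash to an all-zero
fingerprint; the Tanimoto similarity of two all-zero fingerprints is defined
as 1 so that such degenerate duplicates are treated as redundant rather than
maximally dissimilar.

Toxicity labels are 0/1 with 1 = toxic, and the **positive class is
non-toxic** everywhere: TP counts non-toxic molecules predicted non-toxic,
FPR is the fraction of toxic molecules slipping through the filter. This
matches the screening use case — the quantity of interest is how reliably a
compound is cleared for further development.

## Dataset curation

Two standard curation steps are provided. `filter_by_weight()` keeps
molecules with Open Babel average molecular weight in [100, 600] Da — bounds
inclusive on both ends, since the conventional "100–600 Da" window does not
specify a bracket convention and the inclusive reading is the weaker
assumption. `redundancy_filter()` removes near-duplicates at a Tanimoto
coefficient cutoff of 0.8 by a greedy scan in input order: a molecule is
kept iff it is below the cutoff against every previously kept molecule. The
representative of each similarity cluster therefore depends on input order;
this makes the filter deterministic given the file, which we prefer over an
unspecified cluster-medoid rule. The output satisfies a checkable contract:
all pairwise similarities among survivors are strictly below the cutoff.

## Balancing skewed SAscore data

Reference SAscore distributions of screening collections are strongly
skewed: roughly 28.3% of molecules score in [2, 3) and scores above 7 are
rare. Training on the raw distribution starves the tails, so
`resample_sascore()` applies a bin-wise plan (`default_sa_plan()`): [1,2)
duplicated ×2, [2,5) uniformly undersampled to 90,000, [5,6) unchanged, and
[6,7), [7,8), [8,9), [9,10] duplicated ×2, ×5, ×20, ×100. Bins are half-open
on the right except the final closed bin — a convention choice, since score
ranges are usually quoted without brackets. Duplication is an exact
whole-copy (no jitter or interpolation): oversampling a bin of m records at
ratio r yields exactly r·m records, and undersampling draws without
replacement, so the arithmetic is exactly testable. The result is always
shuffled under the caller's seed (whether the original procedure shuffled is
unstated; shuffling is the safe default for mini-batch training). The
90,000 cap is a library-scale value and is exposed as a parameter for
desk-scale work.

`satox_train_sa()` resamples **before** cross-validation, mirroring the
standard workflow for this method. Duplicated records can then appear on
both sides of a fold split, which makes CV estimates of the resampled set
optimistic relative to truly unseen molecules; for unbiased assessment,
evaluate on a held-out set that never entered resampling.

## The DBN regressor

A deep belief network with layer sizes 1024–512–128–32 (visible layer =
fingerprint). Each restricted Boltzmann machine is pre-trained by
contrastive divergence with k = 1 Gibbs alternations (CD-1; k is exposed in
`dbn_control()` but 1 is the standard and default). Hidden states are
sampled binary inside the CD chain; visible reconstructions and all
stacking/forward passes use mean-field probabilities, which lowers the
variance of both the gradient estimate and the stacked representation at the
modest data sizes targeted here. Layer i is trained on the mean-field hidden
activations of layer i−1.

Fine-tuning attaches a linear head (initialized to zero) on the top hidden
layer and minimizes mean squared error plus an L2 penalty on weights (never
biases, default strength 10⁻⁴) by mini-batch gradient descent,
backpropagating through all layers. Head-only fine-tuning is available as a
config switch (`finetune_layers = FALSE`) for when the pre-trained features
should be frozen. The learning rate follows inverse-time decay
lr_t = lr₀ / (1 + decay · t) with t counting parameter updates — the named
constants (initial rate 0.01, decay 10⁻⁴) come with no stated functional
form, and inverse-time decay is the standard schedule those two constants
parameterize. The update counter restarts at each phase (each RBM layer, and
fine-tuning), so a layer's training is reproducible in isolation.

Defaults: batch 100, 20 pre-training epochs per layer, 1000 fine-tuning
epochs. Weights start at N(0, 0.01²), biases at zero. Predictions are
deterministic mean-field forward passes clamped to [1, 10]; no sampling is
ever used at prediction time, so prediction is bit-for-bit reproducible.
Each phase draws its RNG stream from a sub-seed derived from the single
model seed, which is how the test suite can retrain one layer independently
and obtain identical weights.

The mean-squared-error loss is an assumption: the regression target is a
bounded score and MSE is the risk the evaluation itself uses. Gradients are
verified against central finite differences (tolerance 10⁻⁴) at both zero
and non-zero L2.

## The extra-trees classifier

Extremely randomized trees over binary features: every tree is grown on the
**full** training sample (no bootstrap), and at each node k candidate
features are drawn uniformly without replacement (default
k = ⌊log₂ 1024⌋ = 10). For a binary feature the only possible cut is the 0/1
split, so the usual random cut-point degenerates to the feature choice; the
candidate with the largest Gini impurity decrease wins, with ties broken by
the lowest feature index so that forests are deterministic given the seed.
Splitting stops when a node is pure (Gini at or below a configurable
threshold, default 0), at depth 70, when fewer than 19 samples remain to
split, or when a child would receive fewer than 3 samples. The stated
"minimum numbers of 3 and 19 samples to create and split a leaf node" is
read as min_samples_leaf = 3 and min_samples_split = 19; the inverse reading
would make every leaf larger than the split threshold and is rejected.

Leaves store the *fraction* of toxic training molecules rather than a hard
vote, so the ensemble score — the mean leaf fraction over 500 trees — is a
smooth probability. The classic majority vote is a special case: with trees
grown to purity every leaf fraction is 0 or 1, and thresholding the mean at
0.5 with an odd tree count reproduces the mode of the per-tree votes (this
equivalence is a test). A single-class training set yields a warning and a
constant model rather than an error, so batch pipelines degrade gracefully.

The ensemble is hand-built rather than delegated: no installed R ensemble
exposes the exact semantics required here (full-sample growth, per-node
random feature draw on binary splits, leaf class fractions, deterministic
tie-break), and the implementation is ~100 lines whose behaviour the toy
oracles pin down.

Classification direction: non-toxic iff Tox-score ≤ threshold, boundary
inclusive; the default 0.58 is the customary MCC-optimal operating point for
drug-vs-hazard screening, and `satox_train_tox()` re-selects the threshold
on pooled out-of-fold scores (selection on pooled predictions rather than
per-fold is a choice; it uses every instance exactly once and yields a
single operating point).

## Evaluation machinery

ACC, TPR and FPR are the usual confusion-matrix ratios under the
positive = non-toxic convention; a zero denominator returns `NA` with a
message rather than an error, so sweep code keeps running. MCC returns 0
when any marginal sum is zero (the common convention; the measure is
otherwise undefined there). The ROC curve sweeps the decision rule over all
distinct score values, grouping tied scores at one threshold, and integrates
by trapezoid — under that tie convention the area equals the Mann–Whitney
concordance statistic with ties counted ½, which the tests verify to 10⁻⁹.
Threshold selection evaluates the MCC on a fixed grid (step 0.01, matching
the two-decimal resolution at which thresholds are reported) and returns the
smallest maximizing threshold. Cross-validation is stratified for binary
labels (fold class ratios within one instance) and unstratified for
regression; folds partition the data with sizes differing by at most one.
Grid search ranks by mean MCC (computed at the fixed threshold 0.5, a
calibration-free comparison), breaking ties by mean AUC and then grid order.

## Fragment-composition comparison

`fragment_compare()` contrasts the fragment vocabularies of a non-toxic and
a toxic molecule set. A fragment's frequency is its share of *total fragment
occurrences* in the set (so a ubiquitous scaffold like benzene gets a large
frequency); the alternative denominator — the fraction of molecules
containing the fragment — answers a different question and was not adopted
because the occurrence share is what a composition scatter plot of two
fragment sets displays. The two tables are aligned on the union of keys
(absent = 0) and summarized by the Pearson correlation.

The enrichment line is a **major-axis** (first principal component) fit
rather than an ordinary regression of toxic on non-toxic frequency. Neither
set is a predictor of the other, and the major axis is the symmetric
least-squares line: swapping the two sets reflects the fit and exactly
negates every signed perpendicular residual, so "enriched in set A" and
"enriched in set B" are guaranteed to be mirror statements. An ordinary y-on-x
regression cannot satisfy that symmetry. Fragments are ranked by the signed
perpendicular residual: positive = above the line = relatively enriched in
the toxic set.

## Synthetic data generators

The package is developed and tested entirely against two generators, both
pure functions of their configuration (seed included).

`gen_tox_data()` emulates a separable toxicity problem: a configurable
number of informative bits equal the class label and are flipped with
probability `flip_noise`; all other bits are Bernoulli background. Defaults
(8 informative bits, background 0.1, flip noise 0.2) produce a moderately
hard problem on which a good classifier reaches an AUC near — not at — 1,
qualitatively matching real drug/hazard discrimination. Flip noise 0.5
destroys the signal entirely, giving a clean null.

`gen_sascore_data()` draws a unit score bin from weights mimicking the
skewed SAscore distribution (28.3% mass in [2,3), bulk below 5, thin high
tail), a score uniformly inside the bin, and encodes it in the *set-bit
count* via the invertible affine map n_set = n_bits/8 + (n_bits/16)·score;
bit positions are uniform. The recorded label is the score implied by the
realized (rounded) bit count plus Gaussian noise, so at zero noise the label
is exactly recoverable — a property the tests exploit. The quantization step
is 16/n_bits score units; tests that check distributional mass use
n_bits ≥ 256 so quantization leakage at bin edges stays well inside the
tolerance.

What the generators do *not* emulate: real fingerprints are sparse,
correlated, and carry signal in bit *combinations* rather than counts or
single bits; real SAscore labels are deterministic functions of structure,
not noisy affine codes; real toxic/non-toxic sets overlap chemically in ways
a flip-noise model does not capture. Passing the recovery tests therefore
demonstrates that the training machinery optimizes what it claims to
optimize — not that the models reach any particular accuracy on real
compound collections, which depends on data the package deliberately does
not ship.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite finishes in well under a minute of model training: extra-trees
recovery uses 400 molecules × 64 bits × 100 trees over 5 seeds × 4 noise
levels; DBN recovery uses 2000 molecules × 256 bits with layers
[256, 64, 16], 5 pre-training and 100 fine-tuning epochs (held-out PCC ≥ 0.8
and MSE ≤ 1.0 under label noise of sd 0.5, whose irreducible MSE is 0.25).
These sizes are stated here as the package's reference experiment, and the
same computation is what `scripts/acceptance.R` re-runs under a caller
seed.

Other numerics: sigmoids are evaluated directly (R's `exp` saturates
gracefully); predictions are clamped, never resampled; all stochastic code
runs under an explicitly specified RNG (Mersenne–Twister, inversion normals,
rejection sampling) so results are identical across platforms and R
versions; sub-seeds for independent streams are derived from the single user
seed by a fixed affine map. Models are serialized with a format-version tag
and the fingerprint scheme id, and loading refuses mismatches of either.

## Limitations

Reference SAscore labels must be supplied (computed externally by the
standard fragment-contribution method); the package consumes, never
produces, them. Fragment lists for the composition analysis likewise come
from an external decomposition tool. Training the full 1024–512–128–32
network on library-scale data (10⁵–10⁶ molecules) is feasible but slow in
pure R; the implementation targets method fidelity and desk-scale
reproducibility, not GPU-era throughput. No salt stripping, tautomer
normalization or 3D handling is performed.
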