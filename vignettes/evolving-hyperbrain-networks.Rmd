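---
title: "Evolving hyperbrain networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving hyperbrain networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state fMRI yields one BOLD time series per brain region (e.g., 90
AAL parcels). Classical functional-connectivity networks record pairwise
correlations between regions, but a region's activity is typically driven
jointly by several other regions; pairwise edges cannot express such
higher-order interactions. A *hyperbrain network* represents them
directly: each region generates one hyperedge containing the set of
regions that jointly predict its signal. Because functional coupling
changes over the scan, the series is segmented into windows and one
hypergraph snapshot is built per window — a *dynamic* hyperbrain network.
Subjects (e.g., Alzheimer's disease vs. controls) are then classified
from these snapshot sequences with hypergraph neural networks that
aggregate information across adjacent snapshots.

This package implements the full pipeline: sparse-representation
construction of the dynamic hyperbrain network, two evolving hypergraph
network variants (convolution and attention), a training and
cross-validation harness, and a synthetic cohort generator that makes
every stage testable without clinical data.

## Constructing the dynamic hyperbrain network

Within a window, let `Z` be the M x w matrix of windowed signals. For
each region m, the package solves the l1-penalized regression

    min_a (1/(2w)) || z_m - A_m a ||_2^2 + lambda * || a ||_1

where `A_m` is `Z` transposed with column m zeroed, so a region never
selects itself. The solver is least-angle regression with the lasso
modification (`lars_lasso()`), which traces the entire piecewise-linear
coefficient path; the solution at any penalty follows by exact linear
interpolation between path knots. The test suite cross-checks the solver
against an independent coordinate-descent lasso on randomized instances
(agreement well below 1e-4).

**Penalty convention.** The objective divides the squared error by `2w`,
the scaling used by coordinate-descent lasso implementations, so `lambda`
is comparable across window lengths and, with per-window z-scoring of
each region (on by default for the regression), across subjects.
`lambda` values quoted anywhere in this package are in this convention;
published accuracy-versus-sparsity sweeps that leave their normalization
unstated cannot be mapped onto it exactly.

**Incidence assembly.** Hyperedge m contains every region whose
coefficient magnitude exceeds `tau` (default 1e-6), plus region m itself
(the *centroid*; configurable off). The centroid convention keeps each
node attached to its own hyperedge even when the fit is empty, so no node
is structurally isolated by an all-zero solution. Hyperedge weights are 1
by default, or the mean absolute member coefficient
(`weight_mode = "mean_abs_coef"`), which down-weights hyperedges built
from weak, noise-dominated fits.

A numerical point worth knowing: at any `lambda > 0` the lasso
occasionally carries active coefficients of size O(0.1 * lambda) that
vanish only as `lambda -> 0`. Exact support identification should
therefore either use a very small penalty (`lambda ~ 1e-6` on noiseless
data) or a threshold `tau` scaled to the penalty (we use
`tau = lambda / 2` in recovery experiments); `tau = 1e-6` at moderate
`lambda` will report those O(0.1 * lambda) members as well.

**Windows.** The default segmentation partitions the series into
`n_snapshots` equal, consecutive, non-overlapping windows (trailing
points dropped); a `step` smaller than the window length yields
overlapping windows. Bounds are 0-based and half-open internally.

**Node features.** Each snapshot's node features default to the window's
signal rows (F = window length). The regression design is z-scored per
window when `standardize = TRUE`; the features keep the scale of the
input series, because amplitude is itself informative for brain signals.

## The evolving network layers

One hypergraph snapshot defines a node-to-node propagation operator. The
literal form is `H W H^T` (`normalization = "raw"`): node i
receives the features of every node j sharing a hyperedge with it,
weighted by the hyperedge weights. The default is the symmetric
degree-normalized operator `Dv^-1/2 H W De^-1 H^T Dv^-1/2` standard in
hypergraph convolutional networks; it keeps feature magnitudes stable
across layers. Degree-zero nodes and empty hyperedges contribute zero
rows rather than dividing by zero.

**Evolving convolution.** The updated feature of node i at snapshot t
aggregates the propagated features of snapshots t-1, t and t+1 (boundary
snapshots drop absent neighbours), multiplied by the layer's weight
matrix, plus a bias, through an ELU. A literal all-snapshot sum is
retained as `temporal_mode = "all"`. With s = 1 either mode *is* the
static hypergraph convolution, which is how the static baselines are
obtained.

**Evolving attention.** The aggregation-side incidence entries are
replaced by attention scores: for node j at snapshot t, the raw score of
each incident hyperedge is `LeakyReLU(a' [x_j P ; x_e P])` (slope 0.2),
with the effective attention vector `a'` constrained to [0, 1] by an
element-wise sigmoid of an unconstrained parameter. Scores are
softmax-normalized *jointly* over the hyperedges incident to j in
snapshots t-1, t and t+1, so attention mass is conserved across the
temporal window. The masking side of the propagation product stays
binary, so attention never invents structure. The hyperedge feature is
the centroid node's feature by default (each hyperedge is generated by
one region) or the member mean. Interpretation choices the source
formulation leaves open — whether neighbouring-snapshot scores use their
own snapshot's features (they do here) and whether attention replaces one
or both sides of the incidence product (one side here) — are fixed as
stated and exercised by the tests.

During training, dropout (default rate 0.6 for the attention variant) is
applied to the layer inputs and to the attention transition matrix;
the convolution variant trains without dropout by default. Raw attention
scores are clipped at |50| before exponentiation as an overflow guard;
softmax denominators of isolated nodes are zero and yield all-zero score
rows rather than NaNs.

**Readout and head.** Final-layer features (ELU-activated, like every
layer) are pooled by a mean (default) or sum over nodes and snapshots
into one vector per subject, and a softmax gives class probabilities.
Training minimizes cross-entropy with Adam (learning rate 0.005), L2
regularization added to gradients at 3e-4, for 200 full-batch epochs by
default; all parameters (two propagation matrices, their biases, and the
attention vectors) are learned. A fixed seed makes initialization,
dropout masks and fold assignment reproducible bit-for-bit.

Internally, training runs on a batched representation: subjects are
stacked into block-diagonal sparse incidence and propagation operators
(`Matrix`), so an epoch costs a handful of sparse-dense products
regardless of cohort size. The public per-subject layer functions
(`evolving_hyperconv()`, `attention_scores()`, `evolving_hyperatten()`)
are the reference implementation; the test suite proves the batched
engine equal to their composition and checks all analytic gradients
against finite differences.

## The synthetic cohort generator

`generate_cohort()` inverts the construction model into a generator.
Regions split into *root* regions, whose signals are i.i.d. standard
Gaussian series, and *driven* regions (default `max(n_varying, M/4)`),
whose signal in each window is a planted linear combination of
`support_size` roots (coefficient magnitudes uniform in `coeff_range`,
random signs) plus Gaussian noise of sd `noise_sd`. The planted supports
are the ground-truth hyperedges. Generating on this root/driven DAG keeps
the sparse-regression problem well posed; supports are drawn so that two
hyperedges of one class share at most one root, which makes the planted
coefficients the minimum-l1 solution in the noiseless case and hence
makes exact recovery a meaningful oracle.

Class structure: all subjects of a class share the class's support sets.
Relative to class 1, `n_varying` hyperedges differ in the other classes —
they are remapped to different roots *and reduced to
`support_size_varying` members* (default `support_size - 2`), emulating
the loss of inter-regional driving connections that characterizes
neurodegeneration. With `temporal_shift`, those hyperedges are re-drawn
in every window for the disease class while class 1 stays stationary —
unstable connectivity on top of weakened connectivity. The earliest
version of the generator varied membership identity only (same support
sizes); a permutation-invariant readout provably cannot see which
*particular* regions form a hyperedge, only distributional properties, so
identity-only class differences are undetectable by design and the
connection-loss effect was made part of the class contrast.

What the generator does **not** emulate: haemodynamic autocorrelation
(signals are white within windows), scanner drift and motion artifacts,
inter-subject anatomical variability, and baseline offsets (signals are
zero-mean, so classes differ in second-order structure only). Passing
tests on these cohorts show the pipeline recovers planted structure and
class differences of the stated kind; they do not certify clinical
performance.

## What the benchmark can and cannot show

The end-to-end benchmark cohort (2 x 50 subjects, M = 20, d = 150,
s = 5, `n_varying = 6`, `temporal_shift`, `noise_sd = 0.2`, seed 42;
construction at `lambda = 0.3` with mean-|coefficient| hyperedge
weights) carries its class signal purely in network structure and signal
amplitude — subject-level statistics such as incidence density separate
the classes completely (several standard deviations of gap). Reading such
second-order signals through a two-layer network with a mean readout is,
however, statistically inefficient: each hidden unit sees one linear
projection of each node's window, so the readout estimates amplitude
differences at an effective sample size of (nodes x snapshots x hidden
units), and gradient training under the published optimizer settings
(Adam, learning rate 0.005, a few hundred epochs) additionally struggles
with the large common-mode component of structure-derived channels. On
cohorts of this kind the convolution variant cross-validates clearly
above the permuted-label control but well below the headline accuracies
reported for large clinical datasets, whose class differences are
carried by far richer per-node signal features; the attention variant's
heavy dropout (rate 0.6) shifts the variance-sensitive readout between
training and evaluation and keeps it near chance on purely
covariance-coded classes. The acceptance script reports exactly what the
pipeline achieves; the permuted-label control verifies that no leakage
inflates it.

## Numerical choices

- LARS path: correlation ties resolved at relative tolerance 1e-9; the
  path stops at rank deficiency of the active Gram matrix, at
  `lambda_min`, or when the active set reaches min(n, p); dropped
  variables are barred from immediate re-entry (lasso modification).
- All-zero regression targets short-circuit to the zero solution.
- Constant rows z-score to zero rather than NaN.
- Attention softmax: per-(node, window) groups; empty groups give zero
  rows; raw scores clipped at |50| (gradient zero beyond the clip).
- Glorot-uniform initialization for propagation matrices, zero biases,
  uniform(-0.1, 0.1) for unconstrained attention vectors.
- Stratified folds: per-class seeded shuffle dealt round-robin, so fold
  sizes and class proportions are balanced wherever divisible.

## Problem sizes used by the test and acceptance suites

Unit tests run on 6–15 region cohorts with 2–4 windows. Solver oracles
use 100 random instances with at most 15 predictors. Support-recovery
checks use M = 20 with 60-point windows (10 subjects noiseless, 10
noisy). The end-to-end benchmark uses the 100-subject cohort above with
10-fold cross-validation at 200 epochs; the static (s = 1) and
hidden-width comparisons reuse the same cohort. These sizes keep the full
suite re-runnable on a single CPU while leaving every quantity
recomputed from scratch at run time.

## Known limitations

- The mapping between this package's `lambda` convention and
  unnormalized formulations is data-dependent; sweep results should be
  compared within one convention only.
- Attention uses a single head; hyperedge weights are fixed inputs, not
  learned.
- The CLI covers simulate / build / train / crossval / sweep; NIfTI
  ingestion and parcellation are out of scope (inputs are already
  extracted ROI series).
- Classification performance on purely structure-coded synthetic classes
  is bounded by the readout's statistical efficiency discussed above;
  richer node features (e.g., connectivity profiles) would lift it but
  are deliberately out of scope here.
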