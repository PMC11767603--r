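---
title: "Multi-scale convolutional local–global fusion for DTI prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale convolutional local–global fusion for DTI prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mcfdti)
```

## The problem and the model

Predicting whether a small molecule binds a protein target from raw
sequence representations alone is a binary classification problem with two
very different inputs: a SMILES string, whose informative patterns
(functional groups, ring systems) are short and local, and a protein
sequence, whose binding behaviour depends both on local motifs and on
long-range context.  The architecture implemented here encodes each side
according to that structure:

* the **drug** passes through two parallel multi-scale convolution
  branches (three Conv/ReLU layers each, kernel sizes 4/6/8, channels
  32/64/96), whose outputs are concatenated channel-wise;
* the **target** passes through two parallel paths — a convolutional path
  with kernels 4/8/12 capturing local features *L*, and a transformer
  encoder over byte-pair-encoded subwords capturing global features *G* —
  which are aligned to a common shape and concatenated.

The two streams are then crossed by a shared attention mechanism (one
query/key/value projection triple used in both directions, with residual
connections), combined position-wise by a biased feature interaction
module (BFIM), gated by a selective fusion module (SFM) whose per-channel
softmax pair makes the local and global gates compete (they always sum to
one), recalibrated by a squeeze-and-excitation (SE) bottleneck, and
classified by a fully connected sigmoid head reading the max-pooled drug
and selected features.

## Preprocessing

SMILES are tokenized **per character**; two-letter element symbols such as
"Cl" deliberately become two tokens, keeping the tokenizer trivial and
deterministic.  The character vocabulary is built from the training
corpus, sorted (C locale) with the unknown token `?` fixed at index 0.
The `?` token triples as unknown marker, padding symbol and replacement
for invalid characters; a binary mask, not the token value, tells the
model which positions are real.  Sequences are padded or truncated to
fixed lengths (defaults: 100 SMILES characters, 1000 protein characters,
545 protein subwords — all configurable).

Protein symbols outside the 20 standard amino-acid letters are replaced by
`?` before tokenization.  For the transformer path the cleaned sequences
are re-segmented by byte-pair encoding trained on the training-fold
proteins (default 1000 merges; the compact preset uses 50).  BPE treats
its corpus symbols literally and breaks frequency ties lexicographically
on the (left, right) pair, so the merge list is a pure function of the
corpus.  Because vocabulary and BPE are rebuilt inside `mcf_dti()` from
whatever records it receives, cross-validation folds can never leak
held-out sequences into the tokenizer.  Whether the original experiment
used a corpus-trained or pretrained subword table is not stated anywhere
we could find; corpus-trained is the implemented choice and is flagged in
the configuration.

## Decisions where the architecture description is open

Several blocks are named but not specified internally; the package makes
explicit, testable choices and keeps each one configurable:

* **BFIM internals.**  The default is the simplest bias-bearing
  interaction consistent with the name: position-wise
  `ReLU(W [A_d ; A_t ; A_d ⊙ A_t] + b)`, concatenating both streams and
  their element-wise product.  A bilinear variant
  (`bfim_variant = "bilinear"`) multiplies two learned projections
  instead.
* **SFM placement.**  The module is described both as acting on the
  target's (local, global) pair and as acting on the crossed features.
  These are reconciled by applying one SFM once, to the two channel
  halves of the crossed map (the drug-conditioned and target-conditioned
  streams); `sfm_on_target_LG = TRUE` instead applies it to (L, G) before
  interaction.  Either way the computation is the same: time-mean squeeze,
  `ReLU(W_f ·)` reduction with `d_r = max(2C_f/r, 4)`, expansion through
  `W_u1`/`W_u2`, and a per-channel two-way softmax whose gates multiply
  the original streams.
* **Softmax axis.**  The competition softmax runs across the two branches
  per channel (the selective-kernel reading), then broadcasts over time;
  the multiplication by X is element-wise gating, not a matrix product.
* **"Shared-weight" drug branches.**  Only one kernel triple is printed
  for six distinct convolutions.  The default uses independently
  initialized branches with the same kernel sizes;
  `share_drug_branch_weights = TRUE` ties the corresponding layers.
* **Stream alignment.**  Conv and transformer outputs live on different
  time axes and widths; both are linearly projected to `proj_channels`
  (C_f, default 96) and adaptively mean-pooled to `pool_bins` (T_f,
  default 64) bins before any fusion.  Pooling uses the standard
  floor/ceiling bin boundaries, so it is exact for divisible lengths.
* **Unstated trainer details.**  Loss is binary cross-entropy on a sigmoid
  output; the optimizer is Adam at the stated learning rate; the
  classification threshold for accuracy/precision/recall is 0.5; headline
  cross-validation metrics are fold means, with
  `pooled_metrics = TRUE` switching to pooled out-of-fold computation.
  Early stopping exists but is off by default, matching the fixed-epoch
  protocol.
* **Transformer geometry.**  d_model 128, 8 heads, 2 post-norm layers,
  feed-forward width 256, sinusoidal positional encoding — all unstated
  in the source description and all configurable.  Padded subword
  positions are masked out of the attention keys, so token values at
  masked positions provably never influence unmasked outputs (this is a
  property test).

## Numerical choices

All layers and gradients are written out in base R (BLAS matrix products),
with the convolution inner loop — row-shifted GEMM accumulation — in a
small RcppArmadillo kernel.  The backward pass is verified against central
finite differences through the entire network for every architecture
variant.  One subtlety: with zero-initialized biases, some pre-ReLU
activations start *exactly* at the kink, where the analytic subgradient
(zero) and a two-sided finite difference legitimately disagree; the
gradient tests therefore jitter parameters slightly off that
measure-zero set.  Attention uses max-stabilized softmax; masked keys
receive a −∞ logit and an all-masked sequence is an error rather than a
NaN.  The binary cross-entropy is computed on logits in its softplus form,
so extreme scores cannot overflow.  Training aborts with a diagnostic if
the loss ever becomes non-finite.

A single user seed fans out to named sub-streams (initialization,
shuffling, dropout, sampling, folds), each below 2³¹, so every stochastic
component is independently reproducible and two runs with the same
configuration agree bit for bit.

## The synthetic benchmark: what it emulates and what it does not

`synthetic_spec()` generates Davis-format fixtures (keyed ligand/protein
collections plus a dense Kd matrix) and labelled pair files with a
**conjunctive planted rule**: a pair truly interacts iff the drug contains
a fixed 4-character motif *and* the target contains another.  The rule is
chosen because it requires exactly what the architecture claims to
provide — local motif detection on both sides plus a cross-stream
conjunction — and because its ground truth is recoverable by literal
substring search, so labels are exact.  Kd values are drawn log-uniformly
within class ranges on either side of the 30 nM threshold, mimicking the
scale behaviour of affinity data, and the fixture therefore round-trips
through the loader and binarizer to the planted labels.

Defaults: 80 drugs × 60 targets, motif plant probability 0.7 per entity
(≈0.49 positive prevalence, so balancing is nearly a no-op), SMILES of
20–48 characters over a 16-symbol chemistry alphabet, proteins of 60–160
amino acids, and zero label noise unless requested.  The sequence lengths
keep the motif a small fraction of each sequence — the same local-in-global
structure as real data — while staying compact; they are spec fields, not
constants.  A character 3-gram logistic baseline ships as a test utility
and must reach AUC > 0.9 on noiseless fixtures before any conclusion is
drawn about the network, certifying that the signal exists independently
of the architecture.

What passing these tests shows: the implementation can extract planted
local motifs, combine them across streams, and generalize to unseen
drug–target combinations under a known rule.  What it does not show:
performance on real binding data, where labels are noisy thresholdings of
assay measurements, motifs are degenerate and structural, and negatives
are unverified non-measurements.  The full-benchmark script
(`inst/scripts/reproduce_davis.R`) exists for that question; its headline
metrics depend on a long stochastic training run and are not asserted by
the test suite.

## Problem sizes used by the tests and the acceptance script

The end-to-end learnability experiment trains the compact preset
(`small_model_config()`: 32-dimensional embeddings, one transformer layer,
kernel triples unchanged, SMILES length 48, protein length 160, 64
subwords) on 1,500 of 2,000 noiseless pairs for 30 epochs and evaluates
the held-out quarter; this is the package's own choice of a benchmark
small enough to rerun routinely yet large enough that memorization cannot
explain held-out AUC ≥ 0.95.  Null calibration permutes labels on 500
pairs and checks that 2-fold cross-validated AUC stays near 0.5 — the
harness finds nothing when there is nothing.  Unit and property tests use
a deliberately tiny architecture (embedding width 4, three-bin pooling) so
finite-difference gradient checks and invariant sweeps run in
milliseconds.

## Known limitations

* Character-level SMILES tokenization is chemistry-blind: "Cl" is two
  tokens, aromaticity and stereochemistry are untyped characters, and no
  canonicalization or validity checking is attempted.
* The transformer applies no dropout inside its blocks (dropout lives in
  the head only); with the small default depths this has not been a
  regularization problem on the benchmark, but very deep configurations
  may want it.
* Training is CPU-only and single-threaded beyond BLAS; the full-scale
  protocol (500 epochs on a balanced Davis subset) is feasible but slow,
  and is left to the optional reproduction script.
* `balance_by_downsampling()` treats unmeasured or weakly bound pairs as
  negatives, a standard but acknowledged source of false negatives.
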