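# mcfdti

Drug–target interaction (DTI) prediction from raw sequences: a binary
classifier that reads a drug as a SMILES string and a target as an
amino-acid sequence and returns the probability that the pair interacts.
It is aimed at computational chemists and bioinformaticians who screen
compound–kinase pairs against Davis-style binding-affinity benchmarks, and
at method developers who need a fully seeded, dependency-light reference
implementation of a multi-scale CNN + transformer fusion architecture with
every layer and gradient written out explicitly.

## The model

For a drug with character-tokenized SMILES `X_drug` and a target protein
`X_target` (character tokens for the convolutional path, byte-pair-encoded
subwords with a validity mask for the transformer path):

* **Drug encoder** — two parallel multi-scale convolution branches over the
  embedded SMILES,

      F_drug,1 = Conv3(ReLU(Conv2(ReLU(Conv1(X_drug)))))
      F_drug,2 = Conv6(ReLU(Conv5(ReLU(Conv4(X_drug)))))
      F_drug   = Concat(F_drug,1, F_drug,2)

  with output channels (32, 64, 96) and kernel sizes (4, 6, 8) per branch.
* **Target encoder** — a parallel pair of paths: a convolutional path
  (kernels (4, 8, 12)) producing local features `L`, and a transformer
  encoder over BPE subwords — scaled dot-product attention
  `softmax(QKᵀ/√d_k)V` with padded positions masked out of the keys —
  producing global features `G`; both are projected to a common channel
  width and adaptively pooled to a common length, then concatenated.
* **Fusion head** — a shared cross-attention (one Q/K/V projection triple
  serving both directions) crosses the streams; a biased feature
  interaction module (BFIM) combines them position-wise; a selective
  fusion module (SFM) squeezes the result over time, expands it through two
  maps `W_u1`, `W_u2`, and applies a per-channel softmax pair so the two
  stream gates sum to one (`X_f = Softmax(Z) × X`), followed by
  squeeze-and-excitation recalibration; a fully connected sigmoid head
  emits `y = FCN(Concat(F_drug, F_select))`.

Training uses binary cross-entropy with Adam (learning rate 0.001, batch
size 64, 500 epochs, 5-fold stratified cross-validation by default).
Davis-style affinity matrices are binarized at the strict threshold
**Kd < 30 nM ⇒ interacting**, and negatives are downsampled to balance
the classes.  Ablation variants of the architecture (single-branch drug
encoder, conv-only or transformer-only target encoder, plain concatenation
instead of the fusion head) are available through
`train_config(architecture_variant = ...)`.

All layers — embeddings, 1-D convolutions, multi-head attention, layer
norm, the fusion modules and Adam — are implemented in base R with a small
RcppArmadillo kernel for the convolution inner loop, and verified against
finite differences and independent oracles in the test suite.

## Worked example

The synthetic generator plants a conjunctive motif rule — a pair interacts
iff the drug contains one motif and the target another — which exercises
exactly the local/global feature claim of the architecture:

```r
library(mcfdti)

spec <- synthetic_spec(n_drugs = 120, n_targets = 100, seed = 2024)
recs <- generate_pairs(spec, 2000)$records
fold <- stratified_kfold(recs$label, 4, seed = 2024)
fit  <- mcf_dti(recs[fold != 1, ], small_model_config(),
                train_config(epochs = 30, seed = 2024))
print(fit)
#> Drug-target interaction model (mcf_dti)
#>   trained on 1500 pairs for 30 epochs; final loss 0.0000
#>   SMILES vocabulary: 17 tokens; BPE: 50 merges

scores <- predict(fit, recs[fold == 1, ])
auc_score(recs$label[fold == 1], scores)
#> [1] 1
aupr_score(recs$label[fold == 1], scores)
#> [1] 1
```

The final training loss near zero and held-out AUC/AUPR of 1.0 say the
network has recovered the planted rule exactly: every held-out interacting
pair is ranked above every non-interacting one.  On real affinity data the
signal is, of course, far noisier; `inst/scripts/reproduce_davis.R` runs
the full benchmark protocol (loading, 30 nM binarization, balancing,
5-fold cross-validation) for users who download the public Davis
distribution.

A command-line front-end over the same functions lives at
`inst/cli/mcfdti.R`:

```sh
Rscript inst/cli/mcfdti.R make-synthetic --seed 7 --out-dir fx
Rscript inst/cli/mcfdti.R evaluate pairs=fx/pairs.tsv epochs=30 small=true --seed 7
```

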