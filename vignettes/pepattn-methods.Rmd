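---
title: "Classifying anticancer peptides with attention-enhanced parallel CNN-LSTM networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying anticancer peptides with attention-enhanced parallel CNN-LSTM networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepattn)
```

## The problem and the model

Anticancer peptides (ACPs) are short (about 5–50 residue) peptides that
lyse tumour cell membranes, most often via amphipathic helical structures
(barrel-stave and toroidal-pore mechanisms). Two observations motivate the
feature design here: ACP and non-ACP sequences differ systematically in
residue composition (ACPs are relatively enriched in C, F, G, H, I, N, S
and Y; non-ACPs in E, L, M, Q, R and W), and their activity is tied to
secondary structure, so per-residue helix/strand/coil probabilities from
an external predictor carry real class signal.

`pepattn` therefore represents each peptide as two planes — an `L × 20`
one-hot sequence matrix and an optional `L × 3` structure-probability
matrix — and extracts features along three parallel routes:

* **Multi-head self-attention** on the one-hot plane. Queries, keys and
  values are all the sequence itself; per head, scores are scaled dot
  products divided by `sqrt(d_w)`, softmax-normalised into row-stochastic
  weights, and applied to the values. Head outputs are concatenated and
  mixed by a `d_w × d_w` output matrix, giving an enhanced representation
  `S'` of the same shape as the input. There is no positional encoding:
  the operator is permutation-equivariant over valid positions, which the
  test suite asserts explicitly. With one-hot input, attention amounts to
  a learned, context-dependent re-weighting of residue identities — the
  exported weight tables make the per-residue importance inspectable.
* **Single-layer 2-D convolutions** (300 kernels 5×5 on sequence, 150
  kernels 3×3 on structure), treating each plane as one single-channel
  image, 'valid' padding on both axes, ReLU, and **no pooling**: peptides
  are short, so whole activation maps are flattened and kept.
* **Peephole LSTMs** (45 and 20 units) scanning the rows of the two
  planes; the input and forget gates see the previous cell state and the
  output gate the updated one, as elementwise (diagonal) peephole
  weights. `peephole = FALSE` freezes these vectors at zero, recovering
  the common library cell.

In the default *skip* fusion, the flattened attention output joins the
four branch outputs directly at the classification head — concatenation,
dense ReLU layer (64 units), dropout 0.45, one sigmoid unit. In *cascade*
fusion the attention output instead replaces the raw one-hot input of the
sequence CNN/LSTM branches. Attention is always computed on the sequence
representation only, never on the structure plane.

Training minimises mean binary cross-entropy
`-((1-t)·log(1-p) + t·log(p))` (predictions clipped at `1e-7`) with Adam
(lr 1e-3, betas 0.9/0.999) over shuffled minibatches, optional
head-disagreement regularisation (mean pairwise cosine similarity of head
outputs, weight 0 by default — with the default two heads it is not
needed), and early stopping on the loss of a 10% stratified validation
split with patience 10, restoring the best weights.

## Numerical and design choices

Several points were genuinely open and are fixed here as package
conventions:

* **Alphabet order** is alphabetical (`ACDEFGHIKLMNPQRSTVWY`). Any fixed
  order is equivalent up to a column permutation, but it must be frozen
  for checkpoints to be portable.
* **Padding** is post-padding with an explicit mask. Attention gives
  masked keys an additive `-Inf` surrogate before the softmax (their
  weight is exactly zero) and zeroes masked query rows; the LSTM skips
  masked timesteps, carrying its state; the CNN needs no mask because
  padded rows are zero and the convolution layers carry **no bias term**
  — a window lying wholly in the padding therefore outputs exactly
  `ReLU(0) = 0`. This is what makes the mask-safety contract ("padding
  never changes a prediction") hold exactly rather than approximately.
* **Attention scaling** uses the full model width `d_w = 20` (the word
  vector dimension), not the per-head width; the head-count default is 2.
  The output matrix is applied per row of the concatenated heads, the
  only shape-consistent reading that returns an `n × d_w` result.
* **Structure state order** is fixed internally as (helix, strand, coil),
  and profiles are clipped to `[0, 1]` and renormalised per residue on
  load. Predictor output conventions for the three-state labels vary;
  the TSV header (`p_helix`, `p_strand`, `p_coil`) makes the convention
  explicit rather than relying on one-letter state codes.
* **Sequences longer than the configured maximum are rejected, never
  truncated**; the automatic maximum is the dataset's longest sequence,
  capped at 50 residues (the upper end of the ACP length range).
  Non-standard residues (B, J, O, U, X, Z) are an error by default; a
  lenient mode maps them to an all-zero one-hot row.
* **Zero-denominator metrics** (e.g. precision with no predicted
  positives, or a degenerate MCC denominator) return 0 and are flagged in
  the `degenerate` field rather than erroring; MCC is clamped to
  `[-1, 1]` against floating-point rounding.
* The **classification threshold** is 0.5 with ties predicted positive;
  the headline AUC of a cross-validation is computed on the pooled
  held-out scores, with per-fold AUCs also reported; fold averages are
  unweighted arithmetic means.
* **Initialisation** is Glorot-uniform everywhere, seeded; the forget
  gate bias starts at 1 so memory is kept by default. A fixed seed makes
  training bit-reproducible (initialisation, shuffling, dropout masks and
  the validation split all draw from the seeded stream).
* `predict_proba()` accepts batches padded to any width up to the fitted
  `max_len` and re-pads internally; the dense head's input width is tied
  to the fitted length (a consequence of keeping unpooled convolution
  maps), so wider batches are rejected rather than silently truncated.

## The synthetic-data generator

Real ACP benchmarks cannot be bundled, so the generator emulates their
two class signals directly. Sequences are drawn residue-wise from a
uniform background over the 20 residues, tilted multiplicatively by
`1 + effect` toward the positive-enriched set {C,F,G,H,I,N,S,Y} in
positives and the negative-enriched set {E,L,M,Q,R,W} in negatives;
lengths are uniform on 5–50, the union of the length ranges quoted for
ACPs. Structure profiles are per-residue Dirichlet draws with
concentration 2 per state, with `helix_bias` (default 3) added to the
helix component for positives — positives then average ~56% helix
probability against ~33% for negatives, a deliberately clean version of
the helical-ACP tendency. The defaults (`effect = 2`, `helix_bias = 3`,
200 peptides per class) give a learnable but non-trivial problem; with
`effect = 0` and `helix_bias = 0` the class-conditional distributions are
identical and any classifier must sit at chance.

The uniform background isolates the planted signal but is also the main
way the generator is *unlike* real data: real peptides have non-uniform
residue usage, length-composition dependence, phylogenetic redundancy
(real benchmarks are CD-HIT-filtered at 0.9 identity) and noisy predicted
structure profiles correlated with composition. Passing the recovery
tests therefore demonstrates that the pipeline can find planted
compositional and structural signal — not that it attains any particular
accuracy on curated ACP benchmarks.

A second fixture plants a hard motif: every positive contains the 4-mer
`FGHC` and no negative does, with strongly helix- versus coil-tilted
profiles. It is used for overfitting smoke tests. One detail worth
noting: a 5×5 one-hot kernel spans only five consecutive alphabet
columns, while the motif's residues span six (C…H), so no single sequence
kernel can see the whole motif — generalisation on this fixture leans on
the LSTM and structure branches, which is intended.

## Problem sizes and test design

The verification suite works at three scales, chosen as the package's own
testing conventions:

* **Oracle scale** — exact agreement checks against independent
  reimplementations: metric formulas against expanded label vectors (with
  MCC cross-checked as the Pearson correlation of the binary vectors) on
  1000 random confusion tables; trapezoidal AUC against the tie-corrected
  Mann–Whitney rank statistic on 200 score vectors; attention, LSTM and
  convolution outputs against scalar-loop references on 100 random
  instances each; and full-network analytic gradients against central
  finite differences in both fusion modes.
* **Overfit scale** — the full default architecture must reach ≥95%
  training accuracy on the 40-peptide motif fixture within 200 epochs
  (it typically needs far fewer; training stops once the target is hit).
* **Recovery scale** — 5-fold cross-validation on 400 generated peptides
  with `effect = 2` must reach mean held-out AUC ≥ 0.85, and the same
  pipeline on null data (`effect = 0`, `helix_bias = 0`) must stay in
  [0.40, 0.60] pooled AUC; the structure-ablation check uses 180 peptides
  with `effect = 0.5` and `helix_bias = 3` (weak compositional, strong
  structural signal, so the structure branches have headroom to show
  their contribution), 3-fold CV, three generator seeds, comparing the
  full model against `use_structure = FALSE`. CV trainings in these
  checks use a 4-epoch budget with patience 2 — on this generator the
  validation loss plateaus within the first two epochs, and the short
  budget keeps the full suite within ordinary desktop runtimes.

## Known limitations

* No positional encoding (the attention operator cannot express position
  preferences by itself) and no transformer-style layer norm or
  feed-forward blocks — the attention layer is a single re-weighting
  step.
* The unpooled convolution features tie the dense head to the fitted
  padded length and make the first dense layer very wide (~14.7M weights
  at `max_len = 50`); at small sample sizes these features can overfit
  before the recurrent branches finish learning, which is visible in the
  motif-fixture experiments.
* Structure profiles are trusted as given (renormalisation aside);
  predictor error is not modelled.
* Training is CPU-bound single-instance; no GPU path and no pretrained
  embeddings.
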