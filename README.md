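# pepattn

Anticancer peptide (ACP) classification in R with an attention-enhanced
parallel CNN–LSTM network.

ACPs are short peptides (roughly 5–50 residues) that kill tumour cells by
disrupting their membranes, typically through helical membranolytic
structures. Screening candidate peptides experimentally is slow, so
sequence-based classifiers are used to triage candidates. `pepattn`
classifies peptides as ACP / non-ACP from two inputs:

* the **amino-acid sequence**, one-hot encoded over the 20 canonical
  residues (an `L × 20` binary plane per peptide), and
* optionally, **per-residue secondary-structure probabilities**
  (helix / strand / coil, an `L × 3` plane) produced by an external
  predictor such as SPIDER3 — the package consumes these profiles, it does
  not compute them.

## The model

Three feature streams are fused into a dense sigmoid classifier:

1. **Multi-head scaled dot-product self-attention** over the one-hot
   sequence `S ∈ {0,1}^{n×d_w}` (`d_w = 20`). Per head *i* with learned
   projections `W_i^Q, W_i^K, W_i^V ∈ R^{(d_w/h)×d_w}`:

   ```
   Score = Q K' / sqrt(d_w),   A = softmax(Score)   (masked over padding)
   head_i = A · V
   S' = [head_1, …, head_h] · W_M'        S' ∈ R^{n×d_w}
   ```

   The enhanced representation `S'` feeds the classification head directly
   through a *skip connection* (default), or, in *cascade* mode, replaces
   the raw one-hot input of the sequence CNN/LSTM branches. Default
   `h = 2` heads; an optional disagreement penalty (mean pairwise cosine
   similarity of head outputs) can be added to the loss.

2. **Parallel single-layer 2-D CNN branches** — 300 kernels of size 5×5
   on the sequence plane and 150 kernels of 3×3 on the structure plane,
   'valid' convolution, ReLU, **no pooling** (activation maps are kept
   whole and flattened).

3. **Peephole LSTM branches** — 45 memory units scanning the sequence
   rows and 20 units scanning the structure rows, with gates that peek at
   the cell state:

   ```
   i_t = σ(W_xi x_t + W_hi h_{t−1} + w_ci ⊙ c_{t−1} + b_i)
   f_t = σ(W_xf x_t + W_hf h_{t−1} + w_cf ⊙ c_{t−1} + b_f)
   c_t = f_t ⊙ c_{t−1} + i_t ⊙ tanh(W_xc x_t + W_hc h_{t−1} + b_c)
   o_t = σ(W_xo x_t + W_ho h_{t−1} + w_co ⊙ c_t + b_o)
   h_t = o_t ⊙ tanh(c_t)
   ```

The concatenated features pass through a dense ReLU layer (width 64),
dropout 0.45 (training only) and a single sigmoid unit. Training minimises
binary cross-entropy with Adam (lr 1e-3), early stopping on a stratified
validation split, and is fully seeded (bit-reproducible). Forward and
backward passes are implemented in this package directly on BLAS matrix
operations with small compiled kernels for the optimiser step.

Evaluation follows the field's conventions: accuracy, sensitivity,
specificity, precision, Matthews correlation coefficient
(`Mcc = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FN)(TN+FP))`) and ROC/AUC,
under stratified k-fold cross-validation with pooled held-out ROC.

## Worked example

```r
library(pepattn)

## synthetic data with the compositional + structural class signal of
## real ACP benchmarks (positives enriched in C,F,G,H,I,N,S,Y and
## helix-tilted structure profiles)
ds <- generate_dataset(synthetic_spec(n_pos = 200, n_neg = 200,
                                      effect = 2, seed = 101))
ds
#> <pep_dataset> 400 peptides (200 positive, 200 negative), 400 with structure profiles

cfg <- model_config(max_epochs = 4, patience = 2, seed = 77)
cv <- cross_validate(ds, cfg, k = 5, seed = 55)
cv
#> 5-fold cross-validation (seed 55)
#> Fold      Acc(%) Sens(%) Spec(%) Prec(%)  Mcc(%)     AUC
#> 1          97.50  100.00   95.00   95.24   95.12   1.000
#> 2          91.25   87.50   95.00   94.59   82.73   0.990
#> 3          98.75   97.50  100.00  100.00   97.53   0.999
#> 4          97.50   95.00  100.00  100.00   95.12   0.998
#> 5          95.00   90.00  100.00  100.00   90.45   0.998
#> Average    96.00   94.00   98.00   97.97   92.19   0.997
#> Pooled held-out AUC: 0.996
```

Read this the way the benchmark tables are read: per-fold accuracy,
sensitivity, specificity, precision and MCC (all as percentages) on the
held-out fold, their unweighted means, and the pooled held-out AUC as
the headline ranking quality. At compositional effect 2 with helix-biased
structure profiles the planted signal is strong and the network recovers
it almost perfectly; with `effect = 0, helix_bias = 0` the same pipeline
sits at chance (pooled AUC ≈ 0.5).

A model trained with `train_model()` can be saved with
`save_checkpoint()`, and `attention_weight_table()` exports per-residue
attention weights for inspecting which residues the model attends to.

Real data goes in the same way: `read_peptide_fasta("acps.fasta")` (labels
as `>id|1` / `>id|0` header tokens or a sidecar table) plus
`read_structure_profiles("profiles.tsv")`, paired by `build_dataset()`.

A command-line interface with `train`, `crossval`, `predict`, `simulate`
and `attention` subcommands is installed at
`system.file("cli", "pepattn.R", package = "pepattn")`.

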