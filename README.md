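# mirsite

Site-level prediction of miRNA–mRNA interactions from raw sequence,
for computational biologists who want a fully self-contained,
seed-deterministic implementation of the embedding + recurrent-network
approach to target-site classification.

A mature miRNA (19–26 nt) binds a candidate target site (CTS, ≤30 nt
of mRNA) largely through Watson–Crick complementarity of its *seed
region* (nucleotides 2–8). `mirsite` scores a (miRNA, CTS) pair as
binding / non-binding with:

1. **Distributed nucleotide representations** — each base is a dense
   d-dimensional vector learned with the skip-gram (word2vec)
   objective, treating sequences as sentences and nucleotides as
   words. Separate tables are trained on a miRNA corpus (*mi2vec*)
   and an mRNA corpus (*m2vec*); a one-hot encoder is the baseline.
   The skip-gram model maximises
   `Σₙ Σ₋c≤m≤c,m≠0 log P(w_{n+m} | w_n)` with
   `P(w_o | w_t) = exp(v'_{w_o}·v_{w_t}) / Σ_w exp(v'_w·v_{w_t})`,
   trained by negative sampling.
2. **A two-branch stacked bidirectional LSTM** — both sequences are
   right-padded to 30 nt and embedded; each branch passes through its
   own BiLSTM (hidden 50), the two feature maps are concatenated along
   the time axis, a second BiLSTM (hidden 32) reads the joint map, and
   two linear layers (→32 →2) with a softmax yield the binding
   probability: the `50-32-32-2` layout. The LSTM cell is the standard
   gated recurrence `f_t = σ(W_f[h_{t−1},x_t]+b_f)`, …,
   `c_t = f_t⊙c_{t−1} + i_t⊙tanh(W_c[h_{t−1},x_t]+b_c)`,
   `h_t = o_t⊙tanh(c_t)`.

Training uses weighted cross-entropy with Adam (lr 0.001, batch 32,
100 epochs by default); evaluation provides confusion-based metrics
(Acc/Sens/Spec/F-measure), PR/AP and ROC/AUC curves, stratified
5-fold cross-validation and paired Student's t-tests between methods.
Baseline architectures (RNN/GRU/unidirectional LSTM stacks, a 1-d
CNN) and comparison grids over encodings, layer sizes and
hyperparameters reproduce the method's ablation designs. A synthetic
generator produces labelled pairs whose positives carry an exact
reverse-complement seed match, so everything runs end-to-end with no
downloads. All numerics (skip-gram SGD, backpropagation through time,
Adam) are implemented in C++ via Rcpp/RcppArmadillo and are
bit-reproducible from a single seed on CPU.

## Worked example

Real interaction datasets measure a limited vocabulary of mature
miRNAs over and over; the example mirrors that regime with one
recurring miRNA and sites that either contain the reverse complement
of its seed or not. (The bundled generator's fully randomised study
design, and why it is *harder* than this, is discussed in the methods
vignette.)

```r
library(mirsite)

set.seed(1)
mirna <- "UGAGGUAGUAGGUUGUAUAGUU"               # let-7a-5p
site <- reverse_complement(substr(mirna, 2, 8)) # seed-match heptamer
rand_rna <- function(n) paste(sample(c("A","C","G","U"), n, TRUE), collapse = "")
pos <- replicate(500, { L <- sample(20:30, 1); s <- rand_rna(L)
                        o <- sample(L - 6, 1); substr(s, o, o + 6) <- site; s })
neg <- replicate(500, { repeat { s <- rand_rna(sample(20:30, 1))
                        if (!grepl(site, s, fixed = TRUE)) return(s) } })
ds <- site_dataset(sprintf("pair_%03d", 1:1000), rep(mirna, 1000),
                   c(pos, neg), rep(1:0, each = 500))
ds
#> <site_dataset> 1000 pairs (500 binding, 500 non-binding)

# one-hot encoding (on structure-free synthetic corpora the skip-gram
# objective is already optimal and learns nearly collinear vectors)
enc_table <- one_hot_table()

ds <- stratified_kfold(ds, k = 5, seed = 3)
test  <- subset_pairs(ds, ds$fold_of[ds$pairs$pair_id] == 0)
train <- subset_pairs(ds, ds$fold_of[ds$pairs$pair_id] != 0)
model <- init_site_model(model_config(dim = 4, hidden1 = 16, hidden2 = 8,
                                      linear1 = 8), seed = 4)
fit <- train_model(train, model, list(mi2vec = enc_table, m2vec = enc_table),
                   train_config(epochs = 40, seed = 4))
tail(fit$history[, c("epoch", "loss", "train_acc")], 3)
#>    epoch      loss train_acc
#> 38    38 0.2274646   0.91125
#> 39    39 0.2190122   0.91625
#> 40    40 0.2044200   0.93250

scores <- predict_binding(fit$model, encode_dataset(test, enc_table, enc_table))
evaluate_scores(scores, test$pairs$label)
#> <eval_report> acc 0.8750 | sens 0.9600 | spec 0.7900 | F 0.8848 | AP 0.8806 | AUC 0.9106 (thr 0.50)
```

The report reads: at the 0.5 decision threshold the model classifies
87.5% of held-out pairs correctly, recovering 96% of true sites
(sensitivity) at 79% specificity; threshold-free ranking quality is
AP 0.88 and AUC 0.91. The rule-based ceiling
(`seed_match_detector()`) is accuracy 1.0 on noise-free data.

The full pipeline — simulate → mi2vec/m2vec → train → evaluate, with
cached stages, provenance digests and byte-reproducible artifacts —
is one call:

```r
run_experiment(run_config(out_dir = "run1", seed = 7))
```

or from the shell via the bundled CLI (`inst/cli/mirsite`):

```sh
Rscript inst/cli/mirsite run --out run1 --seed 7 --simulate
Rscript inst/cli/mirsite compare-encodings --out grid --seed 7 --dims 4,50 --one-hot
```

## File formats

* **Site pairs**: TSV with header `pair_id  mirna_seq  cts_seq  label`
  (label 1 = binding); `#` lines are comments.
* **Embedding tables**: TSV, header `molecule  dim`, one line per
  token; 17 significant digits, bit-exact round trip
  (`write_embedding_table()` / `read_embedding_table()`).
* **Checkpoints**: plain-text archive of the config plus every
  parameter tensor by name, bit-exact round trip
  (`write_checkpoint()` / `read_checkpoint()`).
* FASTA in/out goes through Biostrings (`read_fasta()` /
  `write_fasta()`); an example site-pair file ships in
  `inst/extdata/example_pairs.tsv`.

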