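# secretrain

Semi-supervised prediction of blood-secretory proteins from amino-acid
sequence.

Most human proteins never reach the bloodstream, and the set of proteins
with experimentally confirmed blood secretion is small — far too small to
train a robust classifier directly while ~190,000 protein entries remain
uncharacterized. `secretrain` implements a self-training framework for this
regime, aimed at computational biologists building secretome predictors or
prioritizing candidate blood biomarkers:

- **Descriptor engine** — 639 interpretable physicochemical and
  sequence-derived descriptors per protein (global indices such as GRAVY,
  instability index, isoelectric point and hydrophobic moment; amino-acid,
  dipeptide and pseudo-amino-acid composition; CTD indices; structure
  fractions; disorder/flexibility/aggregation window profiles).
- **Unsupervised feature selection** — differential evolution over
  continuous inclusion weights $x \in [0,1]^n$, with mutation
  $v = x_{r1} + F\,(x_{r2} - x_{r3})$, binomial crossover at rate $CR$, and
  greedy selection on the mean silhouette $s = (b-a)/\max(a,b)$ of a
  seeded two-cluster k-means over the selected columns.
- **Dual-pathway classifier** — a 1-D CNN (64→128 filters, kernel 3,
  max-pool 2) over the selected descriptors fused with a bidirectional
  LSTM (embedding 128, 128 hidden units per direction) over the encoded
  residue sequence; single affine head with sigmoid output; trained with
  Adam on the class-weighted cross-entropy
  $\mathcal{L} = -\tfrac1N \sum_i w_{c_i}\,[y_i \log p_i + (1-y_i)\log(1-p_i)]$.
- **Constrained self-training** — per iteration $g$, a 3-member ensemble
  scores the unlabeled pool, the top and bottom 1% become pseudo-positives
  and pseudo-negatives, and members retrain on the expanded set under
  $\mathcal{L} + \mathcal{R}$, where the prior penalty
  $\mathcal{R} = \lambda \gamma^g \cdot \max(L - p_+,\, p_+ - U,\, 0)$
  (defaults $\lambda = 20$, $\gamma = 0.95$, band 30–40%) keeps the
  predicted secretory fraction biologically plausible.
- **Validation toolkit** — confusion-matrix metrics (ACC, SN, SP, MCC,
  rank-based AUC, two F1 variants), seeded 80/20 splitting,
  keyword/confidence filtering for negative-set construction, annotation
  cross-checking with retention reports, ER-retention (KDEL/HDEL/KEEL/QEEL)
  and dibasic (KR/RR) motif scanning, and a PCA-space Mahalanobis
  class-separation diagnostic.
- **Synthetic benchmark generator** — sequence classes with planted
  secretion cues (amino-terminal hydrophobic stretch, terminal dibasic vs
  ER-retention motifs, composition tilts) plus an unlabeled pool with a
  configurable hidden positive fraction, so the whole pipeline is testable
  without any downloads.

## Worked example

```r
library(secretrain)

# Synthetic benchmark: 100 + 100 labeled, 500 unlabeled (35% hidden positives)
syn <- simulate_proteins(synthesis_config(n_unlabeled = 500, seed = 1))

# Descriptors, standardized on the labeled partition
fm <- featurize(syn$records, descriptor_config(
        enabled_groups = c("global_physchem", "aac",
                           "structure_fractions", "length"))) |>
  standardize_features(fit_ids = syn$labels$id[syn$labels$label != "unlabeled"])

# Constrained self-training, desk-scale architecture
fit <- run_self_training(
  fm, syn$records, syn$labels,
  selftrain_config(max_iterations = 5, epochs_per_iteration = 2,
                   reg_subsample = 100, seed = 1),
  train_config(learning_rate = 0.01, epochs = 20, seed = 1),
  architecture_spec(conv1_filters = 8, conv2_filters = 16,
                    embedding_dim = 8, recurrent_hidden = 8,
                    max_sequence_length = 400))
fit
#> <selftrain_fit>
#>   3 ensemble member(s), 5 iteration(s)
#>   final loss 0.18620 (bce 0.04747 + penalty 0.13873), hard p+ 0.373

# Hidden-truth evaluation on the pool
pool <- syn$labels$id[syn$labels$label == "unlabeled"]
preds <- ensemble_predict(fit, fm, syn$records[match(pool, syn$records$id), ])
truth <- as.numeric(syn$truth$label[match(pool, syn$truth$id)] == "positive")
compute_metrics(confusion_counts(truth, preds$probability >= 0.5),
                tibble::tibble(probability = preds$probability, label = truth))
#> # A tibble: 1 x 7
#>     acc    sn    sp   mcc   auc    f1 f1_precision_recall
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>               <dbl>
#> 1 0.976 0.931     1 0.948 0.999 0.964               0.964
```

The trace (`tidy(fit)`) records, per iteration, the weighted cross-entropy,
the prior penalty, the soft and hard positive proportions and the pseudo-set
sizes; `autoplot(fit)` draws the loss trajectory. On this run the model
recovers the planted secretion signal (AUC 0.999 against hidden truth) and
the hard positive proportion settles near the 35% planted rate.

A command-line surface wraps the same functions
(`inst/exec/secretrain simulate|featurize|select-features|train|self-train|predict|evaluate|markers|build-negatives|cross-check`),
each subcommand taking `--config` (YAML) and `--seed`.

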