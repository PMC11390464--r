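# iggcn

Multi-type seizure classification from multichannel EEG with an
**iterative gated graph convolutional network**: instead of fixing a
prior electrode graph, the adjacency over channels is re-learned every
iteration by a multi-head graph attention metric, mixed with the
normalized initial graph, and used by a GRU-gated graph propagator to
embed and classify each clip. Training minimizes a joint objective of
focal loss (for the severe class imbalance typical of seizure corpora)
plus three graph regularizers, with hand-written analytic gradients and
Adam.

The package is aimed at researchers studying graph-structure learning on
EEG: it provides the full model, the spectral preprocessing pipeline that
turns annotated recordings into clips, prior-graph construction from
electrode geometry or signal cross-correlation, a class-conditional
vector-autoregressive synthetic EEG generator with ground-truth
connectivity, and an evaluation layer with multi-seed confidence
intervals and graph-recovery scoring.

## The model in brief

For a clip with node features $X \in \mathbb{R}^{C \times F}$ (per-channel
log-amplitude spectra) and initial graph $A^{(0)}$ with normalization
$L^{(0)} = D^{-1/2} A^{(0)} D^{-1/2}$, each iteration $m = 1 \dots M$:

1. **Attention metric** — per head $k$:
   $e^k_{ij} = \alpha\big([\,w^k \odot h_i \,\|\, w^k \odot h_j\,]\big)$,
   $a^k = \mathrm{softmax_{row}}(\mathrm{LReLU}(e^k))$, and
   $A^{(m)} = \tfrac1K \sum_k a^k$. Iteration 1 attends on $X$; later
   iterations attend on the previous embeddings.
2. **Mixing** —
   $\tilde A^{(m)} = \lambda L^{(0)} + (1-\lambda)\{\eta f(A^{(m)}) + (1-\eta) f(A^{(1)})\}$.
3. **Gated propagation** — $T$ tied GRU-style steps:
   $a = \tilde A^\top H + b$, update gate
   $z = \sigma(aW^z + HU^z)$, reset gate $r = \sigma(aW^r + HU^r)$,
   candidate $\tilde h = \tanh(aW^h + (r \odot H)U^h)$,
   $H' = (1-z)\odot H + z \odot \tilde h$; then mean-pool, linear,
   softmax.
4. **Joint loss** —
   $L = L_{pred} + \omega L_{smooth} + L_{degree} + L_{sparsity}$ with
   focal $L_{pred} = -\alpha_y (1-p_y)^\gamma \log p_y$.

Defaults follow the published four-class setting (hidden 256, $M = 10$,
$K = 8$, $\gamma = 2$, $\lambda = 0.3$, $\eta = 0.4$, $\omega = 0.5$,
$\beta = 0.01$, $\theta = 0.3$, 19 channels, Adam at 1e-3); see
`iggcn_config()`.

## Worked example

Two synthetic seizure classes whose 19-channel coupling topologies differ
(distributed, generalized-like, vs a focal cluster), classified end to
end:

```r
library(iggcn)

graphs <- make_class_graphs(2, 19, density = 0.2, seed = 1,
                            families = c("distributed", "cluster"))
spec <- synthetic_dataset_spec(class_counts = c(class1 = 40, class2 = 40),
                               seed = 1)
ds   <- generate_dataset(spec, graphs)
prep <- prepare_clips(ds$clips, levels = names(graphs))

sub <- function(p, idx) {
  o <- lapply(p[c("X", "A0", "L0")], `[`, idx)
  o$y <- p$y[idx]; o$levels <- p$levels; o
}
train <- sub(prep, c(1:30, 41:70))
val   <- sub(prep, c(31:35, 71:75))
test  <- sub(prep, c(36:40, 76:80))

cfg <- iggcn_config(hidden_size = 32, M = 2, K = 2, epoch = 10,
                    batch_size = 16, n_classes = 2)
model   <- iggcn_train(train, val, cfg, seed = 0)
metrics <- iggcn_evaluate(model, test)
round(c(accuracy = metrics$accuracy, weighted_f1 = metrics$f1_weighted,
        auroc_class1 = metrics$auroc[[1]], auroc_class2 = metrics$auroc[[2]]), 3)
#>     accuracy  weighted_f1 auroc_class1 auroc_class2
#>        0.800        0.792        1.000        1.000
```

After ten epochs on sixty clips the class *ranking* is already perfect
(both one-vs-rest AUROCs are 1), while the decision threshold is still
calibrating (accuracy 0.80); the packaged full-size study
(`synthetic_study_run()`, 150 training clips, 30 epochs) reaches mean
test accuracies above 0.9. Per-clip learned and mixed adjacencies are
available via `iggcn_predict(..., keep_graphs = TRUE)` or
`export_graph()` for before/after-optimization inspection.

Preprocessing of annotated recordings uses the same surface:
`map_label()` merges the eight raw annotation types into four classes,
`slice_event()` cuts events into 12-s windows, `select_channels()`
enforces the 10--20 montage order, `compute_features()` builds the
spectral node features, and `split_by_patient()` makes patient-disjoint
partitions. A thin command-line front end with `simulate` / `train` /
`evaluate` / `export-graph` subcommands is installed at
`inst/cli/iggcn.R`.

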