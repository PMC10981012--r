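# mirtransfer

Cross-species transfer learning for miRNA–mRNA target interaction (MTI)
prediction, with TransferSHAP feature attribution for the transfer step.

## The problem

MicroRNAs repress mRNAs by base-pairing to short sites in 3'UTRs.
Experimentally verified interaction catalogs (CLASH / CLEAR-CLIP and
relatives) exist for only a few species, so most species lack enough data to
train an MTI classifier from scratch. Because targeting rules are partially
conserved, a model pre-trained on a data-rich *source* species can be
fine-tuned with a few hundred interactions from a data-poor *target*
species:

* **ANN transfer** — a feed-forward network (ReLU hidden layers, sigmoid
  output, dropout + L2, Adam) is fine-tuned with its early dense layers
  frozen, so fine-tuning updates only the top of the network.
* **XGB transfer** — a gradient-boosted tree ensemble is continued
  ("partial fit"): new trees are fitted on the target chunk on top of the
  frozen source ensemble.

Model quality is scored with ACC, AUC (Mann–Whitney rank statistic),
F1 = TP / (TP + ½(FP + FN)) and MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

**TransferSHAP** asks which features carried the transferred knowledge: with
Shapley matrices Φ (observations × features) of the source-phase and
transfer-phase model computed on the same observations, the importance of
feature *f* to the transfer is

```
importance(f) = Σ_i | Φ_target[i, f] − Φ_source[i, f] |
```

— a feature important in *both* phases but unchanged by fine-tuning scores
zero. Normalized vectors are compared across all source→target pairs by
Spearman correlation and hierarchically clustered (average linkage on 1 − ρ).

The package also provides the full dataset machinery around these methods:
a duplex-scoring dynamic program with exhaustive-enumeration validation,
canonical / non-canonical / other seed typing, seed-constrained negative
generation by miRNA shuffling, a miRNA-stratified 80/10/20 split with
singleton handling and ten repeats, nested label-balanced transfer chunks,
and a seeded multi-species synthetic data generator (sequence-level and
feature-level) with a controllable domain shift δ, so the entire pipeline is
testable without external data.

## Worked example

Two synthetic species whose targeting rules diverge on distinct feature
subsets (δ = 0.6), 3,000 interactions each; pre-train on the source, then
fine-tune on growing chunks of target interactions and compare against a
model trained from scratch on the chunks alone:

```r
library(mirtransfer)

rule <- make_shift_rule(paste0("f", 1:40), c("human_like", "worm_like"),
                        list(human_like = paste0("f", 1:6),
                             worm_like  = paste0("f", 7:12)),
                        deltas = 0.6, seed = 42)
tabs <- simulate_feature_tables(rule, list(
  species_spec("human_like", n_mirnas = 60, shift = 0.6, rng_seed = 301),
  species_spec("worm_like",  n_mirnas = 60, shift = 0.6, rng_seed = 401)), 3000)

cfg <- ann_config(layer_widths = c(32, 16), dropout_rates = c(0.2, 0),
                  epochs = 80, rng_seed = 7)
curve <- run_transfer_curve(tabs$human_like, tabs$worm_like,
                            split_spec(rng_seed = 1),
                            configs = c("ann_transfer", "ann_target_only",
                                        "ann_baseline_full"),
                            chunk_sizes = seq(0, 500, 100),
                            model_args = list(cfg = cfg))
curve[, c("config_name", "chunk_size", "ACC", "AUC")]
#>        config_name chunk_size       ACC       AUC
#>       ann_transfer          0 0.8600000 0.9384951
#>       ann_transfer        300 0.8700000 0.9498993
#>       ann_transfer        500 0.8716667 0.9521245
#>    ann_target_only        100 0.6633333 0.7265435
#>    ann_target_only        300 0.8233333 0.9055174
#>    ann_target_only        500 0.8550000 0.9399971
#>  ann_baseline_full          0 0.8966667 0.9683463
```

(abridged; one row per configuration and chunk size). Read it as the
transfer figure of a cross-species experiment: the transfer curve starts at
the cross-species accuracy (0.86 — the source model applied to the target
test set unchanged), climbs as target chunks are added, and stays above the
target-only curve, which needs all 500 observations to approach it; the
dashed upper bound (0.897) is the model trained on the complete target
training set. The test set is always the fixed, held-out 20% of the target
species.

Explaining a fitted transfer pair:

```r
src   <- train_xgb(tabs$human_like, nrounds = 100)
chunk <- feature_table(as.data.frame(tabs$worm_like)[1:500, ])
tm    <- transfer_xgb(src, chunk, n_new_trees = 50)
eval  <- feature_table(as.data.frame(tabs$worm_like)[501:700, ])
ts    <- transfershap_for_model(tm, eval)
head(sort(ts$importance, decreasing = TRUE))   # target's shifted features on top
```

A thin command-line wrapper for simulation, dataset construction and the
three experiment designs ships in `inst/cli/mirtransfer.R`.

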