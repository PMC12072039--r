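# gtgo

Multi-label Gene Ontology (GO) term prediction for proteins, combining a
confidence-weighted protein–protein interaction (PPI) network with
precomputed protein language model embeddings. Intended for
computational biologists benchmarking network-based function prediction,
and anyone who wants a fully inspectable, pure-R reference implementation
of a graph transformer trained end-to-end.

## The model

The PPI branch is a **dual-branch graph transformer** over the weighted
adjacency `A` (entries are interaction confidences in (0, 1]):

* a **two-layer residual edge-weighted GCN** captures local
  neighbourhoods: with self-loops `Ã = A + I`, weighted degrees `D̃`, and
  `Â = D̃^{-1/2} Ã D̃^{-1/2}`, each layer computes
  `H ← H + σ(Â H W)`;
* a **linear-attention encoder** captures global context in one hop:
  `Q, K, V` are linear maps of the embedded node features, `Q̃, K̃` their
  Frobenius-normalized versions, and
  `SGA = D⁻¹ [V + (1/N) Q̃ (K̃ᵀ V)] + H⁰` with
  `D = diag(1 + (1/N) Q̃ (K̃ᵀ 1))` — associated so the N×N attention
  matrix is never formed; the encoder output is `MLP(LN(SGA))`.

The two blocks are concatenated into the PPI embedding, fused with an
MLP-mapped sequence embedding (mean-pooled protein language model
output), and scored per GO term by a sigmoid linear classifier trained
with binary cross-entropy, Adam, and early stopping (patience 15) on
validation loss. Evaluation is CAFA-style: protein-centric **Fmax** over
a 0.01 threshold grid and micro-averaged **AUPR**. Every linear-algebra
shortcut (linear attention, matrix-form GCN) ships with a brute-force
oracle twin, and the analytic gradients are verified against finite
differences.

A seeded synthetic benchmark generator plants functional modules jointly
in the network, the node features, the labels and the sequence
embeddings, so the whole pipeline is testable at desk scale. See
`vignettes/gtgo-methods.Rmd` for the full account.

## Worked example

```r
library(gtgo)

ds    <- simulate_dataset(sim_config())        # 4 modules x 25 proteins
data  <- assemble_dataset(ds$network, ds$features, ds$annotations,
                          ds$seq_embeddings)
split <- restrict_training_to_network(ds$split, data$network)

tc  <- training_config(hidden_d = 64, learning_rate = 5e-4, dropout = 0.2,
                       max_epochs = 500, patience = 15, seed = 0)
fit <- train_model(data, split, tc)
print(fit$model)
#> gtgo model: both branches, d = 64 , 20 GO terms, 101204 parameters
print(fit$history)
#> training history: 500 epochs, best epoch 500 (valid loss 0.00988), max_epochs

pred <- model_forward(fit$model, data, split$test)
print(evaluate_predictions(ds$annotations$Y[split$test, ], pred$S))
#> Fmax  1.0000 (tau* = 0.10)
#> AUPR  1.0000 (micro)
#> proteins  20
```

The model recovers the planted module structure perfectly on held-out
proteins (Fmax/AUPR 1.0 at the best threshold 0.10), against a
label-prior baseline Fmax of 0.40 — the score obtained by ranking every
protein with the training-set term frequencies.

The same pipeline is available from the shell via the bundled wrapper:

```sh
Rscript inst/cli/gtgo.R simulate --out fixture --seed 0
Rscript inst/cli/gtgo.R train --network fixture/network.tsv \
    --features fixture/features.tsv --annotations fixture/annotations.tsv \
    --seq-emb fixture/seq_embeddings.tsv --train fixture/train.txt \
    --valid fixture/valid.txt --test fixture/test.txt --out run
Rscript inst/cli/gtgo.R predict --model run/model.rds ... --out pred.tsv
Rscript inst/cli/gtgo.R evaluate --truth fixture/annotations.tsv --pred pred.tsv
```

Real data plug in through the same readers: STRING detailed-links edge
lists (`load_network()`, 0–1000 scores auto-scaled), two-column GAF-like
annotation tables (`load_annotations()`), sparse-triplet or dense feature
tables (`read_features()`), and per-protein embedding TSVs
(`read_embeddings()`; residue-level rows can be mean-pooled with
`gtgo pool`).

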