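# dtgcn

Seizure detection and seizure-type classification on multichannel EEG with a
**dynamic temporal graph convolutional network**, for researchers who want a
fully inspectable, CPU-scale implementation of dynamic brain-network
inference on annotated EEG — and a synthetic EEG generator that makes every
stage testable without any clinical data.

## The model

An EEG clip is a matrix `X ∈ R^{N×M}` (N time steps, M = 19 electrodes of
the 10–20 montage). Three modules are chained:

1. **Seizure-attention reconstruction.** Multi-head self-attention over time
   steps reconstructs the clip:
   `Q, K, V = X W_Q, X W_K, X W_V`, `S = softmax(QKᵀ/√d_model)`,
   `X′ = (S V) W_O`. Steps with a large reconstruction error
   `e_t = ‖x_t − x′_t‖₂` are treated as anomalous (ictal). A threshold τ is
   chosen from 50 uniform candidates spanning the training-error range by
   validation F1, and the per-time-step ("fine-grained") seizure labels
   constrain the loss
   `L_re = ‖X − X′‖_F + |card(T1) − card(T2)|/N`, where `T1 = {t :
   label_t = 1}` and `T2 = {t : e_t > τ}` (a differentiable logistic count
   stands in for `card(T2)` during training).
2. **Dynamic graph learning.** At every step, a window of the reconstruction
   is fused with the recurrent hidden state into node features `I_t`,
   diffused over the static electrode **Dist-Graph** (thresholded Gaussian
   kernel on electrode distances), saturated into source/destination
   embeddings `DE = tanh(α·DF)`, and turned into a directed instantaneous
   adjacency `E_t = ReLU(tanh(α(DE¹DE²ᵀ − DE²DE¹ᵀ)))`. Averaging the last
   `n` matrices gives `M_t`, sparsified to the top `k = 5` edges per node.
3. **Graph-convolutional GRU.** A GRU whose linear maps are graph
   convolutions on `M_t` (`u_t`, `r_t` gates, candidate `c_t`,
   `h_t = u_t∘h_{t−1} + (1−u_t)∘c_t`). The final hidden state `h_N` feeds a
   softmax head: 2-class detection, or 4-class seizure type (CF/GN/AB/CT).
   The objective is `L = −log p(e|θ) + λ·L_re` with λ = 0.3.

All gradients are **analytic** (hand-derived backpropagation through the
full pipeline, including the adjacency normalisation, top-k masks and
temporal averaging); the recurrent encoder is RcppArmadillo C++ and is
verified against a plain-R loop reference and finite differences in the
test suite. No deep-learning framework is used.

## Worked example

```r
library(dtgcn)
cfg  <- synth_config(fs = 32, seed = 1)          # 19-channel, 12 s records
data <- generate_dataset(cfg, n_records = 60)    # record-level 9:1 + test split
model <- dtgcn_model(model_config(hidden_dim = 16, d_model = 32,
                                  diffusion_dim = 8, seed = 1))
model <- train_dtgcn(model, data,
                     train_config(learning_rate = 1e-2, max_epochs = 5,
                                  batch_size = 8, seed = 1, verbose = TRUE))
ev <- evaluate_model(model, data$test, head = "detection")
print(ev)
```

Output from this exact script (five epochs, one CPU, ~3 minutes):

```
epoch   1  train 17.4008  val 15.5582  tau 0.517
...
epoch   5  train 12.7179  val 12.1119  tau 0.566
<eval_report>
  AUROC        0.8333
  weighted F1  0.9161
  confusion (row-normalised):
             predicted
true          non-seizure seizure
  non-seizure       1.000   0.000
  seizure           0.167   0.833
```

`tau` is the anomaly threshold re-searched at each validation pass; AUROC is
the detection area under the ROC on held-out records. Longer training on the
desk-scale reference setting (200 records at 64 Hz, ≤ 15 epochs; see
`tests/testthat/test-acceptance.R`) reaches AUROC ≈ 1.0 and 4-class weighted
F1 ≈ 0.96 on held-out synthetic data. Class-wise connectivity analysis
summarises the learned dynamic graphs:

```r
rep <- connectivity_analysis(model, list(
  none = Filter(function(cl) cl$seizure_class == "none", data$test),
  GN   = Filter(function(cl) cl$seizure_class == "GN",  data$test)))
round(rep$frobenius, 3)
#>    GN
#> 1.608
```

— the Frobenius norm of (mean seizure adjacency − mean non-seizure
adjacency); generalized seizures disrupt the learned connectivity more than
focal ones (an ordering the test suite asserts).

## Command line

```sh
Rscript -e 'dtgcn::dtgcn_cli()' simulate --seed 7 --n-records 50 --out data/
Rscript -e 'dtgcn::dtgcn_cli()' train --data data/ --out model.ckpt --epochs 10
Rscript -e 'dtgcn::dtgcn_cli()' evaluate --model model.ckpt --data data/ --out results.tsv
Rscript -e 'dtgcn::dtgcn_cli()' analyze  --model model.ckpt --data data/ --out conn/
Rscript -e 'dtgcn::dtgcn_cli()' sweep --param n --out sweep.tsv   # n ∈ {1,2,4,8,16}
```

## Scope

Synthetic data emulates annotated 10–20 recordings (1/f background, 10 Hz
rhythm, class-specific ictal signatures, planted coupling changes); it is
not a physiological simulation. EDF reading, a lossless flat binary clip
container, and plain-text electrode layouts are included; bipolar montage
re-referencing, artifact rejection and band-pass filtering are out of scope.
See `vignettes/dtgcn-methods.Rmd` for the full methods account.
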