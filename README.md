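# ddipool

Convolutional sentence classification with pluggable pooling for
drug–drug interaction (DDI) extraction.

A drug–drug interaction occurs when one co-administered drug alters the
action or effect of another; mining them from the pharmacological
literature supports drug safety and pharmacovigilance. `ddipool`
implements, end to end and in plain R, a CNN relation classifier over
DDIExtraction-2013 style corpora, built so that the *pooling operator* —
the step that collapses the convolution output into the feature vector the
classifier sees — can be swapped and its effect measured reproducibly:

* **Pre-processing** — XML corpus parsing, candidate-pair enumeration,
  entity blinding (targets → `drug1`/`drug2`, other drugs → `drug0`),
  removal of discontinuous mentions, and rule-based *negative instance
  filtering*: candidate pairs whose drugs are conjuncts of one coordination
  ("heparin **and** warfarin") or members of one hyponymous apposition
  ("anticoagulants, **such as** heparin") cannot interact and are removed.
* **Encoding** — fixed length *n* with a reserved pad token; each token
  carries its word index and its two signed distances *i − p₁*, *i − p₂*
  to the target drugs, regrouped from (−n+1, n−1) onto (1, 2n−1).
* **The network** — input matrix **X** ∈ ℝ^{n×(mₑ+2m_d)} concatenating
  word and position embeddings; for each window size *w* ∈ {2, 4, 6}, *m*
  filters score s_i = ReLU(Σⱼ ⟨f_j, x_{i+j−1}⟩ + b); blocks are
  zero-filled to *n* rows and stacked into **S** ∈ ℝ^{(n·k)×m}; a pooling
  operator reduces **S** to **z**; a dropout-regularised softmax layer
  **o** = **z**_d **W**_s + **d** scores the five classes *mechanism*,
  *effect*, *advice*, *int*, *none*.
* **Pooling operators** — max (z_f = max{s}), average (z_f = mean{s}),
  attentive (M = tanh(S), α = softmax(M·w^α), z = tanh(αᵀS)), and the
  combination of max and attentive over two parallel filter banks.
* **Training** — mean negative log-likelihood, Adam over shuffled
  mini-batches, max-norm constraint on the softmax weight columns,
  inverted dropout; bitwise deterministic for a fixed seed. Gradients are
  hand-derived and verified against finite differences in the test suite.
* **Evaluation** — per-class and micro-averaged P/R/F1 over the four
  interaction classes (the DDI-challenge convention); instances removed by
  the negative filter are scored as predicted-negative, so mistakenly
  filtered positives cost recall.
* **Synthetic corpora** — a seeded generator of DDI-style XML with known
  ground truth (trigger-separable classes, planted coordination /
  apposition / discontinuous structures, optional label noise and
  padding-stress lengths), giving every component a download-free test
  surface. The licensed DDI corpus is not redistributable and is not
  required by anything here.

## Worked example

```r
library(ddipool)

syn <- ddi_synthetic_corpus(200, seed = 42)   # corpus + ground truth
ds  <- ddi_prepare(syn$corpus)                # blind, filter, audit
ds
#> DDI dataset: 282 instance(s), 221 kept, 61 filtered
#> filtered by reason x gold label:
#>         reason  label count
#>  discontinuous effect     5
#>   coordination   none    31
#>     apposition   none    18
#>  discontinuous   none     7

fit <- ddi_cnn(ds, pooling = "max",
               config  = ddi_encoder_config(n = 40, m_e = 50, m_d = 5),
               control = ddi_control(epochs = 20, lr = 3e-3,
                                     n_filters = 20, seed = 1))
fit
#> Convolutional DDI classifier (max pooling)
#>   n = 40  m_e = 50  m_d = 5  widths = 2/4/6  filters/width = 20
#>   vocabulary: 62   training instances: 221
#>   loss: 0.1160 (initial 1.6094) after 20 epoch(s)

newdata <- ddi_synthetic_corpus(80, seed = 43)
ddi_score(ddi_prepare(newdata$corpus), predict(fit, newdata$corpus))
#> DDI classification report (micro-averaged overall)
#>      Class       P       R      F1
#>  mechanism 100.00%  92.31%  96.00%
#>     effect  83.33% 100.00%  90.91%
#>     advice 100.00% 100.00% 100.00%
#>        int 100.00% 100.00% 100.00%
#>    overall  97.30%  97.30%  97.30%
```

The initial loss 1.6094 is the uniform five-class baseline log 5: the
softmax weights start at zero, so the untrained model is exactly
uninformed. The five filtered `effect` pairs in the audit are gold
positives attached to discontinuous mentions; they are scored as
predicted-negative at evaluation time, which is why recall (not
precision) pays for filtering. The fitted object supports `print`,
`summary`, `coef`, `predict` (per-pair class probabilities) and `plot`
(loss curve).

A command-line wrapper with `synth` / `preprocess` / `train` / `predict`
/ `evaluate` subcommands lives at `inst/scripts/ddipool.R` (see
`?ddi_cli`), with `--pooling` selecting the operator and `--no-filter`
disabling negative filtering.

Reference scores of the full-scale configuration (n = 128, mₑ = 300,
m_d = 5, 200 filters per width) on the licensed DDIExtraction-2013 corpus
are recorded in `ddi_reference_results()` for users who supply that
corpus; they are documentation, not targets the synthetic evaluation
reproduces.

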