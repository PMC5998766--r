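---
title: "Pooling operators in a convolutional DDI classifier: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling operators in a convolutional DDI classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddipool)
```

## The task and the model

A sentence mentioning two drugs is a *relation instance*: the candidate
claim that those two drugs interact. The classifier assigns each instance
one of five labels — `mechanism` (pharmacokinetic interaction), `effect`
(pharmacodynamic effect), `advice` (recommendation about
co-administration), `int` (interaction asserted without detail) or `none`.
A sentence with $k$ drug mentions contributes up to $\binom{k}{2}$
instances, one per annotated pair.

The model is a single-layer, multi-width convolutional network over word
and position embeddings:

1. **Word table layer.** After pre-processing, each token $i$ is mapped to
   the concatenation of a word embedding ($W_e \in \mathbb{R}^{|V| \times
   m_e}$) and two position embeddings indexed by its signed distances
   $i - p_1$ and $i - p_2$ to the two target drugs. Distances in
   $(-n{+}1,\, n{-}1)$ are regrouped affinely onto $(1,\, 2n{-}1)$ by
   $d \mapsto d + n$ so the tables need no negative indices; sentences are
   padded to the maximal length $n$ with a reserved token. The result is
   $X \in \mathbb{R}^{n \times (m_e + 2 m_d)}$.
2. **Convolution.** For each window size $w \in \{2,4,6\}$ a bank of $m$
   filters produces scores $s_i = \mathrm{ReLU}\!\left(\sum_{j=1}^{w}
   \langle f_j, x_{i+j-1}\rangle + b\right)$ for $i = 1 \ldots n{-}w{+}1$.
   Per-size blocks are zero-filled to $n$ rows and stacked into
   $S \in \mathbb{R}^{(n k) \times m}$, $k$ the number of window sizes.
3. **Pooling** reduces $S$ to the feature vector $z$ (next section).
4. **Softmax layer.** With inverted dropout during training,
   $o = z_d W_s + d$ and $p(r \mid x) = \mathrm{softmax}(o)_r$ over the
   five classes.

Training minimises the mean negative log-likelihood with Adam over
shuffled mini-batches; after every update each column of $W_s$ is rescaled
to Euclidean norm at most the configured bound. Everything is written in
base R matrix code with a hand-derived backward pass; the test suite
verifies the analytic gradients against central finite differences
(relative error $< 10^{-4}$, in practice $\sim 10^{-8}$) for every pooling
kind.

## The pooling operators

Given the stacked score matrix, the package implements four reductions:

* **Max**: $z_f = \max\{s\}$ per filter, per block.
* **Average**: $z_f = \mathrm{mean}\{s\}$.
* **Attentive**: $M = \tanh(S)$, $\alpha = \mathrm{softmax}(M w^{\alpha})$,
  $z = \tanh(\alpha^{\top} S)$ — a learned soft selection over rows.
* **Combined**: two parallel filter banks, one max-pooled and one
  attentively pooled, concatenated into a single classifier input and
  trained jointly.

Padding is what separates them in practice. With the pad embeddings near
zero and zero biases, a window lying wholly in the pad region scores
$\mathrm{ReLU}(0) = 0$: the per-filter max is unchanged by how much
padding follows the sentence (ReLU keeps all scores non-negative), while
the average divides by the padded length and the attentive softmax assigns
pad rows non-trivial weight. The suite tests this directly: across random
sentences embedded at different padded lengths, the max-pooled vector is
bit-stable while the average-pooled vector moves every time. This is the
mechanism behind max-pooling's advantage on real corpora, made testable.

Two points in the attentive operator are genuinely ambiguous in its usual
presentation, and both readings are implemented:

* **Attention span** (`attention_scope`): the stacked matrix has $nk$ rows
  but the attention weights are usually described per sentence position.
  The default, `"block"`, applies attention independently per window-size
  block with one $w^\alpha$ per block and concatenates ($|z| = mk$,
  preserving the documented pooled length). `"stacked"` runs a single
  attention over all $nk$ rows ($|z| = m$).
* **Pooled rows** (`pool_rows`): `"all"` (default) pools over all $n$ rows
  of each zero-filled block, matching the stated matrix shape; `"valid"`
  restricts to the $n{-}w{+}1$ computed rows, which removes part (not all)
  of the pad sensitivity.

## Pre-processing rules

Tokenization lower-cases, keeps commas and parentheses as tokens (the
filter rules need them), strips other special characters, and replaces
standalone numbers by the literal token `NUM`. Because the text is
lower-cased before token assembly, any token spelled `num` is canonicalised
to `NUM`; this makes normalisation idempotent (re-tokenising the joined
tokens is the identity), at the cost of absorbing a literal word "num".
Each drug mention is collapsed to a single token before blinding, so
multi-word names occupy one position.

The negative filter operates on the *blinded* token sequence with two rule
families (user-replaceable via a one-pattern-per-line config file):

* **Coordination**: `drug1` and `drug2` separated only by tokens from
  {`and`, `or`, `,`, `drug0`} with at least one `and`/`or`. The rule is
  blocked when `drug1` is immediately preceded by `between`: in "between X
  and Y" the `and` links the two interacting drugs, not conjuncts — this
  distinction is exactly what makes the classic three-instance blinding
  example filter only the pair whose drugs sit in the same coordinate
  structure.
* **Apposition**: a trigger (`such as`, `including`, `like`, `e.g.`) or a
  parenthetical list linking `drug1` to a list containing `drug2`.

The original system's regular expressions were never published; these
defaults are an auditable stand-in whose behaviour on planted structures
is exact by construction (see the generator below). Discontinuous mentions
cannot be represented in the fixed-length encoding and any pair touching
one is removed, mirroring standard practice. Filtering applies to training
and test data alike; filtered test instances are scored as
predicted-`none`, so a mistakenly filtered positive costs recall and never
precision.

One labelling corner is undefined in the corpus dialect: a pair marked
interacting but carrying no type. The parser maps it to `int`, the
catch-all interaction class, with a warning — a repository decision, since
the convention is nowhere stated.

## Parameters that matter

| Parameter | Default | Meaning / why |
|---|---|---|
| `n` | 128 | maximal sentence length (tokens); training sentences define it, longer test sentences truncate around the target span |
| `m_e` | 300 | word embedding dimension |
| `m_d` | 5 | dimension of each position table (the published configuration; an earlier line of work used 10 — an unresolved discrepancy we follow the stated value on) |
| `widths` | 2, 4, 6 | convolution window sizes |
| `n_filters` | 200 | filters per window size ($m$) |
| `batch_size` | 50 | mini-batch size |
| `dropout` | 0.5 | Bernoulli drop probability on $z$ |
| `l2` | 3 | softmax-weight constraint: by default the *max-norm bound* on columns of $W_s$ (the convention of this architecture's lineage — 3 is implausibly large as an additive penalty coefficient); `l2_mode = "penalty"` switches to an additive $\ell_2$ term with that coefficient |
| `lr`, `beta1`, `beta2`, `eps` | 1e-3, 0.9, 0.999, 1e-8 | Adam's published defaults; the original training rate is unstated |
| `epochs` | 10 | bounded default; see the training-budget note below |

Initialisation: embedding tables uniform on $(-0.25, 0.25)$; filter banks
uniform with fan-balanced range $\sqrt{6/(wD + m)}$; attention weights
likewise; softmax weights and all biases zero. Zeroing $W_s$ makes the
untrained classifier exactly uniform, so the first recorded loss is the
uniform baseline $\log 5 \approx 1.609$ — a built-in sanity anchor.

## Numerical choices and degenerate inputs

* The convolution window starting at token $i$ covers $x_i \ldots
  x_{i+w-1}$; this is the only indexing consistent with the stated output
  length $n - w + 1$.
* Softmax is computed via the max-shift; prediction ties break toward the
  lowest class index (`which.max`); the max-pooling backward pass routes
  the gradient to the first maximising row.
* Distances that leave $[-n{+}1, n{-}1]$ after truncation clip to the
  boundary; the pad position code 0 sits outside the regrouped range so
  pad effects can be isolated (and zeroed) independently of real
  distances.
* A pair whose two targets cannot both fit within $n$ tokens is dropped
  with a count, not an error; an empty training set, invalid filter
  patterns (checked at load time) and non-finite losses are errors.
* Precision/recall with an empty denominator report 0 and set an explicit
  flag; the overall row pools TP/FP/FN across the four positive classes
  (micro average, the challenge convention — whether the original tables
  micro- or macro-average is not stated; micro is the task's convention).

## The synthetic generator: what it does and does not emulate

`ddi_synthetic_corpus()` emits the same XML dialect the parser reads, with
exact character offsets, multi-drug sentences, planted coordination lists,
hyponymous appositions (including parenthetical ones), discontinuous
mentions (two-span offsets), and a per-pair truth table recording the gold
class and which filter rule must fire. Classes are carried by trigger
phrases ("inhibits the metabolism of" → `mechanism`, "should not be
administered together with" → `advice`, ...), so the classes are separable
by construction and a correct implementation can approach F1 = 1; the
recall ceiling sits slightly below 1 because some planted discontinuous
pairs carry positive labels and are removed before prediction. Two stress
modes exist: `label_noise` breaks separability, and `length_mode =
"bimodal"` pads half the sentences with drug-free filler clauses to
exercise the padding sensitivity of average and attentive pooling.

What it does **not** emulate: real pharmacological lexical variety,
annotation noise, register differences between literature sources, class
co-occurrence within sentences, or trigger ambiguity. Passing the
synthetic evaluation therefore demonstrates that the pipeline and the
optimisation are correct, not that the model attains any particular score
on real corpora. Reference scores of the full-scale configuration on the
licensed DDIExtraction-2013 corpus are recorded in
`ddi_reference_results()` as documentation for users who hold that corpus.

## Problem sizes and the training budget

The desk-scale experiments (tests and `scripts/acceptance.R`) use a scaled
model — $n = 40$, $m_e = 50$, $m_d = 5$, $m = 20$ filters per width — on
500 training and 200 held-out sentences. The learning rate and epoch count
of the original training are unstated; for the scaled experiments the
package uses `lr = 3e-3` for 50 epochs, a budget at which every pooling
kind converges on the separable corpus across seeds (average pooling is
reliably the slowest to converge, consistent with it being the weakest
operator on real data). The exported defaults in `ddi_control()` remain
the conservative `lr = 1e-3`, 10 epochs. Training is single-threaded and
bitwise deterministic given the seed.

## Known limitations

* No pretrained or multi-channel word embeddings (the word table is always
  randomly initialised and learned).
* No dependency-parse features; filtering is token-level regular
  expressions only.
* Discontinuous mentions are removed rather than represented.
* The combined model trains both branches jointly with one softmax;
  pre-training the branches separately is a plausible alternative reading
  of "train two separated models ... and concatenate" that is not
  implemented.
* Pure-R training is comfortable at desk scale (hundreds of instances,
  tens of filters) but not tuned for the full-scale configuration on a
  large corpus.
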