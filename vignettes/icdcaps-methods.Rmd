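---
title: "Methods: a hybrid capsule network coder for ICD-9 assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid capsule network coder for ICD-9 assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the model

Assigning ICD-9 diagnosis categories to free-text clinical notes is
multi-label document classification with two awkward properties: the
documents are long (discharge summaries average ~1500 words), and the label
space is large and heavily skewed (in a typical critical-care corpus the ten
most common 3-digit categories account for roughly a quarter of all code
occurrences while hundreds of rare categories share a single percent).
`icdcaps` implements a hybrid neural coder for this setting with three
interlocking parts.

**Bi-LSTM encoder.** Each note, embedded with pretrained word vectors, is
encoded by a single bidirectional LSTM layer. The step equations are the
standard gate system

$$f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f), \quad
  g_t = \tanh(W_g x_t + U_g h_{t-1} + b_g),$$
$$o_t = \sigma(W_o x_t + U_o h_{t-1} + b_o), \quad
  i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i),$$
$$c_t = f_t \odot c_{t-1} + i_t \odot g_t, \qquad
  h_t = o_t \odot \tanh(c_t),$$

run forward and backward with independent parameters and zero initial
states; position $t$ carries the concatenation of both hidden states.

**Joint label embedding.** Every 3-digit category has a short textual
description ("001 Cholera", "427 Atrial fibrillation and flutter", ...).
Each label vector $C_i$ is the mean of its description's word vectors, which
places labels in the word-embedding space. Label knowledge enters twice:

* before encoding, the similarity map $G = C \otimes V$ (cosine similarity
  of every label vector with every token vector) is concatenated to each
  token embedding, $Z = f_1(G \oplus V)$, so the encoder sees for each word
  how strongly it resembles each code's description;
* after the capsule layer, the encoded note is mean-pooled, linearly
  projected back to the embedding dimension, and compared with every label,
  $D = Z \otimes C$; $D$ is concatenated to the classifier input,
  $Y = f_2(Z \oplus D)$.

**Capsule network with dynamic routing.** Valid-window n-gram convolutions
($K_1$-grams) over the encoded sequence feed a primary-capsule layer:
per window and channel, $p_i = g(W^b M_i + b_1)$ with the squashing
nonlinearity

$$v = \frac{\lVert s\rVert^2}{1+\lVert s\rVert^2}\,
       \frac{s}{\lVert s\rVert},$$

which maps capsule inputs to vectors of norm $< 1$ while preserving
direction. Class capsules are formed by routing-by-agreement: predictions
$\hat u_{j|i} = W_{ij} u_i$, logits $b_{ij}$ initialised to zero, and per
iteration $c_{ij} = \operatorname{softmax}_j(b_{ij})$,
$s_j = \sum_i c_{ij}\hat u_{j|i}$, $v_j = \mathrm{squash}(s_j)$,
$b_{ij} \leftarrow b_{ij} + \hat u_{j|i}\cdot v_j$ (the logit update is
skipped after the final iteration, matching the standard form of the
routing algorithm). The flattened class capsules, fused with $D$, enter a
dense head whose output activation follows the loss mode.

## Parameters that matter

| parameter | default | notes |
|---|---|---|
| embedding dimension `e` | 200 | matches widely used biomedical word2vec vectors; unitless |
| Bi-LSTM hidden units `u` | 300 | per direction |
| capsule dimension `d` | 50 | |
| routing iterations | 3 | more iterations sharpen couplings but rarely change decisions |
| conv window `K1` | 3 | 3–5-gram windows are the norm for clinical text CNNs |
| filters / channels | 64 / 32 | not pinned down for the full model in the source line of work; configurable |
| batch size / learning rate | 16 / 0.01 | Adam |
| loss mode | `sigmoid-bce` | see below |
| decision rule | threshold 0.5 | or top-k (k = 8 ≈ codes per admission) |
| split | 0.7 / 0.1 / 0.2 | by note, seeded |
| label space | 344 most frequent roots | frequency ranking assumed; configurable |

Open design points were resolved as follows, as the package's own choices:

* **Loss.** The source formulation trains with SoftMax + categorical
  cross-entropy, which is atypical for multi-label output because the
  scores then compete; with 8 gold codes per note no softmax score can
  clear a 0.5 threshold. Both modes are implemented; `sigmoid-bce` is the
  default so the decision rule is well-posed, and `softmax-ce` is kept for
  fidelity experiments (targets are multi-hot normalised to sum to one).
* **What `Z` means in the post-encoder cosine.** The encoder output is
  mean-pooled over positions and passed through a learned linear projection
  to dimension `e` before the cosine with `C`; a config switch to use the
  capsule output instead was considered and rejected to keep the two fusion
  points architecturally distinct.
* **How `D` enters.** By concatenation ahead of the dense head. An additive
  score adjustment is a plausible alternative reading; concatenation is
  strictly more expressive (the head can learn an additive combination).
* **Label embeddings are frozen.** `C` is the description-token mean and is
  not trained; this keeps the label-similarity features interpretable and
  spares a large gradient path. Word embeddings are likewise consumed, not
  trained.
* **V/E code rollup.** "Top three digits" is applied as the ICD-9-CM
  category convention: numeric codes keep 3 characters, V-codes `V` + two
  digits, E-codes `E` + three digits, because a literal 3-character cut
  would merge distinct E categories. A `first3` scheme is available.
* **Frequency bins.** The reporting convention for rare-code analysis
  overlaps at 100 ([51,100] and [100,∞)); the package uses [51,100] and
  [101,∞) so the bins partition the counts.
* **Error taxonomy.** The two error families are false positives and false
  negatives; per-label tallies are annotated with frequency bins and the
  top confused pairs (a missed gold code co-occurring with a false
  prediction) are reported with a similarity flag (shared 2-character root
  prefix or description cosine).

## Numerical choices

* `squash` guards the origin with $\lVert s\rVert + 10^{-12}$ in the
  denominator; `squash(0) = 0` exactly.
* Softmaxes are max-subtracted; cosines with a zero-norm argument are 0 by
  convention (padding neutrality).
* Initialisation is Glorot-uniform throughout, biases zero except the LSTM
  forget gate (1, the standard open-memory start); all draws are made in a
  fixed order from the model seed, so builds are bit-reproducible.
* Training is minibatch Adam with early stopping on validation loss
  (patience 3) and restoration of the best-validation parameters.
* The C++ engine computes exact reverse-mode gradients, including through
  the unrolled routing iterations (no stop-gradient on the couplings);
  finite-difference checks cover every parameter block in the test suite.
* Ablation wiring: `label_fusion = FALSE` zeroes the `G` tail and `D` while
  keeping shapes, so the fused graph degrades to the unfused one exactly;
  `bilstm = FALSE` feeds the (augmented) embeddings straight into the
  convolution. CapsNet / BiCapsNet / BiCapsNetLE variants are these flags.
* Notes shorter than `K1` after preprocessing are padded with the reserved
  padding token and flagged; empty notes are scored, not dropped.

## What the synthetic generator emulates

Real clinical corpora cannot be redistributed, so the generator builds
corpora with the same statistical skeleton: per-label disjoint signature
tokens whose concatenation is the label's description (so label-embedding
fusion has true signal to exploit); notes that draw a truncated-Poisson
(mean 8) code multiset from a power-law label popularity (exponent 1.5) and
plant each chosen label's signature tokens at random positions with
probability `signal_insertion_rate` among Zipf-distributed background
tokens (so the low-frequency-token filter is exercised); and 4–5-digit
diagnosis codes that must be rolled up to their roots. With
`signal_insertion_rate = 1` a keyword-matching classifier is exact — the
ceiling against which learned models are judged.

What it does **not** emulate: clinical language itself (negation,
abbreviations, misspellings, section structure), label correlations beyond
popularity, or distribution shift between splits. Tests passing on this
corpus show the architecture can recover planted lexical signal and that
every computational contract holds; they do not certify clinical accuracy.

A consequence worth stating plainly: with 20 labels and ~8 codes per note
the common labels appear in most notes, so *any* model that learns the
label base rates — including one trained on permuted targets — already
scores a substantial micro F1 under a 0.5 threshold. Contrast experiments
on such dense corpora should therefore compare against the permuted-target
control rather than against zero.

## Problem sizes used in the shipped checks

The test suite and the acceptance script train on a 3000-note, 20-label,
400-token-vocabulary corpus with mean note length 120 and a reduced model
(`e = 32`, `u = 32`, `d = 8`, `K1 = 3`, 16 filters, 4 channels), at most 10
epochs with early stopping; the ablation trend uses five seeds of the full
model against the capsule-only variant under the same protocol, since
comparing variants mid-optimisation would measure convergence speed rather
than architecture. These sizes were chosen so the whole pipeline trains to
convergence on one CPU core in minutes while leaving the learning problem
non-trivial (the trained coder reaches the keyword ceiling to within a few
tenths of a percent of micro F1).

## Known limitations

* No dropout or other regularisation inside the full model (the source
  work specifies none for it); overfitting control is early stopping only.
* The per-(channel, class) sharing of the routing transforms keeps the
  parameter count tractable at 344 labels but is an assumption; a full
  per-capsule transform would multiply parameters by the window count.
* `softmax-ce` mode is faithful to the source description but practically
  unusable with a thresholded decision rule (see above).
* Training is single-threaded and CPU-bound; the engine is written for
  exactness and determinism, not for GPU-scale corpora.
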