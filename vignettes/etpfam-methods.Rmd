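---
title: "Windowed classifiers and learned ensemble voting for protein family annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed classifiers and learned ensemble voting for protein family annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etpfam)
```

## The problem

Protein family (domain) annotation assigns each protein sequence to one of
`K` curated families. Profile-HMM pipelines fit one generative model per
family from aligned seed sequences, so they cannot share patterns across
families and struggle when a family has only one or two curated members.
`etpfam` implements the discriminative alternative: small convolutional
classifiers slide over *per-residue embedding tracks* (an `E x L` matrix per
protein, from a protein language model or this package's synthetic
embedder), several such base models are trained with different window
lengths and seeds, and their outputs are combined by voting schemes whose
weights can be *learned per model and per family* on a held-out development
partition.

## The model

### Windows and the base classifier

A sequence of length `L` is never shown to the classifier whole. During
training, windows of `W` residues are sampled at random positions that
overlap an annotated domain by at least `min(W/2, domain length)` residues,
and each window is labeled with the family of its maximal-overlap domain
(ties go to the leftmost domain). At inference, windows slide along the
whole sequence with a discrete `step` (default 4), plus one flush-right
window so the C-terminus is always scored. Sequences shorter than `W` are
right-padded with zero columns and a mask.

Each base model maps an `E x W` window to `K` class probabilities:

1. a kernel-1 convolution takes the `E` input channels to `F` filters;
2. a residual bottleneck branch — kernel-3 convolution to `Fb` filters,
   ReLU, kernel-3 convolution back to `F` — is added to the skip path,
   followed by ReLU;
3. a max-pool along the window (masked so padded columns can never win)
   yields an `F`-vector;
4. a linear layer produces `K` logits, softmaxed to probabilities.

Training minimizes softmax cross-entropy with Adam and stops early when the
development loss has not improved for `patience` epochs (default 5),
restoring the best epoch's parameters. The full-scale reference
configuration is `F = 1100`, `Fb = 550`, window lengths 32/64/128, learning
rates 1e-4 to 1e-6; the package's tests and demo use `F = 32`, `Fb = 16`,
windows 8/16/32 so everything runs on one CPU in minutes. The whole network
(im2col convolutions, masked pooling, backprop, Adam) is implemented in
base-R matrix algebra and is verified against numeric differentiation in
the test suite.

The residual block's kernel size (3), the absence of normalization layers,
and the choice of development *loss* (rather than error) as the
early-stopping metric are this package's own choices where the
architecture family leaves them open: kernel 3 is the smallest context
window that lets adjacent columns interact, omitting batch normalization
keeps single-threaded runs bit-reproducible, and the loss is a smoother
early-stopping signal than the error rate on small development sets.
Embedding tracks are fed raw (no per-track standardization).

### From window scores to one score per sequence

With `s_ik(n)` the score of model `i` for class `k` at window centre `n`,
three rules collapse a track into one vector `s_ik`:

* **CwS** — the row whose centre is nearest the sequence midpoint (earlier
  position on ties);
* **SwA** — the mean of the rows: the normalized area under each class's
  score curve;
* **SwC** — the fraction of positions each class wins (argmax, lowest index
  on ties).

The denominator of SwA/SwC is the *number of evaluated positions*, not the
residue span: with a step-4 slide this makes SwA a mean of probability
vectors and SwC a coverage fraction, so both sum to exactly 1. The
per-model prediction is `argmax_k s_ik`.

### Ensemble strategies

Given the aggregated score tensor `s[sequence, model, class]`:

* **simple voting** — each model votes for its argmax; most-voted class wins;
* **score voting** — `argmax_k sum_i s_ik`;
* **LWM** — `argmax_k sum_i w_i s_ik`, one learned weight per model;
* **LWF (perceptron)** — `argmax_k sum_i w_ik s_ik + b_k`, one weight per
  (model, family) pair plus a per-family bias;
* **LWF (MLP)** — `argmax_k f_k(s_k)`, a small per-family MLP (input `I`,
  one hidden layer of `2I` ReLU units) over the class-`k` column;
* **stacking** — a perceptron or MLP (hidden width 256) over the full `I*K`
  concatenation.

All learned combiners are fitted after the base models, by full-batch
gradient descent (Adam) on the softmax cross-entropy of their class scores
over the development partition, with 10% of the development rows held out
internally for the combiner's own early stopping (patience 5). LWM and the
LWF strategies are initialized at the score-voting reduction (`w = 1`,
`b = 0`; the LWF-MLP hidden layer is a paired +/- identity so its initial
output also equals score voting on non-negative scores). A family that
never occurs in the development rows therefore keeps score-voting
behaviour — a graceful fallback for the long tail of families with no
development members. Weights are unconstrained (no non-negativity or
normalization), and all argmax ties break to the lowest class index.

Member selection follows the central-window rule: only models with CwS
development error below 20% are eligible, members are drawn at random from
the eligible pool up to 10, and each strategy's development error is traced
at every ensemble size so the flattening of the curve can justify the size.

### Metrics

The headline number is the micro error `e = 1 - TP/(TP + FN)` pooled over
all test sequences — in this always-predict, one-label setting, simply the
misclassified fraction. Per family the package reports TP/FP/FN, recall,
error and `F1 = 2TP/(2TP + FP + FN)` (0 when the denominator is 0), with
the macro mean taken over families with at least one test member. A
multi-domain protein counts as correct when the prediction matches *any* of
its annotated families; a miss is attributed to its first-listed family, so
`sum(TP) + sum(FN)` still equals the number of test sequences. Rescue
analysis lists families at 100% error under one model and 0% under another.
Performance can be binned by training-family size or by test-to-train
similarity; the similarity of a family is the mean over its test proteins
of the maximum similarity to any training protein, with a shared-3-mer
Jaccard index as the built-in, alignment-free similarity (any pairwise
function can be plugged in).

## Dataset hygiene

Two filters precede everything: sequences must be strictly shorter than
1024 residues (the positional limit of the embedders this pipeline
targets), and no residue string may occur in more than one partition. A
string found in two or more partitions is removed *everywhere* — keeping
one copy would leak test information into training; a duplicate within a
single partition keeps its first occurrence. Families present only in the
development or test partition stay in the family index: a classifier can
then never predict them and they count as false negatives, which is the
honest accounting for them.

## The synthetic benchmark

`generate_benchmark()` emulates the statistical structure the method
assumes, not biology: each family has a random Gaussian motif vector (unit
norm by default) added to background Gaussian noise (`sd` 0.25) over the
annotated domain span; domains cover 60-90% of the sequence, as domains
typically dominate the proteins of this task; family sizes follow a
power law (smallest families a handful of members); a configurable fraction
of sequences carries two disjoint domains from distinct families; and the
partition is stratified so every family reaches train, dev and test. The
defaults (K = 12 families, E = 16, 300 sequences, lengths 60-160) are the
desk-scale study conditions used by the tests, the demo and the acceptance
script; the noise level was chosen so a small model can learn the task
while per-window ambiguity remains.

What passing on this benchmark shows: the windowing, training,
aggregation, ensemble and metric machinery is correct and the learned
per-family combiner recovers complementary expertise. What it does not
show: performance on real protein-language-model geometry, on ~17,000-way
classification, or under remote-homology splits — the synthetic motifs are
far cleaner than real embeddings, and the 3-mer similarity is only a crude
proxy for alignment identity.

`generate_score_block()` is a second, faster tier that skips training
entirely: per-model score vectors are drawn with a prescribed per-family
reliability `p_ik` and a designated confusion target, so ensemble
mathematics can be tested in milliseconds. The rescue construction — four
models, each the sole expert (p = 0.95) on a disjoint quarter of 20
families and nearly blind (p = 0.1) elsewhere — makes every single model at
least ~50% wrong while a per-family combiner can route each family to its
expert; the fitted LWF-perceptron reaches ~6-8% error there, which is the
package's distilled version of the mechanism that makes per-family
weighting work.

## Numerical choices and degenerate inputs

* All randomness flows through explicit integer seeds; sub-seeds are
  derived with a 31-bit string hash, so no global RNG state leaks between
  stages and every artifact is byte-reproducible under one seed.
* Argmax ties break to the lowest index everywhere (predictions, SwC
  winners, voting).
* Sequences shorter than `W` are zero-padded with a mask; masked columns
  are excluded from pooling by setting them to `-Inf`.
* Tracks must be softmax rows within 1e-6; SwA/SwC outputs then sum to 1 up
  to float addition.
* Probability floors (`1e-300`) guard the cross-entropy against `log(0)`.
* The stacking perceptron's `I*K*K` weight tensor is intentionally allowed
  but warned about at large `K`; it overfits long before it becomes
  computationally infeasible.

## Problem sizes used by the tests

The test suite trains base models only at toy scale (E = 4-16, F = 8-32,
windows 6-32, hundreds of sequences) and runs the full pipeline once on the
default 300-sequence benchmark; aggregation and ensemble properties are
checked on thousands of randomly generated tracks and score blocks. These
sizes are the package's chosen desk-scale study conditions: large enough to
exercise every code path and the learnability claims, small enough that the
whole suite runs in a few minutes on one CPU.

## Known limitations

* No automatic domain segmentation: per-window scores are aggregated to one
  family per sequence; boundary detection from the score tracks is future
  work.
* External embedder adapters (ESM2, ProtT5) declare their dimensions but
  require the external tooling to produce tracks; the package never
  downloads or bundles model weights.
* No score calibration or temperature scaling; combiners consume raw
  softmax probabilities.
* The evaluation rule for multi-domain proteins (any-match) is one
  consistent convention; per-domain credit assignment is out of scope.
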