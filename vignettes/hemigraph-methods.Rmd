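---
title: "Hemispheric-partition graph networks for resting-state EEG depression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric-partition graph networks for resting-state EEG depression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemigraph)
```

## The problem

Major depressive disorder is associated with lateralized abnormalities of
resting brain activity — most prominently an interhemispheric imbalance of
alpha-band (8–12 Hz) power. `hemigraph` implements a classifier that detects
depression from short windows of 19-channel resting-state EEG in a
*cross-subject* setting: every evaluation is on subjects the model has never
seen, which is the regime that matters for screening use and the one where
EEG decoders are weakest, because inter-subject variability dwarfs the
clinical effect.

The model treats electrodes as nodes of per-hemisphere functional graphs and
combines three ideas:

1. **Multi-scale temporal filtering.** Parallel depthwise 1-D convolutions
   with receptive fields of 0.4, 0.2 and 0.1 s (103, 51 and 25 samples at
   256 Hz; the kernel rule is `floor(alpha * fs)` bumped to the next odd
   integer so symmetric same-padding is exact). Each branch is
   batch-normalized per channel and passed through an ELU; branches are
   mean-fused. Depthwise grouping means channels never mix here — spatial
   interactions are deferred to the graph stage.
2. **Brain-partition-based graph learning.** The montage is split into left
   and right hemispheres of 11 electrodes each, with the midline channels
   (Fz, Cz, Pz) shared by both subgraphs. Within each region and *within
   each 2 s window*, an adaptive functional-connectivity graph is built:
   cosine similarity between L2-normalized channel time courses, negative
   similarities suppressed, self-similarity excluded, and the 10 largest
   positive similarities retained per node (element-wise maximum
   symmetrization). Each node's time course is encoded by a per-node
   two-stage ReLU temporal convolution (widths 16 then 32, time extent 7)
   with softmax attention over time steps, then projected to a length-64
   embedding. Two residual blocks of order-3 Chebyshev spectral graph
   convolution (`x <- LN(x + Dropout(ReLU(ChebConv(x))))`, dropout 0.2)
   propagate information within a two-hop neighbourhood of the region graph,
   and node-mean pooling yields one embedding per region.
3. **Attentive fusion.** A shared linear score per region embedding is
   softmaxed into region weights; the weighted sum is layer-normalized and
   classified by a linear layer into HC vs MDD. Average, max and
   concatenation fusion are available as ablation alternatives, as are
   anterior–posterior, four-region and full-brain partitions and Top-K
   values other than 10.

## Evaluation protocol

Recordings (5 min eyes-closed plus 5 min eyes-open per subject at full
scale) are band-pass filtered 0.5–70 Hz with a 50 Hz notch, trimmed to the
centered 180 s, and cut into non-overlapping 2 s windows — the window is the
unit of classification. Depressed and control subjects are matched into
pairs (seeded random matching; the matching is recorded in the output), and
a leave-one-pair-out sweep trains one model per fold on all other pairs,
holding out every window of the test pair. Within a fold, 20% of the
training windows (stratified by class, window-level) form a validation set;
training uses Adam (initial rate 0.001) under cosine annealing
(`T_max = 50`, floor 1e-6), batch size 64, at most 50 epochs, early stopping
after 10 epochs without validation-loss improvement, and restores the
checkpoint with the best validation accuracy (ties broken by lower
validation loss). Fold results are summarized as confusion counts and as
accuracy/sensitivity/specificity percentages and the F-measure
`2TP / (FP + FN + 2TP)`; fold-wise accuracies of two configurations can be
compared with a one-sided paired t-test.

Metric conventions: MDD is the positive class, so sensitivity is the recall
of depressed windows. For equal-size folds the mean of fold accuracies
equals the pooled accuracy; the F-measure is nonlinear in the counts, so its
pooled and fold-averaged values differ legitimately.

## What the synthetic generator emulates — and what it does not

Because clinical EEG cannot be bundled, `synth_spec()` /
`generate_cohort()` produce labeled cohorts in which every channel is
spectrally shaped 1/f background noise plus an alpha oscillation:

- the 1/f^β noise (β = 1 by default) is partially shared across channels
  through four common sources (`channel_correlation = 0.3`), so
  cosine-similarity graphs have real structure rather than being
  near-diagonal;
- each subject draws an alpha frequency from 9–11 Hz; each channel gets a
  random phase; the oscillation-to-noise RMS ratio is `snr`;
- the eyes-open condition attenuates alpha by a factor 0.7 (alpha
  blocking);
- for depressed subjects the alpha amplitude is scaled by
  `asymmetry_effect^(1/4)` on right-hemisphere channels and
  `asymmetry_effect^(-1/4)` on left-hemisphere ones, so the right/left
  alpha **power** ratio on homologous channels equals `asymmetry_effect`
  exactly; midline channels are untouched. `asymmetry_effect = 1` makes the
  classes distributionally identical — the null cohort.

Defaults are 200 s per condition at 256 Hz and 10 µV background RMS, so the
180 s centered-segment extraction is exercised. The generator does *not*
simulate blinks, muscle artifacts, electrode drift, or volume conduction;
passing the recovery tests therefore demonstrates that the pipeline can
find a planted, physiologically shaped class difference across unseen
subjects — not that it reaches any particular accuracy on clinical data.

## Numerical and design choices

- **Kernel rule.** `floor(alpha * fs)`, incremented if even. This is the
  only rule consistent with all three published kernel sizes
  (102.4 → 103, 51.2 → 51, 25.6 → 25); nearest rounding would give 26 for
  the 0.1 s scale.
- **Graphs are data, not parameters.** The adjacency is recomputed from the
  filtered signal of every window; Top-K selection is non-differentiable,
  so no gradient flows through graph construction (self-information
  re-enters through the identity term of the Chebyshev basis). The
  diagonal is excluded before Top-K — keeping it would spend one of the 10
  slots on a constant self-loop.
- **Symmetrization.** Row-wise Top-K is asymmetric; the element-wise
  maximum keeps every retained edge. Mean symmetrization is available via
  `symmetrize = "mean"`.
- **Ties in Top-K** break toward the lower column index, making graph
  construction deterministic across platforms.
- **Laplacian conventions.** `L = I - D^{-1/2} A D^{-1/2}`; zero-degree
  nodes use `D^{-1/2} = 0`, leaving an identity row (isolated nodes pass
  through the identity Chebyshev term). The Chebyshev operator is scaled as
  `L - I`, i.e. `lambda_max` is fixed at 2 — a valid bound for every
  normalized Laplacian — instead of a per-window eigendecomposition, for
  determinism and speed.
- **Width bookkeeping.** The residual in the Chebyshev block forces its
  output width to equal the embedding length (64). Both layers carry the
  full wrapper (residual, dropout, layer norm).
- **Attention details.** The time-attention scorer is per node (one
  length-32 vector each); the region-fusion scorer is one shared linear map
  applied to each region embedding. "Normalization" of the fused vector is
  layer normalization, consistent with the block's use of LN.
- **Loss.** Cross-entropy on two logits; cohorts are balanced by design so
  no class weighting is used.
- **Validation split** is window-level, which mixes a subject's windows
  across train and validation inside a fold; the *test* pair is always
  fully held out, so the cross-subject claim is unaffected.
- **Initialization.** Uniform fan-in scaling for convolutions and linear
  maps; the two scoring heads and the classifier start at zero, so fusion
  begins as an even average and the first logits are zero — this removes an
  unstable transient in the first optimizer steps.
- **Precision.** The embedding convolutions (the bulk of the arithmetic)
  run in single precision, the customary choice for network training;
  `precision = "double"` switches to double, which the gradient-
  verification and permutation tests use. All gradients are hand-derived
  and checked against central finite differences.
- **Zero guards.** Row normalization leaves all-zero rows at zero
  (`eps = 1e-12`); metric denominators of zero yield `NA` rather than an
  error; a zero-variance paired t-test is flagged degenerate and resolved
  by the sign of the mean difference.

## Problem sizes used by the test suite

The bundled tests run the full protocol on deliberately small cohorts: the
signal-recovery and null checks use 6 subject pairs with 14 s recordings
(centered 10 s analysed, so 20 test windows per pair), 15 training epochs,
and — for the recovery check — three seeds averaged; determinism is checked
on a 2-pair cohort. These sizes keep the whole suite at desk scale while
still exercising every stage end to end; they are choices of this package's
test harness, not of the underlying protocol, whose defaults remain 180 s
segments and 50-epoch training. With windows of one subject being strongly
dependent, the null check treats the *subject* as the exchangeable unit and
uses a subject-count binomial interval around chance.

## Known limitations

- The REST (infinity-reference) re-referencing and ICA artifact rejection
  used in clinical preprocessing pipelines require head models and manual
  component review; the package offers an optional common-average reference
  instead and otherwise expects reasonably clean input.
- Graph construction is restricted to intra-region edges by design;
  interhemispheric interaction enters only at the fusion stage.
- The EDF reader/writer covers the plain 16-bit EDF subset (uniform
  sampling rate, no annotations).
- Training is CPU-bound R/C++ with BLAS; it is sized for synthetic cohorts
  and method development, not for large clinical corpora.

## A minimal run

```{r example, eval = FALSE}
spec <- synth_spec(n_pairs = 3, duration = 60, asymmetry_effect = 4,
                   snr = 1, seed = 1)
cohort <- generate_cohort(spec)
ev <- run_lopo(cohort, hemigraph_config(max_epochs = 15, seed = 1),
               segment_seconds = 40)
summary(ev)
```
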