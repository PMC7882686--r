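---
title: "Methods: reduced-alphabet tripeptide and PSSM features for transporter classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-alphabet tripeptide and PSSM features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcp)
```

This vignette documents the model behind `rtcp`, the choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real proteins.

## The feature model

### Reduced alphabets

Four physicochemical properties — hydrophobicity (HP), surface tension
(ST), solvent solubility (SS) and charged polarity (CP) — each split the 20
amino acids into three classes. Pairing two properties and intersecting
their classes yields a reduced alphabet; the six canonical pairings have
7, 5, 5, 7, 8 and 6 classes:

```{r}
vapply(canonical_alphabets(), alphabet_size, integer(1))
```

Two caveats are handled explicitly rather than silently:

* **The property table cannot regenerate every canonical alphabet.** The
  solvent-solubility classification is internally inconsistent as published
  (S, T and C appear in two classes; D, N, Q and R in none), and the ST_CP
  column separates classes (H apart from NQDR; MYP apart from FLWIV) that a
  pure intersection of the printed ST and CP classes would merge. We
  therefore store the six canonical alphabets verbatim from their published
  class cells, in top-to-bottom cell order (which fixes the coordinate
  system of the tripeptide composition), and reserve `build_alphabet()` —
  the generic intersection — for user-supplied properties. A test confirms
  the one pairing that is consistent (HP × ST) is reproduced exactly by
  intersection.
* **Collisions and gaps.** Where a letter appears in more than one class
  cell (SS_CP lists L in both ICWFLV and LH) it keeps its first class, a
  deterministic, order-stable rule that preserves the published class count
  of 6. Letters left unassigned by a user-defined property pair are
  appended as an overflow class so the map is always a total partition.
  Non-standard residue letters (B, J, O, U, X, Z) have no class and are
  dropped with a warning before reduction.

### Tripeptide composition

The reduced sequence's overlapping 3-windows are counted and divided by the
window count L − 2, making the RTC a probability vector over the K³
tripeptides (343 coordinates for ST_SS). Normalising by windows rather
than raw counts keeps proteins of different lengths on a common simplex;
sequences shorter than 3 sanitized residues are rejected as unusable.
Coordinates are ordered lexicographically by class index and labelled
`"x-y-z"`, so feature files are reproducible bit for bit.

### PSSM summary

PSI-BLAST's ASCII profile carries, per position, 20 integer log-odds
scores. Each score is squashed to (0, 1) by the logistic function and
averaged over positions, giving one conservation summary per target
residue. The parser keeps the log-odds block (the first 20 numeric
columns), not the weighted-percentage block: the logistic squashing
presumes signed scores centred near zero, which percentages are not.
Internally the matrix is held as L rows × 20 columns, matching file row
order. The composite RTCP vector is the RTC followed by this 20-vector:
K³ + 20 dimensions, i.e. 532 for the 8-class ST_CP alphabet and 363 for
ST_SS.

### PCA

RTCP is compressed to 80 principal components by default before
classification. Component signs are fixed (largest-magnitude loading
positive) so projections are deterministic. During cross-validation the
reducer is fitted on the training folds only and applied to the held-out
fold — fitting it globally would leak held-out structure into training;
`pca_scope = "global"` is available for comparison.

## The classifier

The network is a 1-D CNN over the 80-long reduced feature vector: five
convolutions (32 filters each) with batch normalization and ReLU, max-pools
after the second and fourth convolutions, then a 64-unit fully connected
layer and a single sigmoid output. Convolution and pooling strides are 2.
Training uses Adam on binary cross-entropy with the step schedule of
`train_config()`: rate 10⁻³, ×0.1 every 100 epochs.

Choices the architecture description leaves open, and what this package
does:

* **Padding.** With unpadded stride-2 convolutions, five conv layers plus
  two pools cannot fit an 80-long input (the length reaches 1 before the
  second pool). Layers therefore use TensorFlow-style "same" zero-padding,
  under which each stride-2 stage maps length L to ⌈L/2⌉ and the stack is
  feasible (80 → 40 → 20 → 10 → 5 → 3 → 2 → 1). The exported
  `conv_output_length()` documents the unpadded arithmetic
  ⌊(L − F)/S⌋ + 1, which includes the `+1` that a literal reading of the
  window-count formula omits (without it a single-window case would count
  zero windows, and the ratio can be fractional).
* **Kernel size 3, pools after conv 2 and 4, 64-unit hidden layer.** None
  of these is pinned down by the architecture summary; all are exposed in
  the model config. Kernel 3 is the smallest standard odd kernel sensible
  for an 80-long input under two pools; pooling after every second
  convolution spreads the two pools evenly; 64 hidden units is comparable
  to the filter count.
* **Heads.** The default model ends in one sigmoid unit. The compact
  4-convolution preset for small datasets (`small_dcnn()`: filters 16, 16,
  32, 32; fully connected 13 and 2) keeps its published 2-unit softmax
  head; at a 0.5 threshold the two parameterisations make identical
  decisions.
* **Batch size 32**, a standard default; epochs are caller-chosen (tests
  and the acceptance script use ≤ 100 — see problem sizes below — while
  `train_config()` defaults to the full 1000-epoch schedule).

The forward/backward passes are implemented in vectorised base R (im2col
convolution, exact batch-norm gradients, argmax-routed pool gradients) and
are verified in the test suite against central-difference numerical
gradients on a small network. One subtlety: conv biases are analytically
cancelled by the following batch-norm mean subtraction, so their gradients
are ~0; they are retained for configurations without normalization.
Training is deterministic for a fixed seed under single-threaded BLAS.

Baselines (`train_baseline()`) delegate to the standard implementations:
`e1071::svm` (RBF kernel, cost 10⁵, gamma 1/p), `e1071::naiveBayes`,
`randomForest`, and `nnet`. All expose a positive-class score so every
classifier gets the same ROC treatment.

## Evaluation

Metrics follow the usual confusion-table formulas; with β = 1 the F-score
is the harmonic mean of precision and sensitivity, and the test suite
checks MCC against the Pearson correlation of the label vectors and AUC
against the normalised Mann–Whitney U statistic. Degenerate denominators
(a fold with no predicted positives, say) yield 0 for the affected metric
rather than NaN, keeping cross-validation aggregation total. ROC curves
sweep every distinct score plus infinite endpoints; tied scores share a
point, so the trapezoid AUC is exact.

Stratified folds are dealt round-robin within each class after a seeded
shuffle, so fold class counts differ from the stratified target by at most
one, and the assignment is persisted in the report. The
stable-misclassification analysis retrains `n_models` times on *fixed*
fold assignments, re-seeding only model initialization (the alternative —
re-splitting folds each repeat — conflates split variance with training
variance), and flags samples mispredicted strictly more than `threshold`
times.

## The synthetic generator

`generate_dataset()` emulates exactly the statistical structure the
features consume, nothing more:

* Class signal lives at the reduced-alphabet level: each class draws
  reduced-symbol sequences from a first-order Markov chain, the two chains
  being a shared uniform transition matrix multiplied by
  1 ± `signal_strength` on a seeded random half of the entries (rows
  re-normalized) for class 1. Symbols are back-translated to uniformly
  random members of their class. RTC is therefore sufficient for the
  classification by construction, which is what makes
  parameter-recovery tests of the feature pipeline meaningful.
* PSSM scores are i.i.d. Normal(mean 0, sd 2) rounded to integers — the
  signed, near-zero-centred shape of real log-odds — with `pssm_shift`
  added to a seeded subset of 5 of the 20 columns for class 1.
* Defaults: 200 sequences per class, lengths uniform on 50–400 (typical
  single- to multi-domain span), ST_SS alphabet, signal 0.5, shift 1.0.

What this does **not** emulate: domain architecture (Walker-A/LSGGQ
motifs), alignment-derived positional correlation in PSSMs, sequence
redundancy structure, or class imbalance. Passing recovery tests shows the
pipeline extracts a compositional signal it was built to see; it does not
certify accuracy on real transporter data, which depends on biology absent
here.

## Problem sizes and numerical choices

* Tests and the acceptance script run the recovery experiment at 200
  sequences per class with 5-fold cross-validation and a 60-epoch network —
  large enough that chance accuracy is ~0.5 ± 0.03 and recovery at the
  default signal is essentially complete, small enough to run in minutes on
  one CPU core.
* Null calibration uses 10 independent seeds at 100 sequences per class
  (2000 held-out predictions); the mean accuracy is required to fall in the
  99% binomial interval around 0.5.
* PCA requires `d_out ≤ min(n − 1, p)` and refuses otherwise; reducer
  orthonormality is asserted to 10⁻⁸.
* Probabilities are clipped at 10⁻¹² in the cross-entropy to avoid log(0);
  max-pool ties route gradients to the earlier position; ROC ties share a
  threshold point.
* All randomness flows from caller-supplied integer seeds; helper
  `local_seed()` restores the caller's RNG state, so library calls do not
  perturb user scripts.

## Known limitations

* The canonical alphabets are constants; regenerating them from repaired
  property definitions is deliberately out of scope.
* The CNN is CPU-only and modest in scale — appropriate for 80-dimensional
  inputs, not a general deep-learning engine.
* The PSSM parser reads the PSI-BLAST ASCII dialect only, and the package
  never runs PSI-BLAST itself; profiles are caller-supplied.
* Checkpoints serialize baseline models via R serialization inside JSON;
  they are portable across sessions of the same R major version, not a
  language-neutral exchange format.
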