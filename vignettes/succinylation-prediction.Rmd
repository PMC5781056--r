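---
title: "Predicting lysine succinylation from structural and evolutionary profiles"
author: "succpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine succinylation from structural and evolutionary profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Succinylation is a post-translational modification in which a succinyl group
is attached to a lysine side chain, flipping its charge and perturbing
protein structure and function. Experimentally mapping succinylated lysines
is expensive, so sequence-based predictors are used to prioritise candidate
sites. The difficulty is that lysines are common and modified ones are rare:
a typical curated benchmark carries on the order of ten non-succinylated
lysines for every succinylated one.

`succpred` implements a predictor that describes each lysine by the
*structural* and *evolutionary* context of its surrounding residues and
classifies it with an RBF-kernel support vector machine, after reducing the
negative-class excess by a k-nearest-neighbour elimination rule.

## Input tracks

Two per-residue profiles are required per protein, both of length L (the
protein length):

* an **evolutionary profile**: the L x 20 position-specific scoring matrix
  (PSSM) produced by an iterative profile search, used on its linear
  probability scale. PSI-BLAST ASCII files carry both integer log-odds and
  weighted observed percentages; by default we use percentages / 100, the
  only columns already on a linear probability scale. A logistic transform
  of the log-odds columns is available via `read_pssm(..., scale_mode =
  "logodds")` since the toolchains behind published predictors are often
  ambiguous on this point.
* a **structural profile** (SPIDER2 `.spd3` style): accessible surface area
  (ASA, in Angstrom^2), the three-state secondary-structure probabilities
  (helix `ph`, strand `pe`, coil `pc`), and four backbone angles
  (phi, psi, theta, tau, in degrees). Secondary-structure rows are accepted
  when they sum to 1 within 0.05, absorbing predictor output jitter.

All external coordinates are 1-based and inclusive. Columns of every PSSM
are remapped at parse time to the fixed PSI-BLAST header order
(`AA_ORDER`), so one canonical feature ordering is used everywhere.

## The peptide window and mirror padding

Each lysine K at position c is represented by the 31-residue peptide
{A−15, ..., A−1, K, A1, ..., A15}. When the window overruns a terminus, the
gap is filled by the *mirror effect*: a nominal position p outside [1, L]
is reflected about the nearest terminal residue,

    p < 1  ->  2 − p          p > L  ->  2L − p

applied iteratively for proteins shorter than the window. The reflection
axis passes *through* the terminal residue (position 1 maps to itself), a
convention this package fixes and documents since figure-level descriptions
of mirror padding generally leave it open; `padding = "mirror-center"` is
retained as a sensitivity alternative. `window_indices()` returns the
resolved positions plus flags marking mirrored slots.

## The 657-component descriptor

Three blocks are concatenated per lysine (`assemble_features()`):

1. **Structural block (248)** — the eight structural tracks over the 31
   slots, track-major: 31 ASA values, then 31 `ph`, `pe`, `pc`, `phi`,
   `psi`, `theta`, `tau`. Angles enter raw in degrees; no sin/cos encoding,
   preserving the printed dimensionality.
2. **PSSM bigram block (400)** — the bigram transition profile of the
   window's 31 x 20 PSSM track,

   B[p, q] = sum over k = 1..30 of m[k, p] * m[k + 1, q],

   flattened row-major (first index slowest). The sum runs over consecutive
   window slots, so the block is 400-dimensional *regardless of the window
   size* — the property that makes wide windows affordable.
3. **Secondary-structure bigram block (9)** — the same transformation on
   the 31 x 3 probability track.

Useful invariants, all tested: for row-normalised tracks the total bigram
mass is exactly 30 (the number of consecutive pairs); reversing the window
transposes B; a window of one-hot rows concentrates the whole mass in a
single cell.

With `bigrams = FALSE` the PSSM and secondary-structure tracks enter raw
(961 components in total) — the ablation configuration used to measure what
the bigram transformation contributes.

## Class balancing by k-NN elimination

With roughly 10 negatives per positive, the classifier would otherwise
learn the prior. `balance_dataset()` eliminates any negative whose k
nearest neighbours (both classes pooled, self excluded) include at least
one positive, starting at k = 10 and increasing k by 1 until the retained
negatives number at most `ratio_max` (default 1.10) times the positives.
Decisions at every k are made simultaneously against the original dataset;
because a positive inside the (k−1)-neighbourhood is inside the
k-neighbourhood, removal sets grow monotonically with k and re-running from
the original set or shrinking the pool cumulatively are equivalent. The
default stopping ratio 1.10 reflects the near-parity (ratio about 1.05)
that this procedure is known to reach on real succinylation benchmarks.

Distances are Euclidean on per-feature z-scores computed on the dataset
being balanced — without standardisation the ASA (tens of Angstrom^2) and
angle (hundreds of degrees) columns would dominate the probability-scale
features. Ties are broken by ascending sample index, making the procedure
deterministic.

A geometric caveat worth knowing: the rule only bites where the classes
overlap. If the positives form a tight, well-separated cluster, every
negative's near neighbourhood is purely negative until k reaches the
cluster's typical rank, at which point most negatives are removed at once.
On such data the retained-negative count can fall from far above the target
ratio to near zero in a few k steps. This is a property of the rule, not of
the implementation, and it is why the balancing tests use weakly separated
synthetic data — the regime the rule was designed for.

## The classifier

An RBF-kernel soft-margin SVM with the conventional settings for this task:
C = 1, gamma = 0.01, solver tolerance 0.001. The decision function is the
dual expansion

    y' = sign( sum_i alpha_i y_i exp(−gamma ||x_i − x'||^2) + beta )

`svm_train()` delegates the dual optimisation to libsvm (via e1071) but
stores the support vectors, dual weights and bias, and `svm_decision()`
evaluates the expansion explicitly — the solver's own prediction path then
serves as an independent cross-check in the tests. Features are z-scored
with training-fold statistics before the kernel; with raw mixed-unit
features a single shared gamma would be meaningless. `sign(0)` is defined
as +1. The round-off parameter epsilon = 1e−12 quoted for the Weka-based
original has no libsvm analogue; it is recorded on the model object for
provenance and the solver tolerance is the operative control. ROC scores
use the real-valued margin; no probability calibration is attempted.

## Evaluation

`confusion_counts()` and `classification_metrics()` implement sensitivity,
specificity, accuracy and the Matthews correlation coefficient from the
four confusion cells; a zero MCC denominator yields 0, and a class absent
from the truth makes the corresponding rate NA. `roc_auc()` computes the
threshold-free AUC as the normalised Mann–Whitney statistic with tied
scores contributing 1/2.

`cross_validate()` follows the standard n-fold protocol: partition,
hold one fold out, train on the rest, score the held-out fold, rotate and
average. Two interpretation choices are fixed and documented:

* partitioning is *stratified* (class proportions preserved per fold) so no
  validation fold can lose a class on small data;
* "repeat n times" is read as rotation over the n folds of one partition,
  not n independent re-partitions.

By default the dataset is cross-validated as given — matching the original
evaluation design in which balancing precedes cross-validation. Because
that lets the elimination step see future validation folds,
`balance_within_folds = TRUE` offers a leakage-free variant that balances
each training portion only.

## The synthetic benchmark generator

`synth_generate()` emulates all four inputs with a tunable
class-conditional effect size delta in [0, 1]:

* sequences uniform over the 20 amino acids, lysines planted at site
  positions, sites spaced at least one full window apart so negative
  windows never overlap a positive site's signal region;
* background PSSM rows from a symmetric Dirichlet; within the flank of a
  positive site each row is mixed with a fixed motif vector at weight
  delta (the default motif is biased toward acidic residues, echoing the
  charge context of succinylation);
* ASA half-normal (scale 60 Angstrom^2), secondary-structure rows
  Dirichlet(1,1,1), angles uniform in [−180, 180]; positive windows are
  mixed toward an exposed ASA mean (120 Angstrom^2) and a helix-leaning
  secondary-structure mean. Angles stay uninformative by design, so block
  ablations can attribute performance.

At delta = 0 the classes are distributionally identical; at delta = 1
positive-window PSSM rows equal the motif exactly. Defaults (120 proteins
of length 150–300, 60 positive and 600 negative sites) mirror the 10:1
imbalance of real succinylation benchmarks at a size where every pipeline
stage runs in seconds. `write_fixture_set()` emits the exact on-disk
dialects the readers parse, quantising PSSM percentages to integers as the
genuine format does (lossy at the 0.005 level; in-memory tests use
unquantised matrices).

What the generator does *not* emulate: phylogenetically realistic PSSMs,
genuine succinylation motifs, correlated structural tracks, or annotation
noise. Passing tests therefore demonstrate that the machinery recovers a
planted signal under controlled conditions, not that any particular
accuracy will be reached on biological data.

## Test problem sizes

The signal-recovery checks use 300 positive + 300 negative sites across 120
proteins: large enough that cross-validated accuracy at delta = 0 settles
near 0.5 (observed 0.49) and the delta = 1 signal is fully recovered, small
enough that the whole suite runs in about a minute and a half. Fold-count
stability is checked by comparing 6-, 8- and 10-fold means on one dataset
(they agree within 0.03). The balancing acceptance check uses a 30 + 300
site benchmark at delta = 0.1 — weak separation, the overlap regime where
incremental elimination terminates gradually (observed k about 139, final
ratio 1.03).

## Limitations

* Published headline figures for this family of predictors (sensitivity
  0.87-ish, accuracy 0.84-ish on curated benchmarks) require the original
  670-protein dataset plus PSI-BLAST and SPIDER2 runs, none of which are
  redistributable here; this package reproduces the method, and its tests
  validate the machinery on synthetic data only.
* Running PSI-BLAST or SPIDER2 is out of scope; the package parses their
  outputs.
* The k-NN elimination rule degenerates on strongly separated data (see
  above); inspect the `removed_per_k` trace in the balance report before
  trusting a balanced set.
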