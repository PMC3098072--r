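---
title: "Predicting GTP-interacting residues from windows and evolutionary profiles"
author: "gtppred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting GTP-interacting residues from windows and evolutionary profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtppred)
```

## The problem and the model

GTP-binding proteins (G-proteins, kinases, Ras-family GTPases) contact their
nucleotide through a small number of residues, classically organised around
the Walker A / P-loop element `GXXXXGK(T/S)`. Given only a protein sequence,
we want to call, residue by residue, which positions contact GTP.

`gtppred` treats this as window classification. Every residue owns a
fixed-length sequence window centred on it; a classifier decides from the
window whether the centre is GTP-interacting. Three *techniques* differ only
in the width of the centre:

* **SRT** (single residue): window length $L = 17$, centre $k = 1$;
* **DPT** (dipeptide): $L = 16$, centre $k = 2$ consecutive residues;
* **TPT** (tripeptide): $L = 17$, centre $k = 3$.

A DPT/TPT pattern is *positive* only when **all** centre residues are
interacting and *negative* only when all are non-interacting; windows whose
centre mixes both labels are excluded outright. This strict definition is
what makes the dipeptide/tripeptide classes cleaner (and their classifiers
stronger) than the single-residue class, at the price of coverage: isolated
interacting residues start no all-interacting pair or triple, so they are
invisible to DPT/TPT. `predict_protein()` therefore combines all three
models, by default as a union over covering calls.

So that terminal residues own full windows, the chain is padded with the
dummy residue `X`: $(L-1)/2$ per terminus for odd $L$ (8 per side at
$L=17$), and $L/2-1$ / $L/2$ at the N-/C-terminus for even $L$ (7/8 at
$L=16$). An even window has no single centre; placing the extra `X`
C-terminally puts the pair centre at window positions 8–9 and guarantees
every adjacent pair, including terminal ones, a complete window.

### Encodings

Two encodings map a window to $L \times 21$ numbers (357 at $L = 17$), one
21-entry block per window position, alphabet fixed alphabetically with `X`
last:

* **binary** — one-hot indicator per position;
* **pssm** — the row of a normalized position-specific scoring matrix for
  the underlying chain position. Raw PSI-BLAST integer log-odds $x$ are
  mapped through the logistic $1/(1+e^{-x})$; padding positions contribute
  all-zero blocks.

The logistic was chosen over min–max scaling because it is
dataset-independent: a min–max fit on pooled data would leak information
across cross-validation folds. Zero padding rows (rather than 0.5, the
logistic image of a raw 0) keep "no residue" distinguishable from "residue
with neutral conservation". Both choices are configurable
(`normalize_pssm(method =)`).

### Classifiers

* **svm** (default): a support-vector machine (libsvm via `e1071`), RBF
  kernel, cost 10, $\gamma$ = 0.01 by default. Scores are signed decision
  margins. A small in-training-fold grid (cost $\{1,10,100\}\times\gamma
  \{0.01,0.1\}$, 3-fold) is available via `hyperparameters = list(tune =
  TRUE)`; it is off by default because it multiplies the number of fits
  roughly twentyfold and the fixed values are adequate across the package's
  benchmarks.
* **ann**: a single-hidden-layer feed-forward network (10 hidden units)
  trained by online error back-propagation on a sum-of-squares error with
  learning rate 0.01, weights initialised uniformly in $[-0.5, 0.5]$ from
  the mandatory seed. Training stops when the sum-of-squares error on a
  held-out fifth of the training patterns has not improved for 5 epochs
  (100 epochs maximum), and the best weights are kept. Outputs are logistic,
  in $[0,1]$.

### Datasets, cross-validation and metrics

Patterns from all chains are deduplicated on the window string (a window
seen with both labels is dropped from both classes, with a warning). The
**main** regime balances classes: all unique positives plus an equal-size
seeded random sample of negatives. The **realistic** regime preserves
imbalance: all negatives for SRT, and ten negatives per positive for
DPT/TPT (binding-site residues are a small minority of any real chain, so
balanced training sets answer a different question than deployment does).

`five_fold_cv()` partitions patterns into five stratified folds; each fold
is the test set exactly once. Test scores are swept over the backend's
threshold range ([0,1] for ann, [−1,1] for svm, step 0.1, endpoints
included, a call being positive when score ≥ threshold) and the per-fold
metric tables are averaged arithmetically at each threshold. Metrics per
threshold: sensitivity/recall, specificity and accuracy as percentages,
precision and F1 as fractions, and the Matthews correlation coefficient
(MCC), with every zero-denominator case defined as 0 — so the degenerate
all-positive threshold on a balanced set prints Sn 100, Sp 0, Acc 50.00,
MCC 0. AUC is the trapezoidal area under the ROC traced over all distinct
score thresholds; the report carries the mean of per-fold AUCs plus pooled
out-of-fold ROC and precision–recall points.

The working threshold is chosen on the fold-averaged table
lexicographically: maximum MCC, then maximum accuracy, then maximum
precision (skipped if the table has no precision column), then least
$|Sn - Sp|$, then the lowest threshold. Ties are compared with a $10^{-9}$
guard so that printed two-decimal tables behave exactly.

Folds are drawn at the pattern level by default, as is conventional for
window methods; note that overlapping windows from one protein then appear
on both sides of a split, which flatters the estimate. `split_by_chain =
TRUE` assigns whole chains to folds instead and is the honest setting when
chains are plentiful.

## What the synthetic generator emulates — and what it does not

The package ships a seeded generator (`generator_config()`,
`generate_chains()`, `generate_profiles()`) so every stage is testable
without downloads. Each chain (default: 100 chains, lengths 80–150 drawn
uniformly) is background sequence at natural amino-acid frequencies with
one planted Walker-A-like motif (`GXXXXGKT`, wildcards stay background).
The motif's fixed residues ±1 neighbour are labeled interacting, giving
about 8 interacting residues per chain — a realistic minority fraction
(~7%). Each chain also receives one *decoy*: the same motif letters planted
without labels and without conservation, mimicking chance occurrences of
P-loop-like strings in non-binding contexts. Decoys are why evolutionary
information matters in this test bed, exactly as on real proteins:
sequence identity alone cannot tell a true site from a look-alike, while
conservation can.

Simulated profiles live on the integer log-odds scale of the PSI-BLAST
ascii dialect (clamped to ±10). A background row scores its own residue +2
and all others −1; at interacting positions the row is sharpened by
`peakedness` (default 4): own residue ×4, others depressed to −4 —
mirroring the high information content of a conserved alignment column.
Integer Gaussian noise (sd 1) is added everywhere. At `peakedness = 1` the
profile carries no label information at all, which anchors the monotone
signal-recovery property the tests exercise over peakedness 1, 2, 4.

What the generator does **not** emulate: homologous chains (every chain is
independent), real alignment pseudocounts and composition biases,
structural context (labels come from a motif rule, not geometry), or motif
degeneracy beyond the wildcard positions. Consequently, passing recovery
tests demonstrate that the pipeline extracts a planted conservation signal
under class imbalance and noise — not that the shipped defaults reach any
particular accuracy on real GTP-binding proteins. Published figures for
this family of methods (main-regime, five-fold CV on a 44-chain
non-redundant set) put profile-based models far ahead of single-sequence
ones and TPT ahead of DPT ahead of SRT; reproducing such numbers requires
the curated structures, contact assignments and SWISS-PROT profile
searches, all outside this package's scope.

Benchmark sizes used in the test suite were chosen to keep the full
pipeline exercises comfortable on a laptop: the main recovery study uses
the generator defaults (100 chains, ≈1,600 balanced SRT patterns of 357
features); property tests use 15–25 chains.

## Numerical and degenerate-input choices

* Ties at the decision threshold are called positive (score ≥ threshold),
  which makes the sweep's low endpoint the all-positive row.
* MCC, precision, F1, sensitivity and specificity are 0 whenever their
  denominator is 0; accuracy is always well defined on non-empty input.
* Sweep grids are generated as `lo + step * 0:n` to avoid floating-point
  drift in the endpoint.
* `extract_patterns()` on a chain whose every centre is mixed returns an
  empty pattern frame rather than an error; `build_dataset()` then reports
  the missing class.
* SVM decision values are re-oriented from libsvm's class-order convention
  so that positive always scores high; scores are unnamed so ordering
  equivariance is exact.
* The structure annotator uses heavy atoms only and squares distances
  (no square roots) against the squared cutoff; cutoff 0 labels nothing.
* Seeds are mandatory arguments everywhere randomness occurs and are used
  through a scoped RNG that restores the caller's state.

## Known limitations

* Pattern-level cross-validation (the default, for comparability with the
  window-method convention) is optimistically biased; prefer
  `split_by_chain = TRUE` for honest generalisation estimates.
* The realistic regime's 10× negative cap for DPT/TPT is a rule, not an
  estimate of the true imbalance, which varies by protein.
* The ANN backend is a reference implementation of online back-propagation;
  it is deliberately small and is not tuned for speed on large feature
  sets.
* The distance-cutoff structure annotator is a simple geometric stand-in
  for dedicated contact-assignment software; its 4.0 Å heavy-atom cutoff is
  exposed precisely because published contact criteria differ.

## A compact end-to-end run

```{r pipeline, eval = FALSE}
cfg <- generator_config(n_chains = 30, seed = 101)
chains <- generate_chains(cfg)
profiles <- generate_profiles(chains, cfg)

patterns <- extract_patterns_all(chains, "SRT")
dataset <- build_dataset(patterns, regime = "main", seed = 102)

cv <- five_fold_cv(dataset, encoding = "pssm", backend = "svm",
                   profiles = profiles, seed = 103)
cv$selected_threshold
cv$averaged[, c("threshold", "sensitivity", "specificity", "accuracy", "mcc")]

model <- train_model(dataset, "pssm", "svm", profiles = profiles,
                     seed = 103, threshold = cv$selected_threshold)
pred <- predict_protein(chains[[1]]$sequence, list(srt = model),
                        profile = profiles[[chains[[1]]$id]],
                        chain_id = chains[[1]]$id)
head(as.data.frame(pred))
```
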