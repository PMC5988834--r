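---
title: "Semi-supervised local-margin gene selection: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised local-margin gene selection: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semimm)
```

## The problem

Tumour expression studies routinely produce matrices with thousands of genes
and a few dozen samples, of which only a handful carry confirmed class
labels: labelling tissue is slow and expensive, profiling it is not. Filter
feature selection — ranking genes by a classifier-independent score before
any model is fit — is the standard first step, but the classical scores sit
at two extremes. The Fisher score uses only the labeled samples and ignores
the rest; the Laplacian score (LS) uses every sample but ignores the labels
entirely. This package implements a semi-supervised criterion, `semiMM`,
that uses both at once, plus the comparison scores and an SVM benchmark
protocol, all testable on synthetic data with known ground truth.

## The score

Samples are first standardized per gene (zero mean, unit population
variance) and connected by a k-nearest-neighbour graph (Euclidean distance,
OR-symmetrized, distance ties broken toward the lower sample index). The
graph is then split into two weight matrices over sample pairs:

* **between-class** `W_b`: weight 1 for neighbour pairs whose two samples
  are labeled with *different* classes;
* **within-class** `W_w`: weight `gamma` for any pair labeled with the
  *same* class, and weight 1 for neighbour pairs with at least one
  unlabeled endpoint. The two matrices are mutually exclusive.

With `S = W_w - W_b`, degree matrix `D_ii = sum_j S_ij`, and signed
Laplacian `L = D - S`, each gene `f` (a row of the standardized matrix) is
scored as

    score(f) = lambda * (f' L f) / (f~' D f~)  +  (1 - lambda) * (1 - NMI(f, C))

where `f~` is `f` centered by its degree-weighted mean (`f~ = f - (f'D1 /
1'D1) 1`) and `NMI(f, C)` is the normalized mutual information between the
discretized gene and the class labels. **Smaller is better.** The quadratic
form `f' L f` equals half the weighted sum of squared within-class feature
differences minus the between-class ones — the local margin — so minimizing
the first term rewards genes that vary little inside a class, much across
classes, and much overall (through the degree-weighted variance in the
denominator). The second term rewards genes whose values predict the class
labels directly.

Two reading notes on the quadratic form. First, the explicit
double-summation form of the margin carries a factor 2 relative to
`f' L f`; we implement the quadratic form, which merely rescales the
meaning of `lambda` by a constant and leaves every ranking unchanged.
Second, the numerator is invariant to adding a constant to `f` (because
`L 1 = 0`), so centering the numerator or not are numerically identical;
the denominator must be centered and is.

### Mutual information details

The class variable exists only on labeled samples, so NMI is computed over
labeled samples alone. The gene is discretized into `B` equal-width bins
spanning its labeled range with an inclusive top edge;
`B = max(2, ceiling(sqrt(n_labeled)))` by default (`mi_bins` overrides).
Entropies and mutual information are plug-in estimates in bits, and

    NMI = MI / max(H(feature), H(classes)),

clamped to `[0, 1]`. If either marginal entropy is zero (constant feature,
single labeled class, or no labels at all) NMI is 0 by convention, making
the second term a constant that cannot reorder genes. Equal-width binning
was chosen over quantile binning for determinism: it never depends on tie
structure, and the bin count rule keeps expected counts per cell roughly
constant as labels accumulate. A consequence worth knowing: with very few
labeled samples the plug-in MI is biased upward for pure-noise genes, which
blunts — but does not invert — the contrast between informative and noise
genes.

### Degenerate genes

A gene is *degenerate* when its degree-weighted variance `f~' D f~` is not
positive: constant genes, and the rare case where between-class edges
dominate a sample's degree so strongly that `D` carries large negative
entries. The quotient is then meaningless; such genes get an `Inf` score,
a `degenerate` flag, and always rank last. This keeps the ranking contract
total without silently fabricating a score. The same convention applies to
constant genes in the Laplacian score.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `lambda`  | 0.6 | blend weight between margin and NMI terms; in (0,1), endpoints allowed for diagnostics (1 = margin only, 0 = NMI only) |
| `k`       | 5   | neighbours per sample in the graph; small enough to stay local at a few dozen samples |
| `gamma`   | 100 | within-class weight for same-labeled pairs; makes labeled agreement dominate the margin |
| `mi_bins` | `max(2, ceiling(sqrt(n_labeled)))` | discretization bins for NMI |
| `t` (LS)  | mean squared neighbour distance | heat-kernel bandwidth; `Inf` gives binary weights |
| `alpha` (LSDF) | 100 | same-class weight in the LSDF-style ratio |
| SVM | linear kernel, cost 1 | benchmark classifier; the conventional microarray default |

The same-class `gamma` clause deserves a note: as written, the within-class
weight applies to *any* same-labeled pair, neighbours or not, and that is
the default here. The restrictive reading — same-labeled *and* neighbours —
is available via `within_labeled_requires_neighbor = TRUE`. We keep the
literal reading as default because the defining case analysis states no
neighbourhood condition for labeled pairs, and because it makes the labeled
part of the margin independent of the (noise-sensitive) neighbour structure.

## Baselines

* **Laplacian score** (`laplacian_score()`): unsupervised;
  `f~' L f~ / f~' D f~` on a heat-kernel kNN graph, smaller is better.
* **Fisher score** (`fisher_score()`): supervised; between-class over
  within-class scatter on labeled samples only,
  `sum_c n_c (mu_c - mu)^2 / (sum_c n_c sigma_c^2 + 1e-12)`, larger is
  better. The epsilon guards perfectly separated genes.
* **LSDF-style margin ratio** (`lsdf_score()`): semi-supervised;
  `f' L_b f / (f' L_w f + 1e-12)` with the within/between Laplacians built
  from the same graph split, larger is better. This is a reconstruction
  from the method's published description and its stated settings
  (`k = 5`, `alpha = 100`), not a line-by-line port of the original
  algorithm; the module documents this explicitly.

## The synthetic generator

`simulate_expression()` emulates the "small sample, high dimension"
regime: `n_genes` i.i.d. Normal(0, `noise_sd`^2) genes over a few dozen
samples in 2–5 classes, with `n_informative` genes given a mean shift of
`effect * noise_sd` in exactly one class each (one-vs-rest marker pattern,
markers split round-robin across classes). `mask_labels()` then keeps `L`
labels per class by stratified sampling, mirroring the protocol in which
the labeled count is `L` times the number of classes. The defaults
(500 genes, 20 informative, 3 classes of 20 samples, effect 2, `L` masks
of 4) are the reference study conditions used by the test suite and the
acceptance script.

What the generator deliberately does **not** model: probe/batch effects,
heavy-tailed noise, correlated gene blocks, or class-conditional variance
changes. Passing tests on this family therefore demonstrate correctness of
the algorithms and calibration of the pipeline, not performance claims on
real microarray data.

One property of this family matters for interpreting results: because
informative genes are the *only* high-variance, graph-smooth genes, the
purely unsupervised Laplacian score is unusually strong here — variance
alone nearly identifies the markers. Real tumour data behave differently
(high-variance genes are often technical artefacts, which is the reason
semi-supervised scores exist), so relative method rankings on this
generator should not be extrapolated.

## The benchmark protocol

`run_benchmark()` reproduces the standard evaluation loop. Per repeat:
a stratified 6:4 train/test split; an `L`-per-class label mask drawn *from
the training portion only*, so no scoring method ever sees a test sample
(the alternative ordering — mask first, split later — risks leaking test
samples into the graph; we use the leak-free ordering and assert it in
tests); gene ranking per method on the training samples; then, for each
subset size on the gene grid, a one-vs-rest linear SVM trained on the
top genes with the training set's full labels and evaluated on the test
set. Genes are z-scored with training-set statistics. Accuracy, precision,
recall and F-score come from the per-class confusion counts (macro
average; a zero denominator defines the metric as 0, flagged), AUC from
the SVM decision values; a class absent from a test fold is dropped from
the AUC mean with a warning. Split and mask seeds derive deterministically
from the master seed per (L, repeat), so method arms are paired. The extra
method `"random"` — a seeded uniform gene shuffle — is the negative
control.

## Numerical choices

* Population (1/m) standard deviations in standardization, matching the
  variance convention of the scores.
* kNN distance ties resolve to the lower sample index; score ties resolve
  to the lower gene index. Both make every ranking reproducible.
* `L` rows sum to zero by construction; tests verify `|L 1|` at 1e-10
  scale and shift invariance of the margin term at 1e-8.
* Degenerate thresholds: denominators are treated as zero below 1e-12.
* All RNG flows through explicit seeds (`with_seed()` restores the
  caller's RNG state), so identical seeds give bit-identical matrices,
  masks, splits and output files.

## Problem sizes used in the tests

Oracle-equivalence tests run 30 random instances with up to 12 samples and
8 genes against independently coded double-loop implementations of every
sum (tolerance 1e-10, relative). Recovery and benchmark tests use the
reference conditions above: 20 generator seeds for recovery, 10 paired
repeats for the SVM comparison, 50 seeds for the null-calibration check
that a fixed gene's rank is uniform when no gene is informative. These
sizes keep the full suite under a minute while leaving the Monte-Carlo
error of each check well below its decision margin.

## Known limitations

* The margin term's supervised signal scales with `gamma` times the number
  of labeled pairs; with very few labels and weak effects it is dominated
  by sampling noise, and no setting of `lambda` can fully compensate.
* Plug-in NMI on few labeled samples is biased; a shrinkage or
  permutation-corrected estimator would sharpen the second term and is a
  natural extension.
* Redundancy among selected genes is not addressed: two perfectly
  correlated markers both rank highly.
* The LSDF baseline is a documented reconstruction (see above), adequate
  as a comparison arm but not a reference implementation.
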