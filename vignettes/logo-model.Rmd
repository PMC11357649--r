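---
title: "The logo model: quantitative matrices for MHC class II binding-core prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The logo model: quantitative matrices for MHC class II binding-core prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logomhc)
```

## The model

MHC class II molecules present peptides to CD4+ T-cells through an
open-ended groove that accommodates a nine-residue binding core. The logo
model predicts binding of peptides to one allele, HLA-DRB1\*03:01 (a
peanut-allergy susceptibility allele), from the amino-acid composition of
that core alone. It is the quantitative cousin of a sequence logo: where a
logo draws letter stacks proportional to per-position frequencies, the logo
model turns the same frequencies into a scoring matrix.

The model is a pair of 20 × 9 quantitative matrices (QMs) — one trained on
nonamer binders, one on nonamer non-binders. Each is obtained by **mean
normalization** of the position-specific frequency matrix of its training
set: with $X_i$ the frequency of amino acid $i$ at a given core position,

$$X_i^{\mathrm{norm}} = \frac{X_i - X_{\mathrm{mean}}}{X_{\mathrm{max}} - X_{\mathrm{min}}},$$

where the mean, maximum and minimum are taken **globally over all 180
cells** of the frequency matrix. Two useful consequences follow. Because
each of the nine position columns sums to 1, the global mean frequency is
always $1/20$ — a cell is positive exactly when its residue is enriched over
a composition-blind draw. And because the denominator is a single global
range, coefficients are directly comparable across positions; with $N$
training nonamers and integer cell counts $c$, the map is affine,
$v = (c - N/20)/(c_{\max}-c_{\min})$, and exactly invertible
(`qm_counts()`), which is how the packaged matrices can be audited against
their stated training composition. Values are bounded in $[-1, 1]$ and the
180 cells sum to zero.

The wording "mean frequency for all positions" admits per-row and per-column
readings as well; we use the global reading because it is the only one whose
reconstructed integer counts agree with the published matrices (e.g. the p4
column of the binder matrix maps back to counts 14/14/14 for Ala/Arg/Leu, 5
for Asp, 2 for Glu, 1 for Asn under $N = 105$, extremes 27/0).

Scoring is linear. The **binding score** (BS) of a nonamer is the sum of its
nine residue coefficients in the binder QM; the **non-binding score** (NBS)
is the same sum under the non-binder QM. A nonamer is called a binder iff
BS > NBS (ties go to non-binder, the conservative reading of the rule). A
peptide of length $L \ge 9$ is decomposed into its $L-8$ overlapping nonamer
windows and called a binder iff **at least one** window is called a binder —
so binder calls are monotone under sequence extension, a property the test
suite asserts. Protein scans flag **strong binders**, windows with BS
strictly above 2 (configurable), as candidate T-cell epitopes for
immunotherapy.

## Parameters that matter

* `strong_threshold` (default 2, strict `>`): BS cutoff for the strong-binder
  flag in scans. Unitless, on the scale of a 9-term sum of coefficients in
  $[-1,1]$.
* `n_train = 105`, `n_splits = 10` in `split_pool()`: the published
  protocol's non-binder training-set size and number of random splits of the
  1123-nonamer pool (leaving 1018 test nonamers per split).
* `seed`: every stochastic operation (splits, synthetic sets, simulation)
  takes an explicit seed, default 1. The original splits were unseeded, so
  per-split metrics are reproducible only as ranges, not bit-for-bit.
* Rounding: matrices and reported scores use half-up rounding at 3 decimals
  (`round_half_up()`), the printed convention; all internal arithmetic keeps
  full precision. Because the packaged matrices are themselves 3-decimal
  values, scores computed from them are exact at 3 decimals either way.

## Evaluation protocol

`evaluate_qms()` mirrors the published validation, which is deliberately
asymmetric in granularity: positive test peptides may be of any length and
are classified at the peptide level (the ≥ 1-window rule), while negative
test peptides are nonamers classified individually. TP/FN therefore come
from peptide-level calls and TN/FP from nonamer-level calls; this inflates
TP relative to a per-window evaluation and should be kept in mind when
comparing to other predictors. Six statistics are computed — sensitivity,
specificity, accuracy, precision, Matthews' correlation coefficient and F1 —
and the non-binder QM among the ten split candidates is selected by highest
MCC (`select_best_qm()`, first occurrence on ties), MCC being the statistic
most robust to the ~7.7:1 class imbalance of the test sets. Metrics with a
zero denominator are reported as `NaN` with a warning rather than coerced to
0, so degenerate evaluations cannot silently inflate summaries.

Positive peptides shorter than nine residues cannot carry a binding core;
`classify_peptide()` errors on them in strict mode and skips them with a
warning in batch mode. (The published positive test set has 7814 peptides
but TP + FN = 7813; evaluating whatever peptides are classifiable, as we do,
is consistent with one unclassifiable record.)

## Degenerate inputs and tie-breaks

* A training set whose 180 frequency cells are all equal has an undefined
  normalization (zero range); this is an explicit error, never silent zeros.
* BS = NBS → non-binder.
* Windows containing non-standard residue codes (B, J, O, U, X, Z, `*`) are
  skipped with a warning and can never support a binder call: the matrices
  define only the 20 standard residues.
* Duplicate nonamers in a binder training set count with multiplicity;
  deduplication is applied only where the protocol states it — within the
  expanded non-binder pool (exact string equality, first occurrence kept)
  and against the positive set.
* Within one protein, repeated identical strong nonamers are reported once
  per occurrence with their own starts; `scan_fasta(distinct = TRUE)`
  collapses to one row per (record, nonamer) pair for Table-style summaries.

## What the synthetic generators emulate

`generate_binder_set()` plants anchor residues (default the canonical
HLA-DR layout: Phe at p1, Arg at p4, Phe at p6, Leu at p9, each with
probability 0.8) on a uniform 20-residue background; 0.8 gives an
anchor-to-background contrast comparable to the strongest published
coefficients while leaving realistic noise. `generate_nonbinder_set()`
draws uniform-background peptides of mixed length (default 9–25, the
typical span of class II ligand collections; the published non-binder set
held 154 such peptides). `implant_motif()` buries a chosen nonamer in a
random host so scans must recover it at a known coordinate.

These generators support parameter-recovery tests: matrices derived from
planted-anchor sets must place their four largest coefficients exactly at
the planted cells in ≥ 95% of 20 seeds, and background-only matrices must
stay strictly below the planted-anchor signal. What passing these tests
shows is that derivation, scoring and selection are self-consistent and
signal-sensitive at realistic sizes (500 training nonamers, pools of ~1100);
what they do not show is real-data performance — uniform backgrounds have no
residue-composition bias, no length/assay artefacts, and no correlation
between positions, all present in curated epitope data. Real-data claims
rest on the packaged published matrices and the printed validation counts.

## Problem sizes

The default suite works at the scale of the published protocol where that is
cheap (1123-element pools split 10 times; 500-nonamer synthetic training
sets over 20 seeds; 1000-nonamer scoring-oracle sweeps) and at smaller
rehearsal scale for the end-to-end selection pipeline (3 splits of a
synthetic pool). The full 28-allergen scan and the 7814-peptide validation
need third-party downloads (UniProt/GenBank accessions, supplementary
peptide lists) and run automatically when those files are placed under
`inst/extdata/external/`.

## Known limitations

* Single-allele model: the packaged matrices are specific to
  HLA-DRB1\*03:01; other alleles need their own training sets.
* Linear, position-independent scoring: no pairwise residue coupling, no
  flanking-region effects, no peptide-length term beyond the window rule.
* No affinity regression: BS orders candidates but is not an IC50 predictor;
  the strong-binder cutoff BS > 2 is a screening convention, and IC50 values
  attached to known epitopes are carried as annotation only.
* Entropy-weighted (Shannon) logos are out of scope; the model exports raw
  frequency and coefficient tables instead.
* `simulate()` requires a model fitted from explicit training peptides: a
  published matrix alone does not determine its training frequencies without
  the count range, so the default model cannot be simulated from.

## A worked pass through the pipeline

```{r pipeline}
model <- logo_model()          # the packaged published matrices
predict(model, c("ARQQWELQGDRRCQS", "EFLEQAFQVDDRQIV"))

scan <- scan_sequence(coef(model, "binder"), coef(model, "non-binder"),
                      "AAAAAFLILSGLILAAAAA")
scan[scan$strong, c("start", "nonamer", "bs")]

# refit from synthetic training data and select among split candidates
binders <- generate_binder_set(200, seed = 1)
pool <- expand_to_nonamer_pool(generate_nonbinder_set(60, seed = 2),
                               positives = binders)
splits <- split_pool(pool, n_train = 50, n_splits = 3, seed = 3)
fits <- lapply(splits, function(s)
  evaluate_qms(derive_qm(binders, "binder"), derive_qm(s$train, "non-binder"),
               generate_binder_set(100, seed = 4), s$test))
select_best_qm(fits)
round_half_up(fits[[select_best_qm(fits)]]$metrics, 3)
```
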