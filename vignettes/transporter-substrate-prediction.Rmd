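---
title: "Predicting transporter substrate specificity from sequence composition and profiles"
author: "transpec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transporter substrate specificity from sequence composition and profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpec)
```

## The problem and the model

Transporters with the same substrate often share little sequence
similarity, which defeats homology-based annotation. What does carry
signal is *composition*: substrate classes differ systematically in the
frequencies of a handful of residues and residue categories, and in the
evolutionary conservation patterns captured by PSI-BLAST profiles.
`transpec` turns these signals into a classifier in three stages:

1. **Encoding.** Each sequence becomes a fixed-length numeric vector
   under one of five schemes — AAC (20), DPC (400), PHC (11), AAI (49),
   PSSM (400) — or a concatenation of schemes (e.g. AAI+PSSM, 449).
2. **One-vs-rest SVMs.** One binary RBF-SVM per class, that class
   positive against the pooled remainder; a query takes the argmax of
   the eight decision scores.
3. **Cross-validated evaluation.** Stratified 5-fold CV with the
   Sn/Sp/Acc/coverage/MCC/AUC suite, averaged per fold and per class.

## Encoders and their conventions

All vectors use the fixed residue order `ACDEFGHIKLMNPQRSTVWY`; PSSM
columns are re-mapped to it at parse time so every downstream matrix is
order-consistent.

* **AAC** divides residue counts by the sequence length L, **DPC**
  divides consecutive-pair counts by L − 1 (the number of pairs); both
  therefore sum to 100 exactly, which the test suite asserts to 1e-9.
* **PHC** counts membership in 11 *overlapping* residue classes, so its
  components sum to no constant. The bundled class table reproduces a
  published table verbatim, in which the `polar` and `neutral` sets are
  printed identically — almost certainly a typo in the source. We ship
  the table as-printed (a one-time message flags the duplication) and
  load it from YAML so users can substitute a corrected `neutral` set;
  silently "fixing" it would make results incomparable with the
  original.
* **AAI** averages 49 residue-property scales over the sequence. The
  property table is configuration, not code: a TSV of 49 AAindex-derived
  scales (physical, chemical, energetic and conformational), each
  min–max normalized to [0, 1]. The exact 49-scale subset used by the
  original web service is not redistributable here, so the bundled file
  (`aaindex49_synthetic.tsv`) is a stand-in assembled from the public
  AAindex database; any 49 × 20 table with entries in [0, 1] can be
  supplied instead. No test depends on specific table values beyond the
  homopolymer identity (the vector of a homopolymer equals the residue's
  property column) and the row/range contract — so conclusions from the
  test suite are invariant to the particular subset.
* **PSSM** sums profile rows that share a query residue, giving a 20×20
  matrix flattened row-major to 400 components, divides by L, and then
  min–max scales the vector to [0, 1]. Two genuinely open conventions
  are resolved as follows and kept switchable:
  * scaling is **per vector**, not per dataset (`scale = FALSE` returns
    the unscaled vector for callers who prefer a global scheme);
  * an all-equal vector (e.g. an all-zero profile) has no min–max image,
    and is mapped to the constant 0.5 — the midpoint, chosen so the
    encoder is total and the degenerate case is order-free.

## The SVM layer

The original models were trained with SVM-Light, whose `-j` flag
weights errors on positive examples; we expose the same quantity as
`cost_factor`, implemented as a class weight on the shared
regularization constant C (default 1), with the RBF width `gamma` as
the second tunable. `grid_search()` scores each (γ, j) pair on the
default grids (γ: 7 log-spaced points over 1e-5…10; j: 1…4) by mean
stratified k-fold CV accuracy, breaking ties deterministically toward
smaller γ, then smaller j — preferring the smoother model. Feature
vectors enter the SVM exactly as encoded (`scale = FALSE` internally):
the encoders already put components on bounded scales, and hidden
re-normalization would break the contract that the model consumes
encoder output as-is.

How the eight binary scores combine into a single call is *not* part of
the original method description, which reports only per-class binary
metrics; the argmax fusion with the fixed class order
(amino_acid, anion, cation, electron, protein_mrna, sugar, other,
non_transporter) as tie-break is this package's documented plumbing
choice, as is the transporter flag (non-transporter score below 0).
libsvm orients decision values by the first label it happens to see, so
the binary wrapper normalizes the sign at training time; without that,
scores would flip orientation unpredictably between fits.

## Evaluation conventions

* Scores exactly at the confusion threshold count as **positive**.
* Sensitivity and coverage are the same number by definition and are
  reported under both names.
* MCC with any zero factor in its denominator is defined as 0, the
  random-prediction value.
* The ROC curve sweeps all distinct thresholds and integrates by the
  trapezoidal rule; this equals the pairwise rank statistic
  P(score⁺ > score⁻) + ½P(tie), which the tests verify against an
  O(n²) oracle and against pROC.
* Folds are **stratified** by class and seeded. The smallest practical
  classes make unstratified "equally sized random partitions" unstable,
  so stratification is the default reading.
* Per-fold metrics are **arithmetically averaged** across folds;
  pooled-count aggregation is available (`average = "pooled"`) as a
  diagnostic, and the same choice applies to AUC (per-fold averaged by
  default).

## What the synthetic generator emulates — and what it does not

`make_class_profiles()` starts from Swiss-Prot-like background residue
frequencies and gives each of the eight classes a signature triple of
residues drawn cyclically from D, E, K, F, G, I, L, S — the residues
with the highest across-class compositional variance in real
transporter data — adding `separation/3` probability mass to each
signature residue and renormalizing. `separation = 0` yields identical
classes (the null model); larger values move the profiles apart
monotonically in L1. Sequence lengths are log-normal around 200
residues (dispersion 0.25, floor 30), typical of transporter chains.
Profile construction is deterministic given its arguments; all sampling
randomness is governed by the single dataset seed. PSSM fixtures give
the true residue's column a score near +conservation·10 and all others
near −conservation·10 plus integer-rounded Gaussian noise, and are
written in the full 40-column PSI-BLAST ASCII dialect so the parser is
exercised against the real format.

The generator emulates *compositional* class structure and
*conservation-shaped* profiles only. It does not simulate domain
architecture, transmembrane topology, phylogenetic correlation between
sequences, or realistic substitution patterns — so passing recovery
tests show that the pipeline detects compositional signal at realistic
noise levels, not that it reaches any particular accuracy on real
transporter data, whose class boundaries are far subtler.

## Problem sizes and defaults

The study-condition defaults used throughout the tests and the
acceptance script: 8 classes × 30 sequences at separation 0.15 for the
recovery experiment (and the same at separation 0 for the null check);
AAC features with γ = 0.01, C = 1, j = 1; stratified 5-fold CV;
determinism checked on 8 × 15 sequences with AAI+PSSM features. With a
class-imbalance baseline of 7/8 = 87.5% accuracy, the recovery
criterion (every class above 90%) requires genuine signal, and the null
criterion bounds each class's accuracy within three binomial standard
deviations of the baseline.

## Known limitations

* The AAI property table is an AAindex-derived stand-in for the
  original 49-scale subset (see above); swap in your own TSV for exact
  comparability with other implementations.
* PSSM generation itself (PSI-BLAST, three iterations, e-value 1e-3,
  BLOSUM62, against UniRef90 or Swiss-Prot) is external: the package
  parses and writes the ASCII format but never invokes the search.
* Probability calibration of decision scores, and abstention rules for
  ambiguous argmax margins, are out of scope.
* Grid search refits one SVM per fold per grid point; with the default
  28-point grid on large feature spaces (DPC, hybrids) this is the slow
  path — tune on a subset or narrow the grids if it matters.
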