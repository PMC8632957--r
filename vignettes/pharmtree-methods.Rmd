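---
title: "Pharmacological subtype trees: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacological subtype trees: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmtree)
```

## The model

`pharmtree` re-classifies tumor cell lines by therapeutic response rather
than tissue of origin. The input is a screen: a cell × drug matrix of
natural-log IC50 values (ln µM), a per-drug maximum screened concentration
(the assay ceiling, µM), and optionally per-cell histology labels plus
gene × cell alteration (0/1) and expression matrices.

Three layers are built on top of it:

1. **Per-drug subtype trees.** Cells are labeled *sensitive* when
   `ln IC50 < ln(ceiling)` and *resistant* otherwise (the ceiling itself is
   resistant — the sensitive definition is a strict inequality). The
   assayed cells are then recursively bisected: at each node the cells are
   sorted by ln-IC50, every division leaving ≥ 3 cells per side is scored
   by a two-sided Mann-Whitney U test between the blocks, and the smallest
   p wins if below 0.05. Terminal conditions: node size < 6, homogeneous
   labels, or no significant division. Leaves in left-first order are the
   subtypes C1..Ck, most sensitive first.
2. **Concordance similarity.** Within one drug, a cell pair scores +1
   (share a leaf, both sensitive), −1 (share a leaf, both resistant) or 0.
   `Cellsim` averages |score| over the drugs in which both cells were
   assayed; `Drugsim` is a Tanimoto-style ratio of two drugs' score
   matrices over their shared cells, which is 1 for identical nonzero
   matrices and can be negative when a pair is concordant-sensitive under
   one drug and concordant-resistant under the other (kept unclamped).
3. **Gene–drug connections.** Per drug, mixed leaves are excluded and the
   remaining cells pooled by leaf class. Alterations: chi-squared on the
   2 × K altered × leaf table. Expression: pooled equal-variance t test,
   with a |PCC| > 0.3 confidence filter between ln-IC50 and expression in
   the sensitive pool, sign-consistent with the direction label (a
   *sensitive* connection means expression rises as ln-IC50 falls, i.e.
   negative PCC). BH adjustment is applied per drug within a modality and
   records with q < 0.1 are retained, forming a bipartite gene–drug
   network.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| split threshold `alpha` | 0.05 | raw Mann-Whitney p needed to accept a division; no multiplicity correction over the `n_s − 5` candidates (the smallest p is selected directly) |
| minimum node size | 6 | below it a node is a leaf; combined with the ≥ 3-cells-per-side rule it gives exactly `n_s − 5` divisions |
| FDR threshold | 0.1 (BH q) | connection retention |
| PCC threshold | 0.3 | expression confidence filter, applied as \|PCC\| with direction-consistent sign |
| ceiling `max_conc` | per drug, µM | sensitivity cutoff; screens typically use 0.08–20 µM |
| min altered cells | 3 | genomic tests on sparser genes are skipped (degenerate tables) |
| min pool size | 3 | expression tests need ≥ 3 cells per class pool |

## A structural property of the split statistic

The Mann-Whitney test is rank-based, and every candidate division is an
ordered cut of cells already sorted by ln-IC50 — so for distinct values
each cut separates the blocks *completely*, the U statistic is always at
its extreme, and the p-value depends only on the block sizes. The
minimum-p division is therefore always the most balanced admissible one,
regardless of where gaps in ln-IC50 actually lie. Consequences:

* The tree is a **balanced bisection** refined by the stopping rules; leaf
  counts grow roughly like log2 of cohort size (2–9 leaves for cohorts of
  tens to hundreds of cells), and where the sensitive/resistant boundary
  falls determines much of the final shape.
* Planted response groups are recovered **only when their boundaries
  coincide with bisection cuts** (e.g. two equal groups). On three planted
  groups of random sizes the leaf-vs-truth adjusted Rand index sits near
  0.5 and essentially never reaches 0.9 — the corresponding acceptance
  test is expected to stay red, documenting the property rather than
  hiding it. A value-based statistic (e.g. a t test) would not have this
  degeneracy, but would be a different method.
* Small exchanges: the exact two-sided minimum p at a 3-vs-3 division is
  `2/C(6,3) = 0.1 ≥ 0.05`, so 6–7-cell nodes never split under the exact
  route; 8-cell nodes split 4|4 (`p = 2/70 ≈ 0.029`).

## Numerical choices

* **Mann-Whitney routes.** The exact permutation distribution of the rank
  sum is computed by a shift/convolution dynamic program that handles
  midrank ties exactly; the two-sided p is `min(1, 2·min(P(W≤w),
  P(W≥w)))`. The asymptotic route uses the tie-corrected normal
  approximation *without* continuity correction. The default (`"auto"`)
  uses the exact route when both blocks have ≤ 8 cells; both routes are
  switchable per call. All-tied inputs give p = 1.
* **Tie-breaks.** Cells tied on ln-IC50 are ordered by cell ID before
  division enumeration; divisions tied on the minimal p resolve to the
  most balanced, then the smaller left size. Together with deterministic
  serialization this makes identical inputs produce byte-identical trees.
* **Chi-squared** is Pearson's statistic without Yates correction and with
  no exact-test fallback for small expected counts (the named test is used
  as named; genes altered in < 3 analyzed cells are skipped instead).
* **Direction labels** require both a sensitive-class and a
  resistant-class pool; drugs whose non-mixed leaves are all one class
  yield no testable records.
* **Undefined similarities** (cell pairs never co-assayed; drug pairs with
  an all-zero denominator) are kept as NA / flagged zeros rather than
  dropped, so downstream clustering stays total; `similarity_to_distance`
  imputes NA to 0 before taking Euclidean row distances.
* **Clustering** is agglomerative with Ward linkage (`ward.D2`) on those
  row distances, cut by requested cluster count; absolute-height cuts are
  available but linkage- and scale-dependent, so counts are the portable
  interface.

## The synthetic cohort

`generate_cohort()` states a small world: per drug, each cell belongs to
one of a few ordered response groups; ln-IC50 is normal around the group
mean (defaults −6/−1/+4 ln-units, sd 0.5, ceiling 1 µM = ln 0, i.e. two
clearly sensitive groups and one clearly resistant); alterations are
Bernoulli with group-specific frequencies; expression of effect genes is
`slope × ln-IC50 + noise`; histology labels are sampled per group of the
first drug (uniform mixing by default, so histology carries no signal
unless asked to). Everything is reproducible from one seed.

What it does *not* emulate: real screens' missingness patterns, dose-range
heterogeneity between drugs, mutation co-occurrence structure, histology
frequencies, or IC50 curve-fitting error. A green test on this world
establishes that the machinery implements the stated statistics — not that
those statistics recover biology from a real screen.

## Known limitations

* The balance degeneracy above: subtype boundaries are size-driven, not
  gap-driven.
* Chi-squared p-values on small or sparse leaves are approximate; the
  min-altered guard avoids the worst tables but no exact fallback is
  attempted.
* The `q` denominator in `Cellsim` counts co-assayed drugs only; cells
  sharing few drugs get noisy similarities with no shrinkage.
* Absolute dendrogram-height cuts are not portable across linkage choices;
  published height-based cluster counts can only be approximated by
  count-based cuts.
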