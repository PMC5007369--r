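---
title: "Quantifying protein abundance and S-nitrosylation from dual-channel gel sets"
author: "snoRoR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein abundance and S-nitrosylation from dual-channel gel sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoRoR)
```

## The measurement model

Saturation thiol labeling couples a fluorescent maleimide dye to every
reduced cysteine of a protein sample, so a 2D-gel spot's fluorescence
volume is proportional to the amount of protein times its reactive-thiol
content.  S-nitrosylation (S-NO) of a cysteine blocks the dye, which is
what makes the modification quantifiable by a *dual-channel* design: each
sample is split into an ascorbate-treated fraction (`Asc+`, S-NO bonds
reduced, all thiols react — a measure of protein abundance) and a
neocuproine-stabilized fraction (`Asc-`, S-NO preserved, modified thiols
silent).  Both fractions are run on their own gels, giving four gels per
matched pair of subjects across the two study groups (healthy controls
`NH` and heart-failure patients `HF`).

Three per-spot quantities follow from normalized spot volumes:

* $\Delta\mathrm{abundance} = \mathrm{Asc^+\,HF} / \mathrm{Asc^+\,NH}$,
* $\Delta\mathrm{S\text{-}NO} = \mathrm{Asc^-\,HF} / \mathrm{Asc^-\,NH}$,
* the **ratio of ratios**
  $\mathrm{RoR} = \Delta\mathrm{S\text{-}NO} / \Delta\mathrm{abundance}$,

the last of which cancels the abundance change out of the Asc− signal and
isolates the occupancy change.  Because modification *quenches* the dye, a
negative RoR (in the signed fold convention: $r \ge 1 \mapsto r$,
$r < 1 \mapsto -1/r$) means *increased* S-NO, and vice versa.  All ratios
are reported in that fold convention; `linear_to_fold()` and
`fold_to_linear()` convert losslessly.

### Group summaries are geometric means

Group ratios are formed from means of log2 volumes and back-transformed
(`group_ratio()`), i.e. they are ratios of geometric means.  The original
acquisition software's convention (arithmetic vs geometric) is not
documented; the geometric mean was chosen because the downstream tests
operate on log2 volumes, and ratios of geometric means compose exactly
with those tests — the per-spot log fold is literally the difference of
the group means being tested.  RoR is computed from the two group-level
ratios rather than per-subject pairs, matching how the published spot
table composes (its printed RoR equals the printed S-NO fold divided by
the printed abundance fold in fold arithmetic, which
`verify_table_fixture()` checks row by row under interval arithmetic that
accounts for the two-decimal rounding of the printed inputs).

## Normalization

Gel-to-gel differences in protein load and scanner gain scale every spot
of a gel by a common factor.  Under the assumption that most spots do not
change, that factor is estimable from the mean log spot-ratio of a gel to
a reference gel: `compute_bias_factor()` returns
$\exp(-\overline{\ln(g/r)})$ over spots positive in both gels, and
`normalize_gelset()` applies one gain per gel so that every mean
log-ratio to the reference becomes zero (to within 1e-9; the tests assert
this for per-gel log-biases up to SD 0.7).  The reference gel is the one
with the most detected (nonzero) spots, with ties broken by the highest
median Spearman correlation to the other gels and then lexicographically
— a deterministic restatement of "the gel that best represents the
experiment".  Whether the original software estimates the bias on all
spots or on a robust subset is unknowable from its description, so a
trimmed-mean option (`trim`) covers both readings; the default is the
plain mean (trim 0).  Zero volumes are excluded from bias estimation
(log undefined) but still rescaled.

## Differential statistics

Per spot and channel, `differential_table()` computes log2 group
means/SDs, the signed fold, a Welch unequal-variance t-test with
Welch–Satterthwaite degrees of freedom, and Benjamini–Hochberg adjusted
q-values; the multiple-testing family is the set of spots with a defined
test (spots with an all-zero group are reported NA and excluded from the
family, since they carry no test).  The CoV is computed on raw-scale
volumes — a CoV of log2 values is ill-defined near zero — and this is
flagged as a potential deviation from the undocumented original.

Two named presets mirror the two selection rules used in the study
design: `discovery` (|fold| ≥ 1.5, BH q < 0.05) feeding spot
identification, and `mars_input` (|fold| ≥ 1.5, BH q < 0.001) feeding the
classifier.  The source description is internally inconsistent about
which rule fed the classifier (p < 0.001 in the methods, p < 0.05 in the
figure legends), so both are exposed and neither is asserted as
canonical.  For S-NO selection (`select_sno_spots()`) the fold criterion
is applied to the RoR — so a pure abundance change, which propagates to
the Asc− channel, does not masquerade as an S-NO change — while the p
criterion comes from the Asc− channel test.  `venn_classify()` partitions
the selected spots into abundance-only / S-NO-only / both.

## MARS classification

`mars_fit()` implements multivariate adaptive regression splines from
scratch: a greedy forward pass adds reflected hinge pairs
$\{\max(0, x-k), \max(0, k-x)\}$ with knots at observed data values,
choosing at each step the (parent, variable, knot) candidate that most
reduces the least-squares RSS; a backward pass then deletes the least
useful basis one at a time and returns the subset minimizing
$\mathrm{GCV} = (\mathrm{RSS}/n) / (1 - C(M)/n)^2$ with
$C(M) = \#\text{coefficients} + d\cdot\#\text{knots}$.  Choices made
where the description was open:

* "1 max interaction term" is read as degree 1, i.e. an additive model;
  `max_interaction` exposes higher degrees (candidate bases are then
  products of an existing basis with a new hinge).
* The GCV knot penalty defaults to $d = 2$, the standard value for
  additive MARS; no penalty is named in the source.
* Knot candidates are all observed values of a variable (no minspan
  thinning) — appropriate at the cohort sizes involved (n = 60).
* Classification is least-squares regression on 0/1 labels with a 0.5
  score threshold (classic MARS classification); no logistic link.
* Ties in the backward deletion and degenerate (rank-deficient) bases are
  handled by dropping aliased coefficients to zero.

Variable importance is the increase in GCV when all bases of a variable
are removed (coefficients refit), rescaled so the top variable scores
100.  `mars_validate()` offers the two anti-overfitting schemes of the
study: class-stratified 10-fold cross-validation with out-of-fold scores
pooled into one test ROC, and a stratified 80/20 split.  Stratification
and pooling are implementation choices (the source states neither); both
are controlled by a single seed.  `roc_auc()` computes the AUC as the
Mann–Whitney concordance probability with ties half-counted, which the
tests verify against a brute-force pairwise oracle and an independent ROC
implementation.

Two empirical caveats, established by the test suite rather than asserted:
on pure-noise features the greedy forward pass (which screens hundreds of
candidate knots per step) occasionally retains one or two bases past the
penalty-2 GCV — the null-pruning property therefore holds in the median
over replicates, not surely per draw.  And under mild noise
(SD 0.01, n = 200) the selected knot concentrates within about twice the
noise SD of the true knot rather than always inside the two bracketing
data values; noise-free hinge targets are recovered exactly.

## The synthetic gel-set generator

Real gel images for this design are not publicly deposited, so every
downstream stage is exercised against `simulate_gelset()`, whose defaults
state the study conditions: 30 subjects per group, 635 spots, technical
CoV 0.09 (the replicate reproducibility reported for the labeling
method), baseline spot intensities log-uniform over three orders of
magnitude (the imager is linear over four).  Each spot's latent
biological volume is shared by a subject's paired Asc+/Asc− fractions
(split-sample design); channels receive independent per-gel biases
$\exp N(0, \sigma_b)$ (default $\sigma_b = 0.2$, a plausible loading
spread) and multiplicative log-normal noise with
$\sigma^2 = \ln(1 + \mathrm{CoV}^2)$ and unit mean, so volumes stay
positive and the sample CoV converges to the configured value.  Quenching
is linear in S-NO occupancy (fluorescence proportional to the unmodified
thiol fraction) — the source states the direction of the effect, not its
functional form, and linearity is the saturation-labeling reading.
Abundance effects multiply affected HF spots by a configurable fold with
a random up/down direction; occupancy effects shift affected HF spots by
a signed amount from a baseline occupancy of 0.3.  Between-subject
biological variance is exposed (`biological_cov`) but defaults to 0
because the source quantifies only technical variance; a missing-spot
fraction (default 0) exercises degenerate-input handling.

What passing tests on this generator do show: the normalization exactly
inverts multiplicative bias; null data yield uniform p-values and a
controlled discovery FDR; planted 2-fold abundance effects and 0.3
occupancy shifts at n = 30/group are recovered with sensitivity above 0.8
and correct RoR direction calls.  What they do not show: robustness to
spatially correlated gel artifacts, spot-boundary errors, saturation
clipping, or non-log-normal biological variation — none of which the
generator emulates.

## Problem sizes and numerical choices

The simulation-based tests use 200 null replicates at 30 + 30 subjects ×
500 spots for FDR calibration, 50 replicates for effect recovery, and
100-replicate knot-recovery sweeps; these sizes put Monte-Carlo error
well below every asserted margin while keeping the default suite fast.
Tolerances: normalization postcondition 1e-9; fold round-trips 1e-12;
oracle agreement for Welch/BH/AUC 1e-10 or exact; fixture verification
uses interval arithmetic from the two-decimal rounding of printed inputs
(a flat epsilon would either over- or under-constrain rows whose inputs
sit near a rounding boundary).  Display rounding is half-even to two
decimals.

## Limitations

The packaged spot table carries the published per-spot folds, so the
arithmetic of the RoR statistic is verifiable exactly, but cohort-level
counts and the published AUCs derive from raw gels that were never
deposited and are mirrored only qualitatively on synthetic data.  The
`NH` subcolumn of the packaged table (a within-NH Asc−/Asc+ ratio by its
heading) does not enter the printed RoR and is carried unasserted.  MARS
feature panels reported for the real cohort cannot be reproduced and are
not targeted.
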