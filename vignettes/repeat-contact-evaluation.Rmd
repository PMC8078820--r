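---
title: "Evaluating contact predictions and model quality on tandem-repeat proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating contact predictions and model quality on tandem-repeat proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatcontacts)
```

## The problem

Tandem-repeat proteins — solenoids, closed rings (propellers, TIM-like
barrels), and "beads on a string" architectures — are a long-standing
difficulty for residue-residue contact predictors. Their repeated units are
near-identical in sequence, so coevolution signals between *equivalent
positions of different units* are confounded with signals within a unit:
predictors tend to place contacts on diagonals at multiples of the repeat
period, many of which are wrong. Evaluating a predictor on these proteins
therefore needs more than a single precision number: contacts must be split
into intra-unit and inter-unit classes, precision must be tracked against
alignment depth, and the periodic false-positive pattern must be
quantified. This package implements that evaluation pipeline, plus a
random-forest regressor that estimates the quality (TM-score) of 3D models
built from predicted contacts.

## Contact definition and precision

A *contact* is a residue pair whose representative atoms lie at most 8 Å
apart with sequence separation greater than five residues
(`true_contacts()`, defaults `cutoff = 8`, `separation_min = 6`). The
distance boundary is inclusive. The representative atom is the β-carbon;
glycine has none, so its α-carbon substitutes — the field-standard
fallback, chosen here explicitly since heavy-atom definitions are out of
scope. Residues missing both atoms (or missing entirely from the
coordinates) are *masked*: they keep their sequence index, so unit spans
remain valid, but never participate in pairs. On messy PDB input the first
alternate location is kept and insertion-coded residues are skipped with a
warning — a deterministic, logged policy rather than a guess at the
depositor's intent.

Precision is *positive predictive value* (PPV): correct predictions over
selected predictions, computed at the top `round(1.5 * L)` scored pairs
(`top_k_l()`), where `L` is the evaluated region length. Rounding is
half-away-from-zero, and rank ties break lexicographically (lower `i`, then
lower `j`), so reruns are reproducible. A selection of size zero yields an
`NA` PPV, never 0 — absence of evidence is not failure.

Distance-distribution predictors are converted to contact scores by summing
the probability of all distance bins whose upper edge is ≤ 8 Å
(`distogram_to_contacts()`). The default binning is 36 half-Å bins from 2
to 20 Å plus a terminal beyond-20 bin. The cutoff must coincide with a bin
edge; the conversion refuses to split a bin rather than silently
interpolate, because the summation rule is defined on whole bins.

## Intra/inter-unit stratification

Unit spans follow the RepeatsDB convention: 1-based, inclusive, ordered and
non-overlapping within a region. A contact is *intra-unit* when both
residues share a unit, *inter-unit* when they occupy two different units,
and *unclassified* when either residue falls in a linker or insertion.
Unclassified pairs are excluded from the stratified analysis: the two
stratified PPVs are then well-defined fractions, and the three counts
always partition the contact total (a property the tests assert on every
fixture).

The stratified PPV (`stratified_ppv()`) uses *matched counts*: if the
structure has `n_intra` true intra-unit and `n_inter` true inter-unit
contacts, exactly the `n_intra` top-scoring predicted intra pairs and the
`n_inter` top-scoring predicted inter pairs are selected and scored. This
makes the two strata comparable at equal support. A stratum with zero true
contacts reports `NA`.

Representative single- and double-unit fragments (`extract_unit_windows()`)
are formalized as the `k` consecutive units whose combined span contains
the fewest non-unit residues, ties resolved by earliest sequence position —
the selection goal ("minimise insertions") stated as a deterministic rule.

## Neff and the precision curve

Alignment depth is summarized by an effective-sequence-number proxy
(`compute_neff()`): each sequence is down-weighted by the number of
sequences within 80% identity of it (including itself), and the weight sum
is divided by √L. Published Neff values come from aligner-specific
formulas that are not reproducible without the aligner; this proxy is
documented, monotone in alignment diversity, and sufficient for
*stratifying* results by depth, which is the only use the pipeline makes of
it. Absolute values are not comparable to external tools.

The precision-versus-Neff curve (`neff_precision_curve()`) sorts proteins
by Neff and applies a running mean over a window of 50 records. The window
is centred and truncated at the ends; centring was an open choice, taken
because it keeps the curve unbiased in the interior where most points lie.

## The periodic-artefact score

The characteristic failure mode on repeats is false positives on diagonals
at the repeat period. `periodicity_artefact_score()` quantifies it as the
fraction of false positives, within the top-1.5L selection, whose sequence
separation lies within ±1 residue (configurable) of a positive multiple of
the *mean unit length*. The mean was preferred over per-adjacent-unit
offsets because annotated unit lengths within a region vary by a few
residues, and the mean period plus a tolerance captures the diagonals
without tuning per protein. A selection with no false positives scores 0.

## Model quality assessment

`qa_forest()` fits a random forest regressing a model's true TM-score on
nine features: the global Pcons consensus score, the global QMeanDisCo
score, four summaries of the per-residue QMeanDisCo profile (mean, median,
minimum, fraction ≥ 0.6), the modelled length, its logarithm, and the
alignment Neff. The forest uses 240 trees with maximum depth 60 — the
hyperparameters this analysis standardizes on — grown single-threaded under
a fixed seed, so training is bit-reproducible. `ranger` provides the
forest because it exposes the depth cap directly. Predictions are clipped
to [0, 1].

Only three of the nine features are identified as dominant in the source
analysis (global Pcons, local QMeanDisCo, length); the full nine-feature
schema is this package's documented operationalization, configurable in
principle but fixed by default so results are comparable across runs.

`qa_cross_validate()` performs seeded, unstratified 5-fold cross-validation
(the simplest reproducible split; labels are continuous, so class
stratification does not apply) and reports per-fold and mean MAE, Pearson
r, and *accuracy at 0.5*: the fraction of held-out models whose predicted
and true correct/incorrect calls agree, where a model is "correct" when its
TM-score is at least 0.5 (`call_model_correct()`, inclusive threshold).
"Accuracy" is undefined for a regression; this operationalization ties it
to the same fold-recognition threshold the modelling pipeline uses, so both
reported metrics have a concrete meaning.

## The synthetic generator

Real benchmarks for this analysis require curated repeat databases,
large-scale alignments, and external predictors. The package instead ships
a generator whose outputs have the *statistical structure* the analysis
assumes, so every stage is exercised end to end:

* `make_structure()` places one representative atom per residue on a
  parametric scaffold. The unit template is a hairpin of two antiparallel
  strands (3.4 Å per residue, 4.8 Å between strands), which produces
  realistic intra-unit contact ladders. Stacked geometries
  (`alpha_solenoid`, 30-residue units; `beta_solenoid`, 12-residue units —
  β units deliberately much shorter, as in real solenoids) repeat the
  template along an axis at a 7.5 Å rise with optional twist, giving
  inter-unit contacts between equivalent positions of adjacent units.
  `closed_ring` arranges units around a circle whose radius makes adjacent
  units 7.5 Å apart, so the last unit contacts the first. `beads_on_string`
  separates unit blobs by ≥ 20 Å, making inter-unit contacts geometrically
  impossible. Insertions are placed far from the scaffold and form no
  contacts. Contact densities are consequences of the geometry, not painted
  onto a matrix — the coordinate-to-contact machinery is tested by the same
  fixtures. Atom clashes under 2 Å trigger seeded jitter with at most 10
  retries.

* `make_prediction()` plants a known precision: the top `1.5 L` band
  contains `round(precision · k)` true contacts, and of its false
  positives a fraction `artefact_rate` sits at separations within ±1 of a
  multiple of the mean unit length, the remainder at explicitly
  non-periodic separations. Scores are drawn from Beta-shaped high/low
  bands controlled by `score_sharpness`. Because the planted rates are
  exact up to rounding, recovery tests have sharp expectations.

* `make_qa_table()` draws QA features and sets the label to
  `clip(0.1 + 0.3·pcons + 0.3·qmean_local_mean + 0.2·sigmoid(length) +
  N(0, 0.05))` by default. Two variants exist: the default, where the
  non-signal features are noisy correlates of the signal (as real QA
  summaries are), and a "three-signal" variant
  (`independent_distractors = TRUE`) where distractors are independent, so
  the planted signal is identifiable from the importance ranking. One
  caveat is intrinsic: `log_length` is the exact log of `length`, so the
  two features induce identical split orderings and a tree ensemble splits
  their importance credit roughly evenly — no importance measure can
  separate them, even in principle. Identifiability checks therefore count
  either one as recovering the planted length signal.

What the generator does **not** emulate: real side-chain packing, sequence-
dependent contact propensities, alignment-quality coupling between Neff and
prediction accuracy, and the error correlations of any particular
predictor. Passing tests show the *pipeline arithmetic* is right under
known ground truth; they do not certify any predictor's real-world
performance.

## Problem sizes and numerical choices

The shipped tests run the contact oracle on 500 random structures of up to
60 residues, precision and artefact recovery on 100 seeded predictions per
planted rate over six-unit solenoids (L = 180), and the QA experiments at
n = 800 (noisy), n = 500 (noise-free) and 50 seeded importance runs at
n = 400 — sizes at which binomial standard errors make the stated
tolerances meaningful. Probability vectors must sum to 1 within 1e-6;
distance comparisons use exact floating-point inequalities (the 8.0 Å
boundary is a designed, inclusive comparison); all Monte-Carlo checks fix
their seeds.

## Known limitations

* Contacts use a single representative atom; all-atom or heavy-atom
  definitions, mmCIF input, and NMR multi-model handling are out of scope.
* The Neff proxy is for stratification only.
* The artefact score keys on the mean unit period; strongly
  variable-length units (large internal insertions) blur the diagonals and
  lower its sensitivity.
* Whether contacts between a unit and a linker should count as inter-unit
  is genuinely ambiguous in the field's usage; this package excludes them,
  which keeps both stratified PPVs well-defined.
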