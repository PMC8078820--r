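# repeatcontacts

Evaluation toolkit for residue–residue contact prediction on
tandem-repeat (solenoid) proteins, with a random-forest model-quality
estimator.

Contact predictors behave differently on repeat proteins than on globular
ones: the near-identical sequence of successive units confounds
coevolution signals, so predictions are strong *within* a unit but weak
*between* units, and false positives pile up on diagonals at multiples of
the repeat period. Anyone benchmarking a contact predictor or a model
quality-assessment method on this protein class needs the statistics this
package computes:

* **Ground-truth contacts** from coordinates: a pair is in contact when
  the Cβ atoms (Cα for glycine) are ≤ 8 Å apart and more than five
  residues apart in sequence.
* **Precision (PPV)** at the top `1.5·L` scored pairs,
  `PPV = TP / (TP + FP)`, from CASP-RR contact lists or from distograms
  (per-pair distance distributions, converted by summing the probability
  of all bins at or below 8 Å).
* **Intra/inter-unit stratified PPV** with *matched counts*: if the
  structure holds `n_intra` intra-unit and `n_inter` inter-unit contacts,
  exactly that many top predictions are selected in each stratum.
* **Periodic-artefact score**: the fraction of false positives in the
  selection whose separation is within ±1 residue of a multiple of the
  mean unit length.
* **Neff-stratified precision curves**: a centred running average
  (window 50) of PPV against an effective-sequence-number proxy.
* **TM-score regression**: a 240-tree, depth-60 random forest over nine
  QA features (Pcons, QMeanDisCo summaries, length, log-length, Neff),
  with seeded 5-fold cross-validation reporting MAE, Pearson r, and
  accuracy at the TM ≥ 0.5 correctness threshold.

A synthetic generator produces solenoid, closed-ring and beads-on-a-string
structures with exact unit annotations, predictions with planted precision
and artefact rates, and labelled QA tables — so the entire pipeline is
testable without external databases or predictors.

## Worked example

```r
library(repeatcontacts)

# a six-unit alpha-solenoid, 30 residues per unit
st <- make_structure(solenoid_params("alpha_solenoid", n_units = 6, seed = 7))
truth <- true_contacts(st$residues)
truth
#> contact_map: L = 180, 366 contacts (separation >= 6), 0 masked residues
count_true_by_class(truth, st$annotation)
#>        n_intra        n_inter n_unclassified
#>            216            150              0

# a prediction with 70% planted precision; 30% of its errors periodic
ps <- make_prediction(truth, st$annotation,
                      prediction_noise(precision = 0.7, artefact_rate = 0.3,
                                       seed = 8))
ppv(top_k_l(ps, truth = truth), truth, "syn_alpha_solenoid_7")
#> ppv_result 'syn_alpha_solenoid_7': 189/270 correct, PPV = 0.700
stratified_ppv(ps, truth, st$annotation)
#> stratified_ppv: intra 0.926 (n=216), inter 0.493 (n=150), inter fraction 0.410
periodicity_artefact_score(ps, truth, st$annotation)
#> [1] 0.2962963
```

The top-270 selection (1.5 × 180) recovers the planted 70% precision
exactly; intra-unit precision (0.926) far exceeds inter-unit precision
(0.493) at matched counts — the hallmark behaviour on repeat proteins —
and 29.6% of the false positives sit on period diagonals, matching the
planted 30% artefact rate.

```r
# model quality assessment on the documented synthetic QA generator
tab <- make_qa_table(800, noise_sd = 0.05, seed = 7)
qa_cross_validate(tab, seed = 7)
#> 5-fold cross-validation (seed 7):
#>  fold   n     mae pearson_r accuracy
#>     1 160 0.04974    0.9080   0.8875
#>     2 160 0.05010    0.9084   0.8438
#>     3 160 0.04745    0.9172   0.8688
#>     4 160 0.04260    0.9134   0.9062
#>     5 160 0.04911    0.9194   0.8375
#> mean: MAE 0.0478, Pearson r 0.9133, accuracy@0.5 86.9%
```

Held-out TM-scores are predicted to within 0.048 on average, and 86.9% of
models get the right correct/incorrect call at the TM 0.5 threshold.
`feature_importance()` ranks the planted signal features first.

A command-line front end over the same functions is installed at
`inst/scripts/repeat-eval.R` with `simulate`, `evaluate` and `qa`
subcommands.

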