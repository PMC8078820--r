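Package: repeatcontacts
Title: Contact-Prediction Evaluation and Model Quality Assessment for Tandem-Repeat Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation toolkit for residue-residue contact prediction on
    tandem-repeat (solenoid) proteins. Derives ground-truth contact maps from
    coordinates under the C-beta 8 Angstrom / sequence-separation > 5
    definition, ingests CASP-RR contact lists and binned distance
    distributions (distograms), stratifies precision into intra- and
    inter-unit contacts using repeat-unit annotations, quantifies periodic
    false-positive artefacts characteristic of coevolution methods on
    repeats, computes Neff-stratified precision curves, and fits a
    random-forest regressor of model TM-score from quality-assessment
    features. Includes a synthetic solenoid generator so the whole pipeline
    is testable without external databases or predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ranger,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
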