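Package: nergen
Title: Generalization Analysis for Biomedical Named Entity Recognition
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how biomedical named entity recognition
    (BioNER) systems generalize beyond memorized training mentions.  Reads
    PubTator and CoNLL corpora, partitions test mentions into memorization,
    synonym-generalization and concept-generalization splits by surface and
    concept-identifier overlap with the training set, runs longest-match
    dictionary baselines, scores predictions at the entity level (including
    per-split recall, relaxed containment recall and abbreviation-subset
    recall), and implements a statistics-based bias-product debiasing method
    with a lightweight linear reference tagger.  A synthetic corpus generator
    emulates the statistical structure of BioNER benchmarks (split
    proportions, name patterns, per-word label skew, annotation
    inconsistency) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
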