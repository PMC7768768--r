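Package: bisrn
Title: Bilateral Simple Recurrent Network Model of Word Repetition and
    Poststroke Aphasia Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a bilateral (dual-pathway) simple recurrent network
    that learns spoken word repetition over a synthetic lexicon of
    consonant-vowel-consonant words, together with the lesion-and-retrain
    protocol used to simulate poststroke aphasia and recovery. Provides
    generators for the phonetic feature inventory and frequency-banded
    lexicon, online cross-entropy backpropagation training of the network,
    graded unit lesioning with weight noise, a gain-ramp schedule modelling
    inefficient early relearning, and model "neuroimaging" read-outs:
    pathway-silenced functional contribution, output-unit activation,
    laterality indices, and representational similarity analysis against
    the target phonological code. Experiment runners reproduce capacity
    sweeps, lesion-severity sweeps, recovery time-courses, and
    interhemispheric-connectivity manipulations across seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
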