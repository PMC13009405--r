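Package: discoursemap
Title: Transcription-Less Discourse Scoring and Lesion-Symptom Mapping for Aphasia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores spoken-discourse samples from people with aphasia using the
    transcription-less Content Word Fluency (CWF) checklist approach and the
    Correct Information Unit (CIU) coding rules, validates the checklist with
    one- to three-parameter logistic item-response models fitted by marginal
    maximum likelihood (with limited-information M2 goodness of fit), and maps
    the lesion correlates of discourse deficits with multivariate sparse
    canonical-correlation lesion-symptom mapping, streamline-template
    disconnection maps, tract lesion-load partial correlations, and an
    AIC-based predictive validity comparison of behaviour pairs. Includes a
    synthetic-cohort generator (transcripts, lesions, tract atlas, streamline
    template, behaviour table) with the statistical structure these analyses
    assume, and a pipeline that orchestrates the full analysis from one
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
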