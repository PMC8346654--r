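Package: figword
Title: Multimodal Biomedical Document Classification with Figure-Words
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Represents biomedical publications by the panel-type composition
    of their figures (Figure-words), by embedding-mean vectors of their figure
    captions, and by embedding-mean vectors of their titles-and-abstracts, and
    classifies them as relevant or irrelevant to a curated database. Two
    information-integration schemes are provided: an SVM on the concatenated,
    standardized feature vector (CombV) and a stacked meta-classifier on base
    classifier labels and probabilities (CombC). Includes repeated stratified
    cross-validation with precision/recall/F-score reporting, Welch t-test
    system comparison, complementarity (error-overlap) analysis, two-proportion
    z-score ranking of class-distinguishing Figure-words, and a synthetic
    corpus generator with controllable class-conditional signal per modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    e1071,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
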