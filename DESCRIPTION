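Package: capiscore
Title: Rule-Based Classification of Nailfold Videocapillaroscopy Disease Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CAPI-score algorithm, a quantitative decision tree
    that assigns nailfold videocapillaroscopy (NVC) disease patterns (normal,
    non-specific, SSc-early, SSc-active, SSc-late) from software-measured
    capillary features: capillary density and the percentages of giant,
    abnormal and tortuous capillaries, plus haemorrhage presence. Ships the
    supporting pipeline: quality control and exam-level aggregation of
    per-image measurement tables, derivation of a majority-vote gold standard
    from three blinded rater verdicts, stepwise diagnostic-accuracy evaluation
    (confusion matrices, per-class precision and recall, accuracy), and a
    seedable synthetic-cohort simulator with known ground truth so the whole
    pipeline can be exercised end to end without clinical data. A command-line
    interface wires the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
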