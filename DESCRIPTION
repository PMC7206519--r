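Package: edurec
Title: Knowledge-Based Recommendation of Patient Education Materials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-based recommender that matches chronic-disease
    patient profiles to educational documents. Patients and documents are
    projected into a shared fixed-length term space: patients through a
    declarative severity-rule engine (integer severities 0-3), documents
    through keyword extraction (TF-IDF and TextRank with weight-assignment,
    compound-word and synonym-elimination strategies) followed by a
    thresholded word-embedding similarity mapping. Recommendations are
    ranked by the inner product of the paired vectors and maintained in a
    thresholded delivery queue. Includes graded information-retrieval
    metrics (credited precision at k, macro precision, mean average
    precision), a keyword-extraction precision metric, and deterministic
    synthetic-data generators (planted-topic corpora, patient populations,
    relevance judgments) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
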