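Package: etiominer
Title: Mining Symptom Etiologies from Parsed Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting the causes (etiologies) of clinical symptoms
    from dependency-parsed sentence corpora. Implements derivation of
    linearized dependency-path patterns from matched sentences, pattern
    matching with phrase-boundary expansion, human-in-the-loop iterative
    bootstrapping of pattern pools from seed (symptom, etiology) tuples, and
    unification of extracted mentions into ranked concepts via phonetic
    fingerprints and abbreviation expansion. Also provides a
    generate-retrieve-rank-vet verification pipeline for etiologies proposed
    by a large language model (behind a pluggable, mockable backend), a
    deterministic synthetic corpus generator with gold relations for testing,
    and pooled precision/recall evaluation utilities including macro
    averaging, source-overlap counts and Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
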