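Package: wordbeauty
Title: Corpus-Derived Features and Classification of Word Beauty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes eight corpus- and taxonomy-derived features of single
    words (syllable count, sonority score, length, surprisal, orthographic
    neighborhood density, taxonomy-based word similarity, valence, and the
    aesthetic potential, a signed semantic-relatedness contrast against an
    aesthetic label vocabulary) and uses them to classify words as beautiful
    or ugly with an extremely-randomized-trees ensemble.  Includes stratified
    cross-validated ROC/AUC evaluation, a label-permutation null, feature
    importance ranking, per-feature one-way ANOVA follow-ups, and a synthetic
    lexicon generator so the full study can run without licensed corpus or
    wordnet resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    igraph,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
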